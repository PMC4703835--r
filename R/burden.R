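#' Total frequency test (TFT)
#'
#' One-tailed exact test that the pooled rare-allele burden in cases exceeds
#' that in controls, computed on the 2x2 table `[alt, non-alt] x [cases,
#' controls]` by the hypergeometric upper tail (the one-tailed Fisher exact
#' test). Vectorised over its arguments.
#'
#' @param case_alt,case_total Alt-allele count and total allele count in cases.
#' @param control_alt,control_total Same for controls.
#' @return One-tailed p-value(s): probability, under fixed margins, of a case
#'   alt count at least as large as observed.
#' @export
tft_test <- function(case_alt, case_total, control_alt, control_total) {
  if (any(case_total <= 0) || any(control_total <= 0)) {
    abort("allele totals must be > 0")
  }
  if (any(case_alt > case_total) || any(control_alt > control_total)) {
    abort("alt counts cannot exceed totals")
  }
  m <- case_alt + control_alt                       # alt alleles overall
  n <- (case_total - case_alt) + (control_total - control_alt)
  phyper(case_alt - 1, m, n, case_total, lower.tail = FALSE)
}

#' Cohort allelic sum test (CAST)
#'
#' One-tailed exact test on the carrier-count 2x2 table `[carrier,
#' non-carrier] x [cases, controls]`; the carrier-level analogue of
#' [tft_test()]. Vectorised.
#'
#' @param case_carriers,n_cases Carrier count and cohort size in cases.
#' @param control_carriers,n_controls Same for controls.
#' @return One-tailed p-value(s) for case carrier excess.
#' @export
cast_test <- function(case_carriers, n_cases, control_carriers, n_controls) {
  if (any(case_carriers > n_cases) || any(control_carriers > n_controls)) {
    abort("carrier counts cannot exceed cohort sizes")
  }
  m <- case_carriers + control_carriers
  n <- (n_cases - case_carriers) + (n_controls - control_carriers)
  phyper(case_carriers - 1, m, n, n_cases, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j : p_(j) >= p_(i)} m * p_(j) / j`,
#' clipped at 1, returned in the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p, method = "BH")
}

#' Gene-level burden testing per cohort
#'
#' Aggregates retained truncating variants per gene within each cancer type
#' and pan-cancer, applies the minimum-observation exclusion, runs the TFT
#' (allele counts) and CAST (carrier counts) one-tailed exact tests against
#' the control cohort, and ranks by Benjamini-Hochberg FDR within each
#' cohort's test family.
#'
#' Genes whose combined case+control carrier count, summed over variants
#' surviving the per-variant minimum-observation rule, is zero are absent from
#' the output rather than reported at p = 1. Allele totals assume diploid
#' autosomal counting (`2 * n` alleles per cohort of `n` samples); a per-gene
#' ploidy override can be supplied.
#'
#' @param variants Germline variant tibble, already passed through
#'   [apply_rare_filters()] (rows with `retained == FALSE` are dropped if the
#'   column is present) and [classify_truncation()] (computed if absent; only
#'   truncating variants are counted).
#' @param meta Sample metadata tibble with case/control roles.
#' @param gene_sets Optional character vector restricting the gene universe;
#'   default all genes observed in `variants`.
#' @param fdr Significance threshold on q (default 0.05).
#' @param min_obs Minimum combined case+control carrier count per variant
#'   (default 2, genotype-level controls); variants below it are excluded
#'   before aggregation.
#' @param min_obs_unit `"carriers"` (default) or `"alleles"` for the
#'   minimum-observation rule.
#' @param ploidy Named numeric vector of per-gene ploidy overrides (default
#'   2 for every gene).
#' @return A tibble with one row per gene x cohort (`cohort` is a cancer-type
#'   code or `"pan"`): aggregated counts, `p_tft`, `p_cast`, `q` (BH within
#'   cohort, on `p_tft`), and `significant` at the configured FDR.
#' @export
run_burden <- function(variants, meta, gene_sets = NULL, fdr = 0.05,
                       min_obs = 2L, min_obs_unit = c("carriers", "alleles"),
                       ploidy = NULL) {
  min_obs_unit <- match.arg(min_obs_unit)
  if (!"is_truncation" %in% names(variants)) {
    variants <- classify_truncation(variants)
  }
  if ("retained" %in% names(variants)) {
    variants <- variants %>% filter(.data$retained)
  }
  variants <- variants %>% filter(.data$is_truncation)
  if (!is.null(gene_sets)) {
    if (length(gene_sets) == 0) abort("empty gene universe")
    variants <- variants %>% filter(.data$gene %in% gene_sets)
  }
  empty_result <- tibble(
    gene = character(), cohort = character(),
    case_alt_alleles = integer(), case_total_alleles = integer(),
    control_alt_alleles = integer(), control_total_alleles = integer(),
    case_carriers = integer(), n_cases = integer(),
    control_carriers = integer(), n_controls = integer(),
    p_tft = numeric(), p_cast = numeric(), q = numeric(),
    significant = logical()
  )
  if (nrow(variants) == 0) return(empty_result)

  v <- variants %>%
    mutate(.key = variant_key(variants)) %>%
    left_join(meta %>% select("sample_id", "role", "cancer_type"),
              by = "sample_id")
  n_controls <- sum(meta$role == "control")
  if (n_controls == 0) abort("no control samples in metadata")

  # minimum-observation rule at the variant level, combined cases + controls
  obs <- if (min_obs_unit == "carriers") {
    v %>% distinct(.data$.key, .data$sample_id) %>% count(.data$.key, name = "n_obs")
  } else {
    v %>% count(.data$.key, name = "n_obs")   # one alt allele per record
  }
  keep_keys <- obs$.key[obs$n_obs >= min_obs]
  v <- v %>% filter(.data$.key %in% keep_keys)
  if (nrow(v) == 0) return(empty_result)

  cohort_sizes <- meta %>%
    filter(.data$role == "case") %>%
    count(.data$cancer_type, name = "n_cases")

  gene_ploidy <- function(g) {
    if (is.null(ploidy)) return(2)
    out <- unname(ploidy[g])
    ifelse(is.na(out), 2, out)
  }

  tally_one <- function(vv, cohort_label, n_cases_cohort) {
    if (nrow(vv) == 0) return(NULL)
    per_gene <- vv %>%
      group_by(.data$gene) %>%
      summarise(
        case_alt_alleles = sum(.data$role == "case"),
        control_alt_alleles = sum(.data$role == "control"),
        case_carriers = dplyr::n_distinct(.data$sample_id[.data$role == "case"]),
        control_carriers = dplyr::n_distinct(.data$sample_id[.data$role == "control"]),
        .groups = "drop"
      ) %>%
      filter(.data$case_carriers + .data$control_carriers > 0)
    if (nrow(per_gene) == 0) return(NULL)
    pl <- gene_ploidy(per_gene$gene)
    per_gene %>%
      mutate(cohort = cohort_label,
             n_cases = n_cases_cohort,
             n_controls = .env$n_controls,
             case_total_alleles = as.integer(round(pl * n_cases_cohort)),
             control_total_alleles = as.integer(round(pl * .env$n_controls)))
  }

  pan <- tally_one(v %>% filter(.data$role == "case" | .data$role == "control"),
                   "pan", sum(cohort_sizes$n_cases))
  per_type <- purrr::map(cohort_sizes$cancer_type, function(ct) {
    vv <- v %>% filter(.data$role == "control" |
                         (.data$role == "case" & .data$cancer_type == ct))
    tally_one(vv, ct, cohort_sizes$n_cases[cohort_sizes$cancer_type == ct])
  })
  res <- bind_rows(c(list(pan), per_type))
  if (is.null(res) || nrow(res) == 0) return(empty_result)

  res <- res %>%
    mutate(
      p_tft = tft_test(.data$case_alt_alleles, .data$case_total_alleles,
                       .data$control_alt_alleles, .data$control_total_alleles),
      p_cast = cast_test(.data$case_carriers, .data$n_cases,
                         .data$control_carriers, .data$n_controls)
    ) %>%
    group_by(.data$cohort) %>%
    mutate(q = bh_fdr(.data$p_tft)) %>%
    ungroup() %>%
    mutate(significant = .data$q <= fdr) %>%
    select("gene", "cohort", "case_alt_alleles", "case_total_alleles",
           "control_alt_alleles", "control_total_alleles",
           "case_carriers", "n_cases", "control_carriers", "n_controls",
           "p_tft", "p_cast", "q", "significant") %>%
    arrange(.data$cohort, .data$q, .data$gene)
  res
}
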