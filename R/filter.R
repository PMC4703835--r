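#' Rare-variant filter configuration
#'
#' Thresholds for the rare-variant filtering cascade. Defaults follow the
#' standard protocol for rare germline truncation discovery in tumour/normal
#' cohorts: pooled case/control minor allele frequency at most 0.05%,
#' population MAF below 1% (1000 Genomes-style reference), per-cancer-type
#' cohort carrier frequency below 1%.
#'
#' @param pooled_maf_max Maximum pooled MAF (average of the case-cohort and
#'   control MAFs per variant). Default `5e-4`.
#' @param maf_1000g_max Population reference MAF ceiling (strict `<`).
#' @param cohort_freq_max Per-cancer-type carrier-frequency ceiling (strict `<`).
#' @param min_obs_combined Minimum combined case+control carrier count per
#'   variant for the burden stage; `2` for genotype-level (WHI-style) control
#'   cohorts, `3` for summary-level (ESP-style) ones. Not applied by
#'   [apply_rare_filters()]; consumed by [run_burden()].
#' @param strict_pooled If `TRUE`, the pooled-MAF rule uses a strict `<`
#'   instead of the default inclusive `<=`.
#' @param splice_flank_bp Width in bp of the exonic flank within which a
#'   splice-site change still counts as truncating, when a distance to the
#'   nearest exon boundary is available.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(pooled_maf_max = 5e-4,
                          maf_1000g_max = 0.01,
                          cohort_freq_max = 0.01,
                          min_obs_combined = 2L,
                          strict_pooled = FALSE,
                          splice_flank_bp = 2L) {
  stopifnot(pooled_maf_max > 0, pooled_maf_max <= 1,
            maf_1000g_max > 0, maf_1000g_max <= 1,
            cohort_freq_max > 0, cohort_freq_max <= 1,
            min_obs_combined >= 1)
  structure(list(pooled_maf_max = pooled_maf_max,
                 maf_1000g_max = maf_1000g_max,
                 cohort_freq_max = cohort_freq_max,
                 min_obs_combined = as.integer(min_obs_combined),
                 strict_pooled = isTRUE(strict_pooled),
                 splice_flank_bp = as.integer(splice_flank_bp)),
            class = "filter_config")
}

#' Classify truncating variants
#'
#' A variant is truncating iff its class is nonsense, splice-site, frameshift
#' indel or nonstop. When a `splice_dist` column is present (distance in bp
#' from the variant to the nearest exon boundary, intronic side), splice-site
#' changes only count within `splice_flank_bp` of the boundary — the two base
#' pairs flanking each exon cover the donor/acceptor dinucleotides.
#'
#' @param variants Tibble with a `variant_class` column and optionally a
#'   `splice_dist` column.
#' @param splice_flank_bp Flank width in bp (default 2).
#' @return The input tibble with a logical `is_truncation` column added.
#' @export
classify_truncation <- function(variants, splice_flank_bp = 2L) {
  trunc_classes <- c("nonsense", "splice_site", "frameshift_indel", "nonstop")
  is_tr <- variants$variant_class %in% trunc_classes
  if ("splice_dist" %in% names(variants)) {
    sp <- variants$variant_class == "splice_site" & !is.na(variants$splice_dist)
    is_tr[sp] <- abs(variants$splice_dist[sp]) <= splice_flank_bp
  }
  variants %>% mutate(is_truncation = is_tr)
}

#' Pooled minor allele frequency
#'
#' The average of the per-cohort minor allele frequencies of a variant in the
#' test (case) and control groups.
#'
#' @param case_alt,case_alleles Alt-allele count and total allele count in
#'   cases.
#' @param control_alt,control_alleles Same for controls.
#' @return `(case_alt/case_alleles + control_alt/control_alleles) / 2`.
#' @export
pooled_maf <- function(case_alt, case_alleles, control_alt, control_alleles) {
  if (any(case_alleles <= 0) || any(control_alleles <= 0)) {
    abort("allele totals must be > 0")
  }
  (case_alt / case_alleles + control_alt / control_alleles) / 2
}

# Variant identity key shared by the filter and burden stages.
variant_key <- function(df) {
  paste(df$gene, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Apply the rare-variant filtering cascade
#'
#' Evaluates, per distinct variant (gene:chrom:pos:ref:alt), three
#' order-independent frequency rules and annotates every input record with the
#' outcome:
#' * `maf_1000g`: population reference MAF must be `< maf_1000g_max`
#'   (missing values pass);
#' * `cohort_freq`: the carrier frequency among cases of every cancer type
#'   must be `< cohort_freq_max`;
#' * `pooled_maf`: the average of the case-cohort allele frequency (one alt
#'   allele per carrier record over `2 * n_cases` alleles) and the control
#'   allele frequency must be `<= pooled_maf_max` (strict `<` when
#'   `cfg$strict_pooled`). The control frequency is taken from genotype-level
#'   control records when present in `variants`, falling back to the `maf_esp`
#'   column (missing treated as unobserved, frequency 0).
#'
#' A rejected variant carries the name of the first failing rule in the order
#' above; since a variant must pass all rules, the retained set does not
#' depend on that order.
#'
#' @param variants Germline variant tibble ([read_variant_table()] layout).
#' @param meta Sample metadata tibble ([read_sample_metadata()] layout)
#'   covering every sample in `variants`.
#' @param cfg A [filter_config()].
#' @return The input tibble with logical `retained` and character
#'   `reject_reason` (`NA` for retained records) columns added.
#' @export
apply_rare_filters <- function(variants, meta, cfg = filter_config()) {
  missing_samples <- setdiff(unique(variants$sample_id), meta$sample_id)
  if (length(missing_samples) > 0) {
    abort(paste0("Sample(s) in variant table absent from metadata: ",
                 paste(utils::head(missing_samples, 5), collapse = ", ")))
  }
  v <- variants %>%
    mutate(.key = variant_key(variants)) %>%
    left_join(meta %>% select("sample_id", "role", "cancer_type"),
              by = "sample_id")
  n_cases <- sum(meta$role == "case")
  n_controls <- sum(meta$role == "control")
  type_sizes <- meta %>%
    filter(.data$role == "case") %>%
    count(.data$cancer_type, name = "n_type")

  per_var <- v %>%
    group_by(.data$.key) %>%
    summarise(
      case_carriers = dplyr::n_distinct(.data$sample_id[.data$role == "case"]),
      control_carriers = dplyr::n_distinct(.data$sample_id[.data$role == "control"]),
      maf_1000g = first(.data$maf_1000g),
      maf_esp = first(.data$maf_esp),
      .groups = "drop"
    )
  # worst per-cancer-type carrier frequency
  type_freq <- v %>%
    filter(.data$role == "case") %>%
    distinct(.data$.key, .data$sample_id, .data$cancer_type) %>%
    count(.data$.key, .data$cancer_type, name = "n_carriers") %>%
    left_join(type_sizes, by = "cancer_type") %>%
    group_by(.data$.key) %>%
    summarise(max_type_freq = max(.data$n_carriers / .data$n_type),
              .groups = "drop")
  per_var <- per_var %>%
    left_join(type_freq, by = ".key") %>%
    mutate(max_type_freq = dplyr::coalesce(.data$max_type_freq, 0))

  case_af <- per_var$case_carriers / (2 * n_cases)
  control_af <- if (n_controls > 0) {
    per_var$control_carriers / (2 * n_controls)
  } else {
    dplyr::coalesce(per_var$maf_esp, 0)
  }
  pmaf <- (case_af + control_af) / 2
  pooled_fail <- if (cfg$strict_pooled) pmaf >= cfg$pooled_maf_max
                 else pmaf > cfg$pooled_maf_max

  reason <- rep(NA_character_, nrow(per_var))
  fail_1000g <- !is.na(per_var$maf_1000g) & per_var$maf_1000g >= cfg$maf_1000g_max
  fail_cohort <- per_var$max_type_freq >= cfg$cohort_freq_max
  reason[pooled_fail] <- "pooled_maf"
  reason[fail_cohort] <- "cohort_freq"
  reason[fail_1000g] <- "maf_1000g"

  verdict <- tibble(.key = per_var$.key,
                    retained = is.na(reason),
                    reject_reason = reason,
                    pooled_maf = pmaf)
  variants %>%
    mutate(.key = variant_key(variants)) %>%
    left_join(verdict, by = ".key") %>%
    select(-".key")
}

#' Wilson score interval
#'
#' Confidence interval for a binomial proportion based on the score statistic.
#' Unlike the Wald interval it behaves well at small depths and near 0 or 1,
#' which is why it is used both for carrier-frequency summaries and for
#' pre-conditioning read-count VAF estimates.
#'
#' @param successes,trials Non-negative integers, `trials > 0`. Vectorised.
#' @param confidence Two-sided coverage, in (0, 1). Default 0.95.
#' @return A tibble with columns `estimate`, `low`, `high`.
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (any(trials <= 0)) abort("trials must be > 0")
  if (any(successes < 0 | successes > trials)) {
    abort("successes must lie in [0, trials]")
  }
  stopifnot(confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- (z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))) / denom
  low <- pmax(0, centre - half)
  high <- pmin(1, centre + half)
  # endpoints are exact in closed form; guard against rounding drift
  low[successes == 0] <- 0
  high[successes == trials] <- 1
  tibble(estimate = p, low = low, high = high)
}

#' Carrier-frequency summaries per cancer type
#'
#' For a gene set, computes per cancer type the fraction of cases carrying at
#' least one retained truncating variant in the set, with a 95% Wilson score
#' interval.
#'
#' @param variants Tibble of retained germline variants; must carry
#'   `is_truncation` (see [classify_truncation()]) or it is computed.
#' @param meta Sample metadata tibble.
#' @param gene_set Character vector of gene symbols (nonempty).
#' @param gene_set_name Label recorded in the output.
#' @param confidence Interval coverage (default 0.95).
#' @return A tibble with one row per cancer type: `cancer_type`, `gene_set`,
#'   `n_cases`, `n_carriers`, `fraction`, `ci_low`, `ci_high`.
#' @export
carrier_frequency <- function(variants, meta, gene_set,
                              gene_set_name = "gene_set",
                              confidence = 0.95) {
  if (length(gene_set) == 0) abort("gene_set must be nonempty")
  if (!"is_truncation" %in% names(variants)) {
    variants <- classify_truncation(variants)
  }
  cases <- meta %>% filter(.data$role == "case")
  if (nrow(cases) == 0) abort("no case samples in metadata")
  carriers <- variants %>%
    filter(.data$is_truncation, .data$gene %in% gene_set) %>%
    distinct(.data$sample_id)
  out <- cases %>%
    mutate(carrier = .data$sample_id %in% carriers$sample_id) %>%
    group_by(.data$cancer_type) %>%
    summarise(n_cases = n(), n_carriers = sum(.data$carrier), .groups = "drop")
  ci <- wilson_interval(out$n_carriers, out$n_cases, confidence)
  out %>%
    mutate(gene_set = gene_set_name,
           fraction = ci$estimate, ci_low = ci$low, ci_high = ci$high) %>%
    select("cancer_type", "gene_set", "n_cases", "n_carriers",
           "fraction", "ci_low", "ci_high")
}
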