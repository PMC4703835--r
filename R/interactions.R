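#' Build germline/somatic carrier matrices
#'
#' @param germline Germline variant tibble (truncation carriers are used:
#'   rows with `is_truncation`, computed if absent).
#' @param somatic Somatic event tibble.
#' @param meta Sample metadata; the sample universe is the cases present in
#'   `meta` (the two indicator matrices share it).
#' @return A list with logical matrices `germline` and `somatic`
#'   (samples x genes) and the per-sample `cancer_type` vector.
#' @export
carrier_matrices <- function(germline, somatic, meta) {
  if (!"is_truncation" %in% names(germline)) {
    germline <- classify_truncation(germline)
  }
  cases <- meta %>% filter(.data$role == "case")
  samples <- cases$sample_id
  mk <- function(df, genes) {
    m <- matrix(FALSE, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
    df <- df %>% filter(.data$sample_id %in% samples, .data$gene %in% genes)
    if (nrow(df) > 0) m[cbind(df$sample_id, df$gene)] <- TRUE
    m
  }
  g_genes <- sort(unique(germline$gene[germline$is_truncation]))
  s_genes <- sort(unique(somatic$gene))
  list(germline = mk(germline %>% filter(.data$is_truncation), g_genes),
       somatic = mk(somatic, s_genes),
       cancer_type = setNames(cases$cancer_type, cases$sample_id))
}

#' Germline-somatic co-occurrence / mutual-exclusivity permutation test
#'
#' The statistic is the number of samples carrying both the germline and the
#' somatic event. The null is built by permuting the germline indicator across
#' samples (within cancer-type strata when supplied), keeping the somatic
#' vector fixed, `n_perm` times. Both tails are reported with the add-one
#' correction: large overlaps indicate co-occurrence, small ones mutual
#' exclusivity.
#'
#' @param g,s Logical indicator vectors over the same samples.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param strata Optional factor of cancer types; permutation is restricted
#'   within levels.
#' @return An object of class `"cooccurrence_test"` with fields `observed`,
#'   `p_cooccurrence`, `p_mutual_exclusivity`, `n_perm`, `untestable`.
#' @export
cooccurrence_permutation <- function(g, s, n_perm = 10000L, seed = NULL,
                                     strata = NULL) {
  if (length(g) != length(s)) abort("indicators must cover the same samples")
  g <- as.logical(g); s <- as.logical(s)
  obs <- sum(g & s)
  if (sum(g) == 0 || sum(s) == 0) {
    out <- list(observed = obs, p_cooccurrence = 1, p_mutual_exclusivity = 1,
                n_perm = as.integer(n_perm), seed = seed, untestable = TRUE)
    return(structure(out, class = "cooccurrence_test"))
  }
  permute_once <- if (is.null(strata)) {
    function() sum(g[sample.int(length(g))] & s)
  } else {
    strata <- as.factor(strata)
    idx_by <- split(seq_along(g), strata)
    function() {
      gp <- g
      for (ii in idx_by) gp[ii] <- g[ii][sample.int(length(ii))]
      sum(gp & s)
    }
  }
  run <- function() vapply(seq_len(n_perm), function(i) permute_once(), integer(1))
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(observed = obs,
                 p_cooccurrence = (sum(null >= obs) + 1) / (n_perm + 1),
                 p_mutual_exclusivity = (sum(null <= obs) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = seed, untestable = FALSE),
            class = "cooccurrence_test")
}

#' @export
print.cooccurrence_test <- function(x, ...) {
  cat("Germline-somatic permutation test (n =", x$n_perm, ")\n")
  cat("  observed co-occurrence:", x$observed, "\n")
  cat("  p(co-occurrence)      :", format(x$p_cooccurrence, digits = 4), "\n")
  cat("  p(mutual exclusivity) :", format(x$p_mutual_exclusivity, digits = 4), "\n")
  if (x$untestable) cat("  [untestable: empty marginal]\n")
  invisible(x)
}

#' Pairwise germline-somatic interaction screen
#'
#' Runs [cooccurrence_permutation()] for every germline x somatic gene pair
#' in the carrier matrices.
#'
#' @param mats Output of [carrier_matrices()].
#' @param n_perm Permutations per pair.
#' @param seed Optional integer seed (each pair gets a derived seed).
#' @param stratify If `TRUE`, permute within cancer types.
#' @return Tibble with one row per pair: `germline_gene`, `somatic_gene`,
#'   `observed`, `p_cooccurrence`, `p_mutual_exclusivity`, `untestable`.
#' @export
run_interaction_screen <- function(mats, n_perm = 10000L, seed = NULL,
                                   stratify = FALSE) {
  strata <- if (stratify) mats$cancer_type[rownames(mats$germline)] else NULL
  pairs <- expand.grid(germline_gene = colnames(mats$germline),
                       somatic_gene = colnames(mats$somatic),
                       stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    fit <- cooccurrence_permutation(
      mats$germline[, pr$germline_gene], mats$somatic[, pr$somatic_gene],
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + i,
      strata = strata
    )
    tibble(germline_gene = pr$germline_gene, somatic_gene = pr$somatic_gene,
           observed = fit$observed, p_cooccurrence = fit$p_cooccurrence,
           p_mutual_exclusivity = fit$p_mutual_exclusivity,
           untestable = fit$untestable)
  })
}

#' Carrier association with somatic mutation burden
#'
#' One-tailed Wilcoxon rank-sum test that carriers have higher per-sample
#' somatic mutation counts than non-carriers; exact enumeration when both
#' groups have at most 10 samples and no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param carrier Logical vector per case.
#' @param somatic_counts Integer vector of somatic mutation counts per case.
#' @return A tibble with `statistic` (rank-sum W) and `p`.
#' @export
mutation_burden_association <- function(carrier, somatic_counts) {
  carrier <- as.logical(carrier)
  x <- somatic_counts[carrier]
  y <- somatic_counts[!carrier]
  if (length(x) == 0 || length(y) == 0) abort("one group is empty")
  if (length(unique(somatic_counts)) == 1) {
    # fully tied data carries no ordering signal; the rank-sum variance is 0
    return(tibble(statistic = length(x) * length(y) / 2, p = 0.5))
  }
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  fit <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(fit$statistic), p = fit$p.value)
}

#' Carrier association with age of onset
#'
#' Linear model `age ~ carrier + cancer_type` with a one-tailed p-value for a
#' negative carrier effect (carriers younger at diagnosis). With a single
#' cancer type the covariate is dropped with a warning. A one-tailed Wilcoxon
#' rank-sum alternative (carriers younger) is also reported.
#'
#' @param data Tibble with columns `carrier` (logical), `age` (years) and
#'   `cancer_type`.
#' @return An object of class `"age_onset_fit"` wrapping the lm fit, with
#'   fields `effect` (years), `p` (one-tailed), `p_wilcoxon`, `covariate_used`.
#' @export
age_onset_association <- function(data) {
  data <- data %>% filter(!is.na(.data$age))
  if (length(unique(data$age)) < 2) abort("age vector is constant")
  use_cov <- length(unique(data$cancer_type)) >= 2
  if (!use_cov) warn("single cancer type: covariate dropped")
  fml <- if (use_cov) age ~ carrier + cancer_type else age ~ carrier
  fit <- lm(fml, data = data %>% mutate(carrier = as.logical(.data$carrier)))
  sm <- summary(fit)$coefficients
  eff <- sm["carrierTRUE", "Estimate"]
  tval <- sm["carrierTRUE", "t value"]
  p_one <- pt(tval, fit$df.residual)            # lower tail: negative effect
  pw <- suppressWarnings(
    wilcox.test(data$age[as.logical(data$carrier)],
                data$age[!as.logical(data$carrier)],
                alternative = "less", exact = FALSE)$p.value
  )
  structure(list(fit = fit, effect = eff, p = p_one, p_wilcoxon = pw,
                 covariate_used = use_cov),
            class = "age_onset_fit")
}

#' @export
print.age_onset_fit <- function(x, ...) {
  cat("Age-of-onset association (linear model",
      if (x$covariate_used) "with cancer-type covariate)" else ")", "\n")
  cat("  carrier effect (years):", format(x$effect, digits = 4), "\n")
  cat("  one-tailed p (younger):", format(x$p, digits = 4), "\n")
  cat("  Wilcoxon alternative p:", format(x$p_wilcoxon, digits = 4), "\n")
  invisible(x)
}
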