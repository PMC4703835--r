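#' Tidy a gene-level LOH test
#'
#' @param x A `"loh_gene_test"` object.
#' @param ... Unused.
#' @return One-row tibble: `gene`, `mode`, `statistic`, `df`, `p.value`,
#'   `included`, `exclusion_reason`.
#' @export
tidy.loh_gene_test <- function(x, ...) {
  tibble(gene = x$gene, mode = x$mode, statistic = x$statistic,
         df = as.integer(x$df), p.value = x$p,
         included = x$included, exclusion_reason = x$exclusion_reason)
}

#' @rdname tidy.loh_gene_test
#' @export
glance.loh_gene_test <- function(x, ...) {
  tibble(mode = x$mode, p.value = x$p, included = x$included)
}

#' Tidy a germline-somatic permutation test
#'
#' @param x A `"cooccurrence_test"` object.
#' @param ... Unused.
#' @return One-row tibble with the observed overlap, both tail p-values, the
#'   permutation count and the untestable flag.
#' @export
tidy.cooccurrence_test <- function(x, ...) {
  tibble(observed = x$observed,
         p.cooccurrence = x$p_cooccurrence,
         p.mutual_exclusivity = x$p_mutual_exclusivity,
         n.perm = x$n_perm, untestable = x$untestable)
}

#' @rdname tidy.cooccurrence_test
#' @export
glance.cooccurrence_test <- function(x, ...) tidy(x)

#' Tidy an age-of-onset association fit
#'
#' @param x An `"age_onset_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (carrier effect in years), `p.value`
#'   (one-tailed, younger onset), `p.wilcoxon`, `covariate_used`.
#' @export
tidy.age_onset_fit <- function(x, ...) {
  tibble(term = "carrierTRUE", estimate = x$effect, p.value = x$p,
         p.wilcoxon = x$p_wilcoxon, covariate_used = x$covariate_used)
}

#' @rdname tidy.age_onset_fit
#' @export
glance.age_onset_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, df.residual = x$fit$df.residual,
         p.value = x$p)
}
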