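#' LOH analysis configuration
#'
#' Tuning parameters for the site-level loss-of-heterozygosity tests.
#'
#' @param confidence Coverage of the Wilson interval used for VAF
#'   pre-conditioning (default 0.90; two-sided z of 1.6449).
#' @param max_halfwidth Maximum allowed larger distance between a VAF estimate
#'   and either end of its Wilson interval (default 0.12); sites with a wider
#'   interval are too noisy to test.
#' @param prefilter_scope `"both"` (tumour and normal VAF intervals must both
#'   qualify, default) or `"tumour"`.
#' @param site_fdr_truncation,site_fdr_missense Significance thresholds on the
#'   BH q within each variant-class family (defaults 0.05 and 0.01).
#' @param prioritize_fdr Looser threshold flagged as `prioritized` (default
#'   0.20).
#' @param null_cap Maximum size of the permutation-null cross-product; larger
#'   nulls are uniformly subsampled (default 1e6).
#' @param combine_method `"fisher"` (chi-square with 4 df, default) or
#'   `"stouffer"` for combining the Fisher-exact and permutation p-values.
#' @param permutation_stat `"vaf"` (default; tumour VAF against the somatic
#'   null) or `"ratio"` (tumour/normal VAF ratio against the null of ratios to
#'   0.5).
#' @param seed Optional integer seed for the null subsample.
#' @return A list of class `"loh_config"`.
#' @export
loh_config <- function(confidence = 0.90,
                       max_halfwidth = 0.12,
                       prefilter_scope = c("both", "tumour"),
                       site_fdr_truncation = 0.05,
                       site_fdr_missense = 0.01,
                       prioritize_fdr = 0.20,
                       null_cap = 1e6,
                       combine_method = c("fisher", "stouffer"),
                       permutation_stat = c("vaf", "ratio"),
                       seed = NULL) {
  stopifnot(confidence > 0, confidence < 1,
            max_halfwidth > 0, max_halfwidth < 1,
            null_cap >= 1)
  structure(list(confidence = confidence,
                 max_halfwidth = max_halfwidth,
                 prefilter_scope = match.arg(prefilter_scope),
                 site_fdr_truncation = site_fdr_truncation,
                 site_fdr_missense = site_fdr_missense,
                 prioritize_fdr = prioritize_fdr,
                 null_cap = null_cap,
                 combine_method = match.arg(combine_method),
                 permutation_stat = match.arg(permutation_stat),
                 seed = seed),
            class = "loh_config")
}

#' Variant allele fractions and tumour/normal ratio
#'
#' @param df Tibble with read-count columns `n_ref`, `n_alt`, `t_ref`,
#'   `t_alt`.
#' @return The tibble with `vaf_normal`, `vaf_tumour` and `vaf_ratio` columns
#'   added; the ratio is `NA` where the normal VAF is 0.
#' @export
add_vafs <- function(df) {
  vn <- df$n_alt / (df$n_ref + df$n_alt)
  vt <- df$t_alt / (df$t_ref + df$t_alt)
  df %>% mutate(vaf_normal = vn, vaf_tumour = vt,
                vaf_ratio = ifelse(vn > 0, vt / vn, NA_real_))
}

#' Tumour-to-normal VAF ratio
#'
#' With no loss of heterozygosity the tumour and normal VAFs at a
#' germline-heterozygous site coincide (ratio 1); with complete loss of the
#' wild-type allele in a pure tumour the ratio is 2. Impurity and clonal
#' heterogeneity pull the ratio back toward 1.
#'
#' @param n_ref,n_alt,t_ref,t_alt Read counts (vectorised).
#' @return `vaf_tumour / vaf_normal`; errors if any normal VAF is 0.
#' @export
vaf_ratio <- function(n_ref, n_alt, t_ref, t_alt) {
  vn <- n_alt / (n_ref + n_alt)
  if (any(vn == 0)) abort("vaf_ratio undefined where normal VAF is 0")
  (t_alt / (t_ref + t_alt)) / vn
}

#' Pre-condition sites on VAF estimate reliability
#'
#' Read-count VAF estimates vary in reliability with depth. A site is retained
#' only if the larger distance from the VAF to either end of its Wilson score
#' interval, at the configured confidence, does not exceed `max_halfwidth` —
#' by default for both the tumour and the normal estimate.
#'
#' @param sites Tibble with `n_ref`, `n_alt`, `t_ref`, `t_alt`.
#' @param cfg A [loh_config()].
#' @return The tibble with a logical `prefilter_pass` column added.
#' @export
prefilter_by_confidence <- function(sites, cfg = loh_config()) {
  halfwidth <- function(successes, trials) {
    ci <- wilson_interval(successes, trials, cfg$confidence)
    pmax(ci$high - ci$estimate, ci$estimate - ci$low)
  }
  hw_t <- halfwidth(sites$t_alt, sites$t_ref + sites$t_alt)
  pass <- hw_t <= cfg$max_halfwidth
  if (cfg$prefilter_scope == "both") {
    hw_n <- halfwidth(sites$n_alt, sites$n_ref + sites$n_alt)
    pass <- pass & hw_n <= cfg$max_halfwidth
  }
  sites %>% mutate(prefilter_pass = pass)
}

#' Site-level Fisher exact test of allelic enrichment
#'
#' One-tailed exact test, on the 2x2 table of allele type (reference,
#' variant) versus sample type (tumour, normal), that the tumour alt-allele
#' fraction exceeds the matched normal's. Vectorised.
#'
#' @param n_ref,n_alt,t_ref,t_alt Read counts.
#' @return One-tailed p-value(s): hypergeometric upper tail at the observed
#'   tumour alt count with margins fixed.
#' @export
site_fisher_test <- function(n_ref, n_alt, t_ref, t_alt) {
  tot <- n_ref + n_alt + t_ref + t_alt
  if (any(tot == 0)) abort("all-zero read-count table")
  m <- t_alt + n_alt                 # variant alleles overall
  n <- t_ref + n_ref                 # reference alleles overall
  k <- t_alt + t_ref                 # tumour reads drawn
  phyper(t_alt - 1, m, n, k, lower.tail = FALSE)
}

#' Build the empirical somatic-VAF permutation null
#'
#' Permutes all combinations of reference and variant read counts of the
#' background somatic events — every pairing of a reference count `r_i` with a
#' variant count `v_j` yields a null VAF `v_j / (r_i + v_j)` — giving an
#' empirical null for the characteristic VAF of somatically mutated genes.
#' Genes with prior evidence of significance (e.g., burden-test hits) must be
#' excluded from the background before calling this, so the null is not
#' contaminated by true signal.
#'
#' @param somatic Tibble of background somatic events with `t_ref`, `t_alt`
#'   (and optionally `gene`).
#' @param exclude_genes Genes removed from the background (candidate genes).
#' @param cap Maximum null size; the cross-product is uniformly subsampled to
#'   `cap` when larger.
#' @param seed Optional integer seed for the subsample.
#' @return Sorted numeric vector of null VAFs.
#' @export
build_permutation_null <- function(somatic, exclude_genes = character(),
                                   cap = 1e6, seed = NULL) {
  if ("gene" %in% names(somatic) && length(exclude_genes) > 0) {
    somatic <- somatic %>% filter(!.data$gene %in% exclude_genes)
  }
  if (nrow(somatic) == 0) abort("empty somatic background")
  r <- somatic$t_ref
  v <- somatic$t_alt
  n_pairs <- length(r) * length(v)
  draw <- function() {
    if (n_pairs <= cap) {
      grid <- expand.grid(r = r, v = v)
      grid$v / (grid$r + grid$v)
    } else {
      i <- sample.int(length(r), cap, replace = TRUE)
      j <- sample.int(length(v), cap, replace = TRUE)
      v[j] / (r[i] + v[j])
    }
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  sort(vals)
}

#' Empirical upper-tailed permutation p-value
#'
#' @param x Observed statistic(s) (tumour VAF by default).
#' @param null Sorted or unsorted numeric null distribution (nonempty).
#' @return `(#\{null >= x\} + 1) / (N + 1)` per element; the add-one
#'   correction keeps p strictly positive so it can enter Fisher's
#'   combination.
#' @export
site_permutation_test <- function(x, null) {
  if (length(null) == 0) abort("empty null distribution")
  null <- sort(null)
  N <- length(null)
  # count of null values >= x via binary search on the sorted null
  n_ge <- N - findInterval(x, null, left.open = TRUE)
  (n_ge + 1) / (N + 1)
}

#' Combine two independent p-values
#'
#' Fisher's method: `X = -2 (ln p1 + ln p2)` referred to a chi-square
#' distribution with 4 degrees of freedom, whose survival function has the
#' closed form `exp(-X/2) (1 + X/2)`. Stouffer's z-average is available as an
#' alternative. Zero inputs are clamped to the smallest representable
#' positive double with a warning.
#'
#' @param p1,p2 p-values in (0, 1] (vectorised).
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return Combined p-value(s).
#' @export
combine_pvalues <- function(p1, p2, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  clamp <- function(p) {
    if (any(p <= 0)) {
      warn("p-value(s) of 0 clamped to .Machine$double.xmin")
      p <- pmax(p, .Machine$double.xmin)
    }
    if (any(p > 1)) abort("p-values must be <= 1")
    p
  }
  p1 <- clamp(p1); p2 <- clamp(p2)
  if (method == "fisher") {
    X <- -2 * (log(p1) + log(p2))
    pchisq(X, df = 4, lower.tail = FALSE)
  } else {
    z <- (qnorm(p1, lower.tail = FALSE) + qnorm(p2, lower.tail = FALSE)) / sqrt(2)
    pnorm(z, lower.tail = FALSE)
  }
}

#' Site-level LOH testing pipeline
#'
#' For each germline-heterozygous site with tumour and normal read counts:
#' pre-condition on Wilson-interval reliability, test tumour-vs-normal allelic
#' enrichment (one-tailed Fisher exact), test the tumour VAF against the
#' somatic-background permutation null, combine the two (essentially
#' independent) p-values by Fisher's method, and correct by Benjamini-Hochberg
#' separately within the truncation and missense families.
#'
#' @param sites Germline variant tibble with read counts and `variant_class`
#'   (a `is_truncation` column is computed if absent); rows without tumour
#'   counts are dropped.
#' @param somatic Background somatic events for the permutation null.
#' @param cfg A [loh_config()].
#' @param exclude_genes Candidate genes excluded from the null background
#'   (typically the burden-test genes, including those in `sites`).
#' @return The site tibble with `vaf_normal`, `vaf_tumour`, `vaf_ratio`,
#'   `prefilter_pass`, `family` (`"truncation"`/`"missense"`/`"other"`),
#'   `p_fisher`, `p_perm`, `p_combined`, `q`, `significant` and `prioritized`
#'   columns. Tests and FDR are computed over pre-filter survivors only
#'   (others carry `NA` p/q and `FALSE` flags); silent/other classes are
#'   retained but not assigned to a test family.
#' @export
run_site_loh <- function(sites, somatic, cfg = loh_config(),
                         exclude_genes = unique(sites$gene)) {
  sites <- sites %>% filter(!is.na(.data$t_ref) & !is.na(.data$t_alt))
  if (!"is_truncation" %in% names(sites)) sites <- classify_truncation(sites)
  sites <- sites %>%
    add_vafs() %>%
    prefilter_by_confidence(cfg) %>%
    mutate(family = dplyr::case_when(
      .data$is_truncation ~ "truncation",
      .data$variant_class == "missense" ~ "missense",
      TRUE ~ "other"
    ))
  if (!any(sites$prefilter_pass)) {
    warn("no sites survive the reliability pre-filter")
  }
  null <- build_permutation_null(somatic, exclude_genes = exclude_genes,
                                 cap = cfg$null_cap, seed = cfg$seed)
  idx <- which(sites$prefilter_pass)
  p_fisher <- p_perm <- p_combined <- rep(NA_real_, nrow(sites))
  if (length(idx) > 0) {
    p_fisher[idx] <- site_fisher_test(sites$n_ref[idx], sites$n_alt[idx],
                                      sites$t_ref[idx], sites$t_alt[idx])
    stat <- if (cfg$permutation_stat == "vaf") {
      sites$vaf_tumour[idx]
    } else {
      sites$vaf_tumour[idx] / pmax(sites$vaf_normal[idx], .Machine$double.eps) * 0.5
    }
    p_perm[idx] <- site_permutation_test(stat, null)
    p_combined[idx] <- combine_pvalues(p_fisher[idx], p_perm[idx],
                                       method = cfg$combine_method)
  }
  out <- sites %>%
    mutate(p_fisher = p_fisher, p_perm = p_perm, p_combined = p_combined,
           q = NA_real_)
  for (fam in c("truncation", "missense")) {
    sel <- which(out$family == fam & out$prefilter_pass)
    if (length(sel) > 0) out$q[sel] <- bh_fdr(out$p_combined[sel])
  }
  thr <- c(truncation = cfg$site_fdr_truncation,
           missense = cfg$site_fdr_missense, other = NA_real_)
  out %>%
    mutate(significant = !is.na(.data$q) & .data$q <= unname(thr[.data$family]),
           prioritized = !is.na(.data$q) & .data$q <= cfg$prioritize_fdr)
}

#' Gene-level LOH test for truncations
#'
#' Pooled two-sample one-tailed t-test comparing the tumour VAFs of a
#' candidate gene's sites against the background of all other tested sites;
#' degrees of freedom are 2 less than the total number of sites.
#'
#' @param gene_vafs Tumour VAFs at the gene's sites (length >= 2).
#' @param background_vafs Tumour VAFs of the background sites (length >= 2).
#' @param gene Optional gene label carried into the result.
#' @return An object of class `"loh_gene_test"` (mode `"truncation_ttest"`)
#'   with fields `statistic`, `df`, `p`, group summaries, and `included`.
#' @export
gene_truncation_loh <- function(gene_vafs, background_vafs, gene = NA_character_) {
  n1 <- length(gene_vafs); n2 <- length(background_vafs)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 sites")
  v1 <- stats::var(gene_vafs); v2 <- stats::var(background_vafs)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled variance")
  tstat <- (mean(gene_vafs) - mean(background_vafs)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  structure(list(gene = gene, mode = "truncation_ttest",
                 statistic = tstat, df = df,
                 p = pt(tstat, df, lower.tail = FALSE),
                 n_gene = n1, n_background = n2,
                 mean_gene = mean(gene_vafs),
                 mean_background = mean(background_vafs),
                 included = TRUE, exclusion_reason = NA_character_),
            class = "loh_gene_test")
}

#' Gene-level LOH test for missense variants
#'
#' Compares the fraction of a gene's missense sites showing significant LOH
#' (at the strict site-level FDR) with the corresponding background fraction,
#' by a one-tailed Fisher exact test on the 2x2 table of LOH status versus
#' cohort. To limit noise a gene is only tested if its significant fraction
#' exceeds the background fraction by at least `min_diff` and it has at least
#' `min_events` significant sites; otherwise the gene is excluded with a
#' reason (exclusion is a result, not an error).
#'
#' @param gene_sig,gene_total Significant and total missense site counts for
#'   the gene.
#' @param bg_sig,bg_total Same for the background population.
#' @param min_diff Minimum fractional excess (default 0.02, two percentage
#'   points).
#' @param min_events Minimum significant events in the gene (default 3).
#' @param gene Optional gene label.
#' @return An object of class `"loh_gene_test"` (mode `"missense_fraction"`).
#' @export
gene_missense_loh <- function(gene_sig, gene_total, bg_sig, bg_total,
                              min_diff = 0.02, min_events = 3L,
                              gene = NA_character_) {
  if (gene_total <= 0 || bg_total <= 0) abort("totals must be > 0")
  f_gene <- gene_sig / gene_total
  f_bg <- bg_sig / bg_total
  reason <- NULL
  if (gene_sig < min_events) {
    reason <- sprintf("fewer than %d significant events", min_events)
  } else if (f_gene - f_bg < min_diff) {
    reason <- sprintf("fractional excess below %.0f percentage points",
                      100 * min_diff)
  }
  p <- if (is.null(reason)) {
    # upper tail for the gene's significant count with margins fixed
    phyper(gene_sig - 1, gene_sig + bg_sig,
           (gene_total - gene_sig) + (bg_total - bg_sig),
           gene_total, lower.tail = FALSE)
  } else NA_real_
  structure(list(gene = gene, mode = "missense_fraction",
                 statistic = f_gene - f_bg, df = NA_integer_, p = p,
                 gene_sig = gene_sig, gene_total = gene_total,
                 bg_sig = bg_sig, bg_total = bg_total,
                 included = is.null(reason),
                 exclusion_reason = reason %||% NA_character_),
            class = "loh_gene_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-level LOH testing over a site-result table
#'
#' Convenience wrapper applying [gene_truncation_loh()] (truncation mode, on
#' tumour VAFs) or [gene_missense_loh()] (missense mode, on significant-site
#' fractions at the strict FDR) to every candidate gene against the pooled
#' background of the remaining genes, with BH correction across included
#' genes.
#'
#' @param site_results Output of [run_site_loh()].
#' @param genes Candidate genes (default: all genes in the relevant family).
#' @param mode `"truncation"` or `"missense"`.
#' @param ... Passed to the per-gene test.
#' @return Tibble with one row per candidate gene: `gene`, `mode`,
#'   `statistic`, `df`, `p`, `q`, `included`, `exclusion_reason`.
#' @export
run_gene_loh <- function(site_results, genes = NULL,
                         mode = c("truncation", "missense"), ...) {
  mode <- match.arg(mode)
  fam_label <- if (mode == "truncation") "truncation" else "missense"
  fam <- site_results %>%
    filter(.data$family == .env$fam_label, .data$prefilter_pass)
  if (is.null(genes)) genes <- unique(fam$gene)
  fits <- purrr::map(genes, function(g) {
    gv <- fam %>% filter(.data$gene == g)
    bg <- fam %>% filter(.data$gene != g)
    if (mode == "truncation") {
      if (nrow(gv) < 2 || nrow(bg) < 2) {
        return(structure(list(gene = g, mode = "truncation_ttest",
                              statistic = NA_real_, df = NA_integer_,
                              p = NA_real_, included = FALSE,
                              exclusion_reason = "fewer than 2 sites in a group"),
                         class = "loh_gene_test"))
      }
      gene_truncation_loh(gv$vaf_tumour, bg$vaf_tumour, gene = g)
    } else {
      gene_missense_loh(sum(gv$significant), nrow(gv),
                        sum(bg$significant), nrow(bg), gene = g, ...)
    }
  })
  out <- purrr::map_dfr(fits, function(f) {
    tibble(gene = f$gene, mode = f$mode, statistic = f$statistic,
           df = as.integer(f$df %||% NA_integer_), p = f$p,
           included = f$included, exclusion_reason = f$exclusion_reason)
  })
  out$q <- NA_real_
  inc <- which(out$included & !is.na(out$p))
  if (length(inc) > 0) out$q[inc] <- bh_fdr(out$p[inc])
  out %>% select("gene", "mode", "statistic", "df", "p", "q",
                 "included", "exclusion_reason")
}
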