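test_that("the Wilson interval matches the closed form and the score-test oracle", {
  expect_equal(wilson_interval(0, 10, 0.90)$low, 0)
  got <- wilson_interval(50, 100, 0.95)
  expect_equal(c(got$low, got$high), c(0.4038, 0.5962), tolerance = 1e-4)
  # prop.test without continuity correction inverts the same score statistic
  for (s in c(0, 3, 50, 97)) {
    ref <- stats::prop.test(s, 100, correct = FALSE, conf.level = 0.9)$conf.int
    got <- wilson_interval(s, 100, 0.90)
    expect_equal(c(got$low, got$high), as.numeric(ref), tolerance = 1e-10)
  }
  # interval always contains the point estimate
  set.seed(5)
  s <- rbinom(50, 30, runif(50)); n <- rep(30, 50)
  ci <- wilson_interval(s, n, 0.9)
  expect_true(all(ci$low <= ci$estimate & ci$estimate <= ci$high))
  expect_error(wilson_interval(1, 0), "trials")
})

test_that("reliability pre-filtering keeps well-measured VAFs and is monotone in depth", {
  # closed-form halfwidths at VAF 0.5: depth 5 ~ 0.296 (removed),
  # depth 200 ~ 0.058 (retained) at 90% confidence
  hw <- function(n) {
    ci <- wilson_interval(n / 2, n, 0.90)
    max(ci$high - ci$estimate, ci$estimate - ci$low)
  }
  expect_equal(hw(5), 0.296, tolerance = 5e-3)
  expect_equal(hw(200), 0.058, tolerance = 5e-3)
  mk <- function(depth) tibble::tibble(n_ref = depth / 2, n_alt = depth / 2,
                                       t_ref = depth / 2, t_alt = depth / 2)
  expect_false(prefilter_by_confidence(mk(10))$prefilter_pass)
  expect_false(prefilter_by_confidence(mk(40))$prefilter_pass)
  expect_true(prefilter_by_confidence(mk(100))$prefilter_pass)
  expect_true(prefilter_by_confidence(mk(400))$prefilter_pass)
  # any site removed at depth d is removed at every smaller depth, same VAF
  depths <- seq(10, 400, by = 10)
  pass <- vapply(depths, function(d) prefilter_by_confidence(mk(d))$prefilter_pass,
                 logical(1))
  expect_true(all(diff(pass) >= 0))
  # tumour-only scope is laxer than both-sample scope
  site <- tibble::tibble(n_ref = 5, n_alt = 5, t_ref = 200, t_alt = 200)
  expect_false(prefilter_by_confidence(site)$prefilter_pass)
  expect_true(prefilter_by_confidence(
    site, loh_config(prefilter_scope = "tumour"))$prefilter_pass)
})

test_that("the site Fisher test is the upper hypergeometric tail toward tumour enrichment", {
  expect_gt(site_fisher_test(50, 50, 50, 50), 0.5)
  expect_equal(site_fisher_test(50, 50, 20, 80),
               hyper_upper_oracle(80, r1 = 130, r2 = 70, c1 = 100))
  expect_gt(site_fisher_test(50, 50, 80, 20), 0.99)
  expect_equal(site_fisher_test(50, 50, 20, 80),
               stats::fisher.test(matrix(c(80, 50, 20, 50), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(site_fisher_test(0, 0, 0, 0), "all-zero")
})

test_that("the permutation null is the cross-product of background counts", {
  one <- tibble::tibble(t_ref = 50, t_alt = 50)
  expect_equal(build_permutation_null(one), 0.5)
  bg <- tibble::tibble(t_ref = c(90, 50), t_alt = c(10, 50))
  expect_equal(build_permutation_null(bg),
               sort(c(10 / 100, 10 / 60, 50 / 140, 50 / 100)))
  # cap: exact size, reproducible under seed, sorted
  big <- tibble::tibble(t_ref = rpois(2000, 60) + 1, t_alt = rpois(2000, 30) + 1)
  n1 <- build_permutation_null(big, cap = 5000, seed = 9)
  n2 <- build_permutation_null(big, cap = 5000, seed = 9)
  expect_length(n1, 5000)
  expect_identical(n1, n2)
  expect_true(!is.unsorted(n1))
  # candidate genes are excluded from the background
  bg$gene <- c("BRCA1", "OTHER")
  expect_equal(build_permutation_null(bg, exclude_genes = "BRCA1"), 0.5)
  expect_error(build_permutation_null(bg, exclude_genes = c("BRCA1", "OTHER")),
               "empty")
})

test_that("empirical p-values use the add-one correction", {
  null <- seq(0.01, 0.5, length.out = 999)
  expect_equal(site_permutation_test(0.9, null), 1 / 1000)
  expect_equal(site_permutation_test(0.001, null), 1)
  expect_equal(site_permutation_test(stats::median(null), null),
               (500 + 1) / 1000)
  expect_error(site_permutation_test(0.5, numeric(0)), "empty")
})

test_that("Fisher's combination has the 4-df closed form", {
  expect_equal(combine_pvalues(1, 1), 1)
  expect_equal(combine_pvalues(0.5, 0.5), 0.5966, tolerance = 1e-4)
  grid <- expand.grid(p1 = c(0.001, 0.05, 0.3, 0.9, 1),
                      p2 = c(0.001, 0.05, 0.3, 0.9, 1))
  X <- -2 * (log(grid$p1) + log(grid$p2))
  expect_equal(combine_pvalues(grid$p1, grid$p2),
               exp(-X / 2) * (1 + X / 2), tolerance = 1e-12)
  # a second small p strengthens the combination; a large one dilutes it
  # (combined < p1 iff p2 (1 - ln(p1 p2)) < 1, e.g. p2 = 0.1 at p1 = 0.05)
  expect_lt(combine_pvalues(0.05, 0.1), 0.05)
  expect_gt(combine_pvalues(0.05, 0.9), 0.05)
  expect_warning(p0 <- combine_pvalues(0, 0.5), "clamped")
  expect_lt(p0, 1e-300)
  # Stouffer option
  expect_equal(combine_pvalues(0.5, 0.5, method = "stouffer"), 0.5)
})

test_that("the gene-level truncation test is a pooled one-tailed t-test", {
  g <- c(0.9, 0.95, 0.85)
  bg <- c(0.48, 0.52, 0.50, 0.46, 0.55, 0.49, 0.51, 0.53)
  fit <- gene_truncation_loh(g, bg, gene = "BRCA1")
  ref <- stats::t.test(g, bg, var.equal = TRUE, alternative = "greater")
  expect_equal(fit$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fit$p, ref$p.value, tolerance = 1e-12)
  expect_equal(fit$df, 3 + 8 - 2)
  expect_equal(gene_truncation_loh(rnorm(4), rnorm(10))$df, 12)
  # identical group means -> t = 0, p = 0.5
  same <- gene_truncation_loh(c(0.4, 0.6), c(0.3, 0.5, 0.7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)
  expect_error(gene_truncation_loh(0.5, c(0.4, 0.6)), "at least 2")
  expect_error(gene_truncation_loh(c(0.5, 0.5), c(0.5, 0.5)), "variance")
  td <- tidy(fit)
  expect_equal(td$p.value, fit$p)
})

test_that("the missense gene test applies the inclusion criteria before Fisher", {
  ex <- gene_missense_loh(2, 10, 10, 1000)
  expect_false(ex$included)
  expect_match(ex$exclusion_reason, "fewer than 3")
  inc <- gene_missense_loh(3, 10, 10, 1000)
  expect_true(inc$included)
  expect_equal(inc$p, hyper_upper_oracle(3, r1 = 13, r2 = 997, c1 = 10))
  eq <- gene_missense_loh(3, 100, 30, 1000)
  expect_false(eq$included)
  expect_match(eq$exclusion_reason, "percentage points")
})

test_that("site pipeline separates planted complete-LOH sites from neutral ones", {
  n_loh <- 40; n_neutral <- 160
  sites <- dplyr::bind_rows(
    simulate_loh_site(n_loh, rho = 1, mode = "deletion", depth_mean = 100,
                      seed = 31),
    simulate_loh_site(n_neutral, rho = 1, mode = "none", depth_mean = 100,
                      seed = 32)
  ) %>%
    mutate(sample_id = sprintf("s%03d", dplyr::row_number()),
           gene = "CAND", variant_class = "missense",
           truth = rep(c(TRUE, FALSE), c(n_loh, n_neutral)))
  somatic <- simulate_loh_site(500, rho = 1, mode = "none", depth_mean = 100,
                               seed = 33) %>%
    mutate(gene = "BG", variant_class = "missense")
  res <- run_site_loh(sites, somatic, loh_config(seed = 34),
                      exclude_genes = "CAND")
  called <- res %>% filter(significant)
  expect_gt(nrow(called), 0.8 * n_loh)
  expect_gt(mean(called$truth), 0.95)
  # single input site: q equals the combined p
  single <- run_site_loh(sites[1, ], somatic, loh_config(seed = 35),
                         exclude_genes = "CAND")
  expect_equal(single$q, single$p_combined)
})

test_that("under the diploid-neutral null the combined p is stochastically >= uniform", {
  n <- 4000
  sites <- simulate_loh_site(n, rho = 0.8, mode = "none", depth_mean = 110,
                             seed = 41) %>%
    mutate(sample_id = sprintf("s%04d", dplyr::row_number()),
           gene = "CAND", variant_class = "missense")
  # coherent null: background drawn from the same binomial(depth, 0.5)
  somatic <- simulate_loh_site(300, rho = 0.8, mode = "none", depth_mean = 110,
                               seed = 42) %>%
    mutate(gene = "BG", variant_class = "missense")
  res <- run_site_loh(sites, somatic, loh_config(seed = 43),
                      exclude_genes = "CAND") %>%
    filter(prefilter_pass)
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    mc_se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lte(mean(res$p_fisher <= alpha), alpha + 3 * mc_se)
    expect_lte(mean(res$p_combined <= alpha), alpha + 3 * mc_se)
  }
})

test_that("combining both aspects beats either alone on diluted planted LOH", {
  n <- 300
  sites <- simulate_loh_site(n, rho = 0.6, mode = "deletion", depth_mean = 100,
                             seed = 51) %>%
    mutate(sample_id = sprintf("s%03d", dplyr::row_number()),
           gene = "CAND", variant_class = "missense")
  somatic <- simulate_loh_site(400, rho = 0.6, mode = "none", depth_mean = 100,
                               seed = 52) %>%
    mutate(gene = "BG", variant_class = "missense")
  res <- run_site_loh(sites, somatic, loh_config(seed = 53),
                      exclude_genes = "CAND") %>%
    filter(prefilter_pass)
  alpha <- 1e-3
  power_combined <- mean(res$p_combined <= alpha)
  expect_gte(power_combined, mean(res$p_fisher <= alpha))
  expect_gte(power_combined, mean(res$p_perm <= alpha))
})

test_that("planted-LOH recovery increases monotonically with purity", {
  frac_called <- vapply(c(0.6, 0.8, 1.0), function(rho) {
    sites <- simulate_loh_site(100, rho = rho, mode = "deletion",
                               depth_mean = 100, seed = 61) %>%
      mutate(sample_id = sprintf("s%03d", dplyr::row_number()),
             gene = "CAND", variant_class = "missense")
    somatic <- simulate_loh_site(300, rho = rho, mode = "none",
                                 depth_mean = 100, seed = 62) %>%
      mutate(gene = "BG", variant_class = "missense")
    res <- run_site_loh(sites, somatic, loh_config(seed = 63),
                        exclude_genes = "CAND")
    mean(res$significant)
  }, numeric(1))
  expect_true(all(diff(frac_called) >= 0))
})

test_that("VAF ratio hits the textbook endpoints", {
  expect_equal(vaf_ratio(50, 50, 0, 50), 2)    # complete LOH in a pure tumour
  expect_equal(vaf_ratio(50, 50, 25, 25), 1)   # no LOH
  expect_equal(vaf_ratio(50, 50, 75, 25), 0.5)
  expect_error(vaf_ratio(100, 0, 50, 50), "undefined")
})

test_that("run_gene_loh screens candidates against the pooled background", {
  loh <- simulate_loh_site(8, rho = 1, mode = "deletion", depth_mean = 150,
                           seed = 71) %>%
    mutate(gene = "HIT", sample_id = sprintf("a%d", 1:8))
  neut <- simulate_loh_site(60, rho = 1, mode = "none", depth_mean = 150,
                            seed = 72) %>%
    mutate(gene = sample(c("N1", "N2", "N3"), 60, replace = TRUE),
           sample_id = sprintf("b%d", 1:60))
  sites <- dplyr::bind_rows(loh, neut) %>%
    mutate(variant_class = "nonsense")
  somatic <- simulate_loh_site(200, rho = 1, mode = "none", depth_mean = 150,
                               seed = 73) %>%
    mutate(gene = "BG", variant_class = "missense")
  sr <- run_site_loh(sites, somatic, loh_config(seed = 74),
                     exclude_genes = c("HIT", "N1", "N2", "N3"))
  gr <- run_gene_loh(sr, mode = "truncation")
  expect_equal(gr$gene[which.min(gr$q)], "HIT")
  expect_lt(gr$q[gr$gene == "HIT"], 0.05)
  # degrees of freedom bookkeeping
  expect_equal(gr$df[gr$gene == "HIT"],
               sum(sr$prefilter_pass & sr$family == "truncation") - 2L)
})
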