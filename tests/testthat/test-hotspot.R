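test_that("the per-event Bernoulli probability is the product of the two conditions", {
  expect_equal(bernoulli_prob(100, 100, 5, 0), 1)      # W = L, D_n = 0
  expect_equal(bernoulli_prob(100, 1000, 5, 45), 0.01)
  expect_equal(bernoulli_prob(30, 1000, 0, 10), 0)
  expect_error(bernoulli_prob(2000, 1000, 5, 5), "window")
  expect_error(bernoulli_prob(10, 100, 0, 0), "event")
})

test_that("the window tail probability is the binomial upper tail", {
  expect_equal(window_tail_prob(0, 10, 0.05), 1)
  expect_equal(window_tail_prob(10, 10, 0.05), 0.05^10)
  expect_equal(window_tail_prob(3, 10, 0.05), 0.011504, tolerance = 1e-4)
  # term-by-term oracle
  direct <- sum(choose(10, 3:10) * 0.05^(3:10) * 0.95^(10 - (3:10)))
  expect_equal(window_tail_prob(3, 10, 0.05), direct, tolerance = 1e-12)
  # monotone non-increasing in k; non-decreasing in p_b
  expect_true(all(diff(window_tail_prob(0:10, 10, 0.05)) <= 0))
  expect_true(all(diff(window_tail_prob(3, 10, c(0.01, 0.05, 0.2, 0.5))) >= 0))
  expect_error(window_tail_prob(3, 10, 1.5), "p_b")
})

test_that("the tail probability matches a Monte-Carlo null on a small protein", {
  # fixed window [20, 39] of a 60-aa protein, 12 events, 4 significant overall
  L <- 60; W <- 20; D_s <- 4; D_n <- 8; n <- D_s + D_n
  p_b <- bernoulli_prob(W, L, D_s, D_n)
  for (k in c(1, 2, 3)) {
    analytic <- window_tail_prob(k, n, p_b)
    reps <- 30000
    set.seed(100 + k)
    hits <- vapply(seq_len(reps), function(i) {
      pos <- sample.int(L, n, replace = TRUE)
      sig <- runif(n) < D_s / n      # iid significance under the null model
      sum(sig & pos >= 20 & pos <= 39) >= k
    }, logical(1))
    mc <- mean(hits)
    se <- sqrt(mc * (1 - mc) / reps)
    expect_lt(abs(analytic - mc), 3 * se + 1e-6)
  }
})

test_that("scan assigns each significant event its minimal-tail window", {
  cfg <- hotspot_config(window_min = 5, window_max = 20)
  # no significant events -> empty candidate list
  ev0 <- tibble::tibble(position = c(10L, 40L), significant = FALSE)
  expect_equal(nrow(scan_protein(ev0, 100, cfg)), 0)
  expect_error(
    scan_protein(tibble::tibble(position = 500L, significant = TRUE), 100, cfg),
    "outside"
  )

  # single significant event, D_n = 0: P_S = W/L minimised at window_min
  ev1 <- tibble::tibble(position = 50L, significant = TRUE)
  got1 <- scan_protein(ev1, 100, cfg)
  expect_equal(got1$W, 5L)
  expect_equal(got1$P_S, 5 / 100)
  expect_equal(got1$k, 1L)

  # clustered events: the chosen window matches an exhaustive reduced-range oracle
  set.seed(7)
  ev <- tibble::tibble(
    position = as.integer(c(30:34, sample(1:200, 20))),
    significant = rep(c(TRUE, FALSE), c(5, 20))
  )
  got <- scan_protein(ev, 200, cfg)
  oracle_best <- Inf
  for (W in 5:20) {
    pb <- bernoulli_prob(W, 200, 5, 20)
    for (s in 1:(200 - W + 1)) {
      k <- sum(ev$position[ev$significant] >= s &
                 ev$position[ev$significant] <= s + W - 1)
      oracle_best <- min(oracle_best, window_tail_prob(k, 25, pb))
    }
  }
  expect_equal(min(got$P_S), oracle_best, tolerance = 1e-12)
  best <- got[which.min(got$P_S), ]
  expect_lte(best$start, 30)
  expect_gte(best$end, 34)

  # determinism / caching invariance: identical input, identical output
  expect_identical(scan_protein(ev, 200, cfg), scan_protein(ev, 200, cfg))
})

test_that("overlapping candidate regions merge to their union with the best tail", {
  a <- tibble::tibble(start = 100L, end = 150L, P_S = 1e-4, W = 51L)
  b <- tibble::tibble(start = 140L, end = 190L, P_S = 1e-3, W = 51L)
  c2 <- tibble::tibble(start = 300L, end = 320L, P_S = 0.5, W = 21L)
  merged <- merge_regions(dplyr::bind_rows(a, b, c2))
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start[1], 100L)
  expect_equal(merged$end[1], 190L)
  expect_equal(merged$P_S[1], 1e-4)
  expect_equal(merged$start[2], 300L)       # disjoint region unchanged

  # chain of pairwise-overlapping regions collapses to one span
  chain <- tibble::tibble(start = c(1L, 40L, 80L, 120L),
                          end = c(50L, 90L, 130L, 170L),
                          P_S = c(0.2, 0.01, 0.3, 0.4))
  got <- merge_regions(chain)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(1L, 170L))
  expect_equal(got$P_S, 0.01)
})

test_that("the full scan recovers a planted cluster inside its domain", {
  sim <- simulate_hotspot_protein(L = 1000, interval = c(400, 449),
                                  n_sig = 8, n_nonsig = 40, seed = 12)
  ann <- tibble::tibble(
    protein = "P1", length = 1000L,
    domains = list(tibble::tibble(domain = "KINASE", start = 380L, end = 470L))
  )
  res <- run_hotspot_scan(sim$events %>% mutate(protein = "P1"), ann)
  expect_gt(nrow(res), 0)
  top <- res[which.min(res$q), ]
  expect_true(top$start <= 449 && top$end >= 400)   # overlaps the planted interval
  expect_match(top$overlapping_domains, "KINASE")
  expect_lt(top$q, 0.05)

  # protein shorter than window_min is scanned with W clipped to L
  short <- tibble::tibble(protein = "S", position = c(5L, 9L),
                          significant = c(TRUE, FALSE))
  ann_s <- tibble::tibble(protein = "S", length = 20L,
                          domains = list(tibble::tibble(domain = character(),
                                                        start = integer(),
                                                        end = integer())))
  res_s <- run_hotspot_scan(short, ann_s)
  expect_equal(nrow(res_s), 1)
  expect_lte(res_s$W, 20L)
  expect_error(run_hotspot_scan(short %>% mutate(protein = "X"), ann_s),
               "lacking length")
})

test_that("null placement keeps the hotspot false-call rate at or below the FDR", {
  n_prot <- 60
  events <- purrr::map_dfr(seq_len(n_prot), function(i) {
    simulate_hotspot_protein(L = 500, n_sig = 3, n_nonsig = 12,
                             null = TRUE, seed = 500 + i)$events %>%
      mutate(protein = sprintf("P%02d", i))
  })
  ann <- tibble::tibble(
    protein = sprintf("P%02d", seq_len(n_prot)), length = 500L,
    domains = purrr::map(seq_len(n_prot),
                         ~ tibble::tibble(domain = character(),
                                          start = integer(), end = integer()))
  )
  res <- run_hotspot_scan(events, ann)
  frac <- length(unique(res$protein[res$significant])) / n_prot
  mc_se <- sqrt(0.05 * 0.95 / n_prot)
  expect_lte(frac, 0.05 + 3 * mc_se)
})
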