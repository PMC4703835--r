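suppressMessages(library(dplyr))

# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: hypergeometric tails are accumulated from lchoose
# terms, BH from the literal step-up definition, rank-sum p from explicit
# enumeration of label assignments.

# One-tailed upper hypergeometric p for cell x11 of a 2x2 table with rows
# (r1, r2) and first-column margin c1: P(X >= x11).
hyper_upper_oracle <- function(x11, r1, r2, c1) {
  N <- r1 + r2
  js <- max(x11, c1 - r2):min(r1, c1)
  sum(exp(lchoose(r1, js) + lchoose(r2, c1 - js) - lchoose(N, c1)))
}

# Literal step-up definition: q_i = min over j with p_(j) >= p_(i) of m p_(j)/j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact one-tailed rank-sum p (x > y) by enumerating all label assignments.
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  Ws <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  mean(Ws >= W_obs)
}

# Small germline table builder (valid by construction).
make_germline_tbl <- function(n = 3) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    gene = "BRCA1", chrom = "17", pos = 41222944L + seq_len(n),
    ref = "A", alt = "G",
    variant_class = "Missense_Mutation",
    protein_pos = 1700L + seq_len(n),
    maf_1000g = 0, maf_esp = 0,
    n_ref = 50L, n_alt = 50L, t_ref = 20L, t_alt = 80L
  )
}

write_tsv_text <- function(df, path) {
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  path
}
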