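#' Hotspot scan configuration
#'
#' @param window_min,window_max Scan window sizes in amino acids (defaults 30
#'   and 200; windows wider than the protein are clipped to its length).
#' @param step Slide step in amino acids (default 1).
#' @param hotspot_fdr Significance threshold on the BH q of merged regions
#'   (default 0.05).
#' @return A list of class `"hotspot_config"`.
#' @export
hotspot_config <- function(window_min = 30L, window_max = 200L, step = 1L,
                           hotspot_fdr = 0.05) {
  stopifnot(window_min >= 1, window_min <= window_max, step >= 1)
  structure(list(window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 step = as.integer(step),
                 hotspot_fdr = hotspot_fdr),
            class = "hotspot_config")
}

#' Per-event Bernoulli probability of a relevant observation
#'
#' An observation is relevant if it is statistically significant (probability
#' `D_s / (D_s + D_n)` under the null) and falls inside the current window
#' (probability `W / L` under uniform placement); the two conditions are
#' independent under the null, so the Bernoulli probability is their product.
#'
#' @param W Window size (amino acids), `1 <= W <= L`.
#' @param L Protein length (amino acids).
#' @param D_s,D_n Total significant and non-significant event counts for the
#'   protein (`D_s + D_n >= 1`).
#' @return `p_b = (W / L) * D_s / (D_s + D_n)`.
#' @export
bernoulli_prob <- function(W, L, D_s, D_n) {
  if (any(W > L) || any(W < 1)) abort("window size must lie in [1, L]")
  if (any(D_s + D_n < 1)) abort("at least one event is required")
  (W / L) * D_s / (D_s + D_n)
}

#' Binomial tail probability of a window's significant-event count
#'
#' Events are independently and identically distributed under the null, so
#' the count of relevant observations among the protein's `n = D_s + D_n`
#' events is binomial with success probability `p_b`; the test probability of
#' `k` observations is the upper tail at `k`.
#'
#' @param k Observed significant events in the window, `0 <= k <= n_events`.
#' @param n_events Total events for the protein.
#' @param p_b Per-event probability from [bernoulli_prob()].
#' @return `P_S = sum_{j >= k} C(n, j) p_b^j (1 - p_b)^(n - j)`.
#' @export
window_tail_prob <- function(k, n_events, p_b) {
  if (any(p_b < 0 | p_b > 1)) abort("p_b must lie in [0, 1]")
  if (any(k < 0 | k > n_events)) abort("k must lie in [0, n_events]")
  pbinom(k - 1, n_events, p_b, lower.tail = FALSE)
}

#' Scan one protein for candidate LOH hotspots
#'
#' Slides windows of every size in `[window_min, window_max]` (clipped to the
#' protein length) across the protein with the configured step, computing for
#' each placement the number `k` of significant events inside and its tail
#' probability `P_S`. Each significant event is then assigned the window
#' (size and placement) containing it with the smallest `P_S`; ties resolve
#' to the smallest window, then the smallest start. `p_b` is constant for a
#' protein at a given window size, so it is computed once per size.
#'
#' @param events Tibble with `position` (1-based amino acid) and `significant`
#'   (logical) columns.
#' @param L Protein length.
#' @param cfg A [hotspot_config()].
#' @return Tibble of candidate regions (one per significant event, possibly
#'   duplicated windows): `start`, `end`, `W`, `k`, `D_s`, `D_n`, `p_b`,
#'   `P_S`.
#' @export
scan_protein <- function(events, L, cfg = hotspot_config()) {
  if (nrow(events) > 0 && any(events$position < 1 | events$position > L)) {
    abort("event position outside [1, L]")
  }
  empty <- tibble(start = integer(), end = integer(), W = integer(),
                  k = integer(), D_s = integer(), D_n = integer(),
                  p_b = numeric(), P_S = numeric())
  D_s <- sum(events$significant)
  D_n <- sum(!events$significant)
  if (D_s == 0) return(empty)
  n <- D_s + D_n
  sig_pos <- events$position[events$significant]
  # prefix counts of significant events over residues 1..L
  cnt <- tabulate(sig_pos, nbins = L)
  csum <- c(0L, cumsum(cnt))
  sizes <- seq(min(cfg$window_min, L), min(cfg$window_max, L))
  best <- tibble(pos = sort(unique(sig_pos)), P_S = Inf,
                 W = NA_integer_, start = NA_integer_,
                 k = NA_integer_, p_b = NA_real_)
  for (W in sizes) {
    p_b <- bernoulli_prob(W, L, D_s, D_n)
    starts <- seq(1L, L - W + 1L, by = cfg$step)
    ks <- csum[starts + W] - csum[starts]
    PS <- pbinom(ks - 1, n, p_b, lower.tail = FALSE)
    for (e in seq_len(nrow(best))) {
      p <- best$pos[e]
      # windows [s, s+W-1] containing p: s in [p-W+1, p]; starts[i] = 1+(i-1)*step
      i_lo <- max(1L, ceiling((p - W + 1 - 1) / cfg$step) + 1L)
      i_hi <- min(length(starts), (p - 1L) %/% cfg$step + 1L)
      if (i_lo > i_hi) next
      idx <- i_lo:i_hi
      i_min <- idx[which.min(PS[idx])]     # which.min takes the first: smallest start
      if (PS[i_min] < best$P_S[e]) {       # strict <: smaller W wins ties
        best$P_S[e] <- PS[i_min]
        best$W[e] <- W
        best$start[e] <- starts[i_min]
        best$k[e] <- ks[i_min]
        best$p_b[e] <- p_b
      }
    }
  }
  best %>%
    mutate(end = .data$start + .data$W - 1L, D_s = .env$D_s, D_n = .env$D_n) %>%
    select("start", "end", "W", "k", "D_s", "D_n", "p_b", "P_S") %>%
    distinct() %>%
    arrange(.data$start, .data$end)
}

#' Merge overlapping candidate regions
#'
#' Overlapping intervals on the same protein are unioned; the merged region
#' keeps the statistics of its smallest-`P_S` constituent. Output is sorted by
#' protein then start.
#'
#' @param candidates Tibble of candidate regions with at least `start`, `end`,
#'   `P_S` (and optionally `protein` plus the scan statistics).
#' @return Tibble of merged regions, same columns.
#' @export
merge_regions <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  if (!"protein" %in% names(candidates)) {
    candidates <- candidates %>% mutate(protein = "")
    drop_protein <- TRUE
  } else drop_protein <- FALSE
  merged <- candidates %>%
    arrange(.data$protein, .data$start, .data$end) %>%
    group_by(.data$protein) %>%
    mutate(.grp = cumsum(.data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                                  default = -Inf))) %>%
    group_by(.data$protein, .data$.grp) %>%
    summarise(
      new_start = min(.data$start),
      new_end = max(.data$end),
      best = which.min(.data$P_S),
      across(dplyr::any_of(c("W", "k", "D_s", "D_n", "p_b", "P_S")),
             ~ .x[which.min(P_S)]),
      .groups = "drop"
    ) %>%
    mutate(start = .data$new_start, end = .data$new_end) %>%
    select(-".grp", -"new_start", -"new_end", -"best") %>%
    arrange(.data$protein, .data$start)
  cols <- intersect(c("protein", "start", "end", "W", "k", "D_s", "D_n",
                      "p_b", "P_S"), names(merged))
  merged <- merged %>% select(dplyr::all_of(cols))
  if (drop_protein) merged <- merged %>% select(-"protein")
  merged
}

#' Genome-wide hotspot scan with FDR
#'
#' Runs [scan_protein()] for every protein with events, merges overlapping
#' candidate regions per protein, applies Benjamini-Hochberg correction
#' across the full list of merged regions, and annotates overlapping domains.
#'
#' @param events Tibble with `protein`, `position`, `significant` columns
#'   (e.g., missense rows of a [run_site_loh()] result keyed by
#'   `protein_pos`).
#' @param annotations Nested domain-annotation tibble from
#'   [read_domain_annotations()] (columns `protein`, `length`, `domains`);
#'   every scanned protein needs a length.
#' @param cfg A [hotspot_config()].
#' @return Tibble of hotspot regions: `protein`, `start`, `end`, `W`, `k`,
#'   `D_s`, `D_n`, `p_b`, `P_S`, `q`, `significant`, `overlapping_domains`.
#' @export
run_hotspot_scan <- function(events, annotations, cfg = hotspot_config()) {
  proteins <- unique(events$protein)
  missing_len <- setdiff(proteins, annotations$protein)
  if (length(missing_len) > 0) {
    abort(paste0("Protein(s) lacking length annotation: ",
                 paste(utils::head(missing_len, 5), collapse = ", ")))
  }
  cand <- purrr::map_dfr(proteins, function(pr) {
    L <- annotations$length[annotations$protein == pr][1]
    scan_protein(events %>% filter(.data$protein == pr), L, cfg) %>%
      mutate(protein = pr)
  })
  if (nrow(cand) == 0) {
    return(tibble(protein = character(), start = integer(), end = integer(),
                  W = integer(), k = integer(), D_s = integer(),
                  D_n = integer(), p_b = numeric(), P_S = numeric(),
                  q = numeric(), significant = logical(),
                  overlapping_domains = character()))
  }
  merged <- merge_regions(cand) %>%
    mutate(q = bh_fdr(.data$P_S),
           significant = .data$q <= cfg$hotspot_fdr)
  doms <- annotations %>% tidyr::unnest("domains")
  overlaps <- purrr::map_chr(seq_len(nrow(merged)), function(i) {
    d <- doms %>%
      filter(.data$protein == merged$protein[i],
             .data$start <= merged$end[i],
             .data$end >= merged$start[i])
    if (nrow(d) == 0) "" else paste(d$domain, collapse = ",")
  })
  merged %>% mutate(overlapping_domains = overlaps) %>%
    select("protein", "start", "end", "W", "k", "D_s", "D_n",
           "p_b", "P_S", "q", "significant", "overlapping_domains") %>%
    arrange(.data$protein, .data$start)
}
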