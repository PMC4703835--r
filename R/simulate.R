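#' Simulation configuration
#'
#' Defaults encode the cohort conditions the package's statistical tests are
#' designed for: a case/control exome cohort of 3,000 cases and 1,000
#' controls over 200 genes, rare truncations at a baseline carrier frequency
#' of 0.1% with planted susceptibility genes at carrier relative risk 20,
#' mean sequencing depth 110x with negative-binomial overdispersion, tumour
#' purity 0.8, and a subclonal somatic VAF background.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_genes Number of genes.
#' @param planted_genes Integer indices (into `1..n_genes`) of burden genes.
#' @param rr Carrier relative risk in planted genes (cases only).
#' @param baseline_freq Baseline carrier frequency per gene.
#' @param n_sites_per_gene Size of the small allelic series per gene (carrier
#'   records are spread over this many recurrent variant sites).
#' @param depth_mean Mean sequencing depth (default 110).
#' @param depth_size Negative-binomial size (dispersion) parameter; `Inf`
#'   selects the Poisson fallback.
#' @param purity Tumour purity rho in `[0, 1]`.
#' @param loh_mode LOH mode planted in carriers of planted genes: `"none"`,
#'   `"deletion"` or `"cn_neutral"`.
#' @param loh_fraction Fraction of planted-gene case carriers receiving the
#'   LOH mode (others stay `"none"`).
#' @param cancer_types Character vector of cancer-type codes for cases.
#' @param n_somatic Somatic background size (events).
#' @param somatic_fractions True cellular fractions of the subclonal somatic
#'   VAF mixture.
#' @param trunc_class_probs Named probabilities over variant classes for
#'   carrier records.
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_cases = 3000L, n_controls = 1000L,
                              n_genes = 200L, planted_genes = integer(),
                              rr = 20, baseline_freq = 0.001,
                              n_sites_per_gene = 20L,
                              depth_mean = 110, depth_size = 8,
                              purity = 0.8,
                              loh_mode = c("deletion", "cn_neutral", "none"),
                              loh_fraction = 1,
                              cancer_types = c("BRCA", "OV", "STAD"),
                              n_somatic = 2000L,
                              somatic_fractions = seq(0.1, 0.5, by = 0.1),
                              trunc_class_probs = c(nonsense = 0.4,
                                                    frameshift_indel = 0.3,
                                                    splice_site = 0.15,
                                                    missense = 0.15),
                              seed = 1L) {
  loh_mode <- match.arg(loh_mode)
  stopifnot(baseline_freq >= 0, baseline_freq <= 1, rr >= 1,
            depth_mean > 0, purity >= 0, purity <= 1,
            all(planted_genes >= 1), all(planted_genes <= n_genes),
            loh_fraction >= 0, loh_fraction <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 planted_genes = as.integer(planted_genes),
                 rr = rr, baseline_freq = baseline_freq,
                 n_sites_per_gene = as.integer(n_sites_per_gene),
                 depth_mean = depth_mean, depth_size = depth_size,
                 purity = purity, loh_mode = loh_mode,
                 loh_fraction = loh_fraction,
                 cancer_types = cancer_types,
                 n_somatic = as.integer(n_somatic),
                 somatic_fractions = somatic_fractions,
                 trunc_class_probs = trunc_class_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected tumour VAF at a germline-heterozygous site
#'
#' Allele-accounting expectation for the variant allele fraction observed in
#' a tumour sample of purity `rho` at a site that is heterozygous in the
#' germline. With no LOH the expectation stays at the heterozygous 0.5
#' regardless of purity. Under deletion LOH the tumour cells lose the
#' wild-type allele: per cell the tumour contributes 1 variant of 1 allele
#' and the admixed normal 1 of 2, giving `rho / (2 - rho)` variant alleles
#' over `(2 - rho) ... ` i.e. `1 / (2 - rho)`. Under copy-neutral LOH the
#' wild-type copy is replaced by a second variant copy: `(1 + rho) / 2`.
#'
#' @param rho Tumour purity in `[0, 1]` (vectorised).
#' @param mode `"none"`, `"deletion"` or `"cn_neutral"`.
#' @return Expected tumour VAF; at `rho = 1` deletion gives 1.0 (a
#'   tumour/normal VAF ratio of 2 against the heterozygous 0.5), and any mode
#'   at `rho = 0` gives 0.5 (ratio 1).
#' @export
expected_tumour_vaf <- function(rho, mode = c("none", "deletion", "cn_neutral")) {
  mode <- match.arg(mode)
  if (any(rho < 0 | rho > 1)) abort("purity must lie in [0, 1]")
  switch(mode,
         none = rep(0.5, length(rho)),
         deletion = 1 / (2 - rho),
         cn_neutral = (1 + rho) / 2)
}

draw_depth <- function(n, depth_mean, depth_size) {
  d <- if (is.infinite(depth_size)) stats::rpois(n, depth_mean)
       else rnbinom(n, size = depth_size, mu = depth_mean)
  pmax(d, 8L)   # floor keeps denominators sane at the extreme left tail
}

#' Simulate read counts at germline-heterozygous sites
#'
#' Normal counts are binomial at VAF 0.5; tumour counts are binomial at the
#' purity- and mode-dependent expectation from [expected_tumour_vaf()].
#' Depths are negative-binomial around `depth_mean`.
#'
#' @param n Number of sites.
#' @param rho Tumour purity.
#' @param mode LOH mode (`"none"`, `"deletion"`, `"cn_neutral"`); recycled.
#' @param depth_mean,depth_size Depth model parameters.
#' @param seed Optional integer seed.
#' @return Tibble with `n_ref`, `n_alt`, `t_ref`, `t_alt`, `mode`, `rho`.
#' @export
simulate_loh_site <- function(n, rho, mode = "none",
                              depth_mean = 110, depth_size = 8,
                              seed = NULL) {
  mode <- rep_len(mode, n)
  draw <- function() {
    mu_t <- purrr::map_dbl(mode, ~ expected_tumour_vaf(rho, .x))
    dn <- draw_depth(n, depth_mean, depth_size)
    dt <- draw_depth(n, depth_mean, depth_size)
    na <- rbinom(n, dn, 0.5)
    ta <- rbinom(n, dt, mu_t)
    tibble(n_ref = as.integer(dn - na), n_alt = as.integer(na),
           t_ref = as.integer(dt - ta), t_alt = as.integer(ta),
           mode = mode, rho = rho)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full case/control tumour/normal cohort
#'
#' Emits a germline variant table, a somatic background table, sample
#' metadata, and a ground-truth object, with the statistical structure the
#' analysis stages assume: per-gene carrier indicators at the baseline
#' frequency (relative-risk-scaled in planted genes for cases), a small
#' recurrent allelic series per gene, binomial read counts at heterozygous
#' normal VAF, planted LOH in a configurable fraction of planted-gene case
#' carriers, a subclonal somatic VAF background, and per-cancer-type bimodal
#' age-of-onset distributions.
#'
#' @param cfg A [simulation_config()].
#' @return A list with tibbles `germline`, `somatic`, `meta`, and `truth`
#'   (list with `genes`, `loh_events`, `purity`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%03d", seq_len(cfg$n_genes))
    planted <- genes[cfg$planted_genes]
    samples <- c(sprintf("case_%04d", seq_len(cfg$n_cases)),
                 sprintf("ctrl_%04d", seq_len(cfg$n_controls)))
    role <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
    ctype <- ifelse(role == "case",
                    sample(cfg$cancer_types, length(samples), replace = TRUE),
                    NA_character_)
    # bimodal ages per cancer type (two-component normal mixture)
    age <- rep(NA_real_, length(samples))
    is_case <- role == "case"
    comp <- runif(sum(is_case)) < 0.4
    age[is_case] <- ifelse(comp, rnorm(sum(is_case), 48, 6),
                           rnorm(sum(is_case), 66, 7))
    age[!is_case] <- rnorm(sum(!is_case), 64, 8)
    age <- pmin(pmax(round(age), 18), 90)
    meta <- tibble(sample_id = samples, role = role, cancer_type = ctype,
                   age = age,
                   sex = sample(c("F", "M"), length(samples), replace = TRUE),
                   ethnicity = "synthetic")

    # carrier draws per gene
    germ <- purrr::map_dfr(seq_len(cfg$n_genes), function(gi) {
      g <- genes[gi]
      f <- rep(cfg$baseline_freq, length(samples))
      if (g %in% planted) {
        f[is_case] <- pmin(cfg$baseline_freq * cfg$rr, 1)
      }
      carrier <- runif(length(samples)) < f
      if (!any(carrier)) return(NULL)
      idx <- which(carrier)
      site <- sample.int(cfg$n_sites_per_gene, length(idx), replace = TRUE)
      cls <- sample(names(cfg$trunc_class_probs), length(idx), replace = TRUE,
                    prob = cfg$trunc_class_probs)
      tibble(sample_id = samples[idx], gene = g,
             chrom = as.character(1 + (gi %% 22)),
             pos = 1000L * gi + 10L * site,
             ref = "A", alt = "T",
             variant_class = cls,
             protein_pos = 50L * site,
             site = site, gene_index = gi)
    })
    n_rec <- nrow(germ)
    germ <- germ %>%
      mutate(maf_1000g = 0, maf_esp = 0,
             is_case_rec = .data$sample_id %in% samples[is_case])

    # planted LOH among planted-gene case carriers
    loh_mode <- rep("none", n_rec)
    cand <- which(germ$gene %in% planted & germ$is_case_rec)
    if (length(cand) > 0 && cfg$loh_mode != "none" && cfg$loh_fraction > 0) {
      n_loh <- round(cfg$loh_fraction * length(cand))
      loh_mode[sample(cand, n_loh)] <- cfg$loh_mode
    }
    # read counts: normals for everyone, tumours for cases only
    dn <- draw_depth(n_rec, cfg$depth_mean, cfg$depth_size)
    na <- rbinom(n_rec, dn, 0.5)
    mu_t <- purrr::map_dbl(loh_mode, ~ expected_tumour_vaf(cfg$purity, .x))
    dt <- draw_depth(n_rec, cfg$depth_mean, cfg$depth_size)
    ta <- rbinom(n_rec, dt, mu_t)
    germline <- germ %>%
      mutate(n_ref = as.integer(dn - na), n_alt = as.integer(na),
             t_ref = ifelse(.data$is_case_rec, as.integer(dt - ta), NA_integer_),
             t_alt = ifelse(.data$is_case_rec, as.integer(ta), NA_integer_)) %>%
      select("sample_id", "gene", "chrom", "pos", "ref", "alt",
             "variant_class", "protein_pos", "maf_1000g", "maf_esp",
             "n_ref", "n_alt", "t_ref", "t_alt")

    # somatic background: subclonal VAF mixture over non-planted genes
    bg_genes <- setdiff(genes, planted)
    frac <- sample(cfg$somatic_fractions, cfg$n_somatic, replace = TRUE)
    sd_depth <- draw_depth(cfg$n_somatic, cfg$depth_mean, cfg$depth_size)
    sa <- rbinom(cfg$n_somatic, sd_depth, frac)
    somatic <- tibble(
      sample_id = sample(samples[is_case], cfg$n_somatic, replace = TRUE),
      gene = sample(bg_genes, cfg$n_somatic, replace = TRUE),
      protein_pos = sample.int(500L, cfg$n_somatic, replace = TRUE),
      variant_class = "missense",
      t_ref = as.integer(sd_depth - sa), t_alt = as.integer(sa)
    ) %>% filter(.data$t_ref + .data$t_alt > 0)

    truth_genes <- tibble(gene = genes,
                          planted = genes %in% planted,
                          rr = ifelse(genes %in% planted, cfg$rr, 1))
    truth_events <- germline %>%
      mutate(loh_mode = loh_mode, rho = cfg$purity) %>%
      filter(!is.na(.data$t_ref)) %>%
      select("sample_id", "gene", "pos", "loh_mode", "rho")
    list(germline = germline, somatic = somatic, meta = meta,
         truth = list(genes = truth_genes, loh_events = truth_events,
                      purity = cfg$purity))
  })
}

#' Simulate events on one protein for the hotspot scan
#'
#' Under the alternative, significant events are uniform within the planted
#' interval and non-significant events uniform over the whole protein; in
#' null mode both are uniform over the protein.
#'
#' @param L Protein length (amino acids).
#' @param interval Planted interval `c(start, end)` within `[1, L]`.
#' @param n_sig,n_nonsig Event counts.
#' @param null If `TRUE`, place significant events uniformly too.
#' @param seed Optional integer seed.
#' @return A list with `events` (tibble `position`, `significant`) and
#'   `truth` (the planted interval, or `NULL` in null mode).
#' @export
simulate_hotspot_protein <- function(L, interval = c(1L, L), n_sig, n_nonsig,
                                     null = FALSE, seed = NULL) {
  if (interval[1] < 1 || interval[2] > L || interval[1] > interval[2]) {
    abort("interval must lie within [1, L]")
  }
  draw <- function() {
    sig_pos <- if (null) sample.int(L, n_sig, replace = TRUE)
               else sample(seq(interval[1], interval[2]), n_sig, replace = TRUE)
    non_pos <- sample.int(L, n_nonsig, replace = TRUE)
    tibble(position = as.integer(c(sig_pos, non_pos)),
           significant = rep(c(TRUE, FALSE), c(n_sig, n_nonsig)))
  }
  events <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(events = events,
       truth = if (null) NULL else list(start = interval[1], end = interval[2]))
}
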