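---
title: "Statistical methods behind lohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind lohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscan)
library(dplyr)
```

# The problem

In a tumour/normal sequencing cohort, two questions about rare germline
variants arise together. First, which genes carry more rare truncating
variants in cases than in ancestry-matched controls — the association
question, answered by burden testing. Second, which of those inherited
variants are under somatic selection — the mechanism question, answered by
looking for allelic enrichment of the variant in the tumour sample, i.e.
loss of heterozygosity (LOH) of the wild-type allele. A germline variant that
is both enriched in cases and preferentially retained by tumours is a far
stronger susceptibility candidate than one supported by association alone.

`lohscan` implements the full chain: frequency filtering, exact burden tests
with FDR ranking, a combined site-level LOH test, gene-level LOH tests, a
sliding-window scan for spatial hotspots of significant LOH in protein
coordinates, germline–somatic interaction tests, and a synthetic cohort
generator that makes the whole pipeline testable without controlled-access
patient data.

# Rare-variant filtering

A variant qualifies as truncating if its class is nonsense, frameshift
indel, nonstop, or splice site; splice-site changes only count within the
two base pairs flanking an exon (`splice_flank_bp`, default 2), because only
the donor/acceptor dinucleotides are reliably loss-of-function.

Three frequency rules then apply per distinct variant, in any order:

* **Pooled MAF ≤ 0.05%** (`pooled_maf_max = 5e-4`): the average of the
  case-cohort and control allele frequencies. The boundary is inclusive by
  default with a `strict_pooled` switch, because the headline variant set in
  this style of analysis is defined with the inclusive reading; the switch
  covers the strict one.
* **Population MAF < 1%** (`maf_1000g_max`): against a 1000-Genomes-style
  reference panel, missing values passing.
* **Cohort frequency < 1% in each cancer type** (`cohort_freq_max`): as a
  carrier frequency over the cases of that type. We deliberately use carrier
  counts rather than allele counts here — the rule is phrased as a cohort
  frequency, and for rare heterozygous variants the two differ only by a
  factor of two in the denominator.

The minimum-observation rule — a variant must be seen at least `min_obs`
times in cases and controls combined (2 for genotype-level control cohorts,
3 for summary-level ones) — is *not* part of `apply_rare_filters()`. It
exists to stabilise the burden test's 2×2 tables, so it is applied inside
`run_burden()` at the variant level before aggregation. Keeping it out of
the generic filter also preserves the invariant that a singleton variant
absent from controls survives frequency filtering (it is, after all, exactly
what a rare susceptibility allele looks like); pushing it into the filter
would contradict that.

Carrier-frequency summaries use the Wilson score interval at 95%. The Wilson
interval is used instead of the Wald interval deliberately: carrier
fractions are small and read-count VAFs sit near 0.5 on 10–200 reads, both
regimes where the Wald interval misbehaves and the score interval does not.

# Burden testing

Both burden tests are one-tailed Fisher exact (hypergeometric upper-tail)
tests: the total frequency test (TFT) on pooled allele counts
([alt, non-alt] × [case, control], diploid totals `2n`), and the cohort
allelic sum test (CAST) on carrier counts. The one-tailed direction is case
excess. These are the canonical forms of both tests; the TFT is the primary
statistic and CAST is reported alongside because the two correlate strongly.

FDR families are per cohort: each cancer type's gene list is one
Benjamini–Hochberg family, and the pan-cancer list is its own family.
Reporting defaults to FDR ≤ 5%, with 10%/15% tiers available downstream
(looser tiers are how LOH refinement widens its candidate list). All genes
are treated as diploid with a per-gene `ploidy` override rather than any
automatic X-chromosome handling, since gene symbols alone do not carry
chromosome information.

## Choices worth recording

* *Minimum-observation unit.* Whether "fewer than three observations"
  counts alleles or carriers is ambiguous in the field's usage; for rare
  heterozygous variants they coincide per sample. We count carriers, with
  `min_obs_unit = "alleles"` exposed.
* *Genes below `min_obs` are absent from the output*, not reported at
  p = 1 — a gene with no testable variants has no test, and padding with
  p = 1 would distort the BH family size.

# Site-level LOH

At a germline-heterozygous site with normal counts `(n_ref, n_alt)` and
tumour counts `(t_ref, t_alt)`, the evidence for selection is an elevated
tumour VAF. Two complementary aspects are tested:

1. **Against the matched normal**: a one-tailed Fisher exact test on
   allele type × sample type.
2. **Against the somatic background**: the tumour VAF is referred to an
   empirical null built by crossing every background somatic reference
   count `r_i` with every background variant count `v_j`, null VAFs
   `v_j / (r_i + v_j)`. The cross-product is subsampled uniformly to
   `null_cap` (default 10⁶) under a seed when it is larger. Genes with any
   prior evidence of significance (the burden candidates, and the tested
   genes themselves) are excluded from the background so the null is not
   contaminated with true LOH signal. The empirical p uses the add-one
   correction `(#{null ≥ v_t} + 1)/(N + 1)`, which keeps p strictly
   positive — necessary because the combination step takes logs.

The two p-values use distinct information (the matched normal versus the
cohort-wide somatic VAF population) and are combined by Fisher's method:
`X = −2(ln p₁ + ln p₂) ~ χ²₄`, with survival function `e^(−X/2)(1 + X/2)`.
Stouffer's z-average is exposed as `combine_method = "stouffer"`. The
permutation statistic is the tumour VAF by default; a ratio-based variant
(`permutation_stat = "ratio"`, tumour/normal ratio rescaled by the
heterozygous 0.5) is available where matched-normal contamination is a
concern.

**Pre-conditioning.** Because depth varies across sites and samples, VAF
estimates vary in reliability. A site enters testing only if the larger
distance from its VAF to either end of its Wilson interval at 90% confidence
(z = 1.6449) is ≤ 12% (`max_halfwidth = 0.12`). By default both the tumour
and the normal interval must qualify (`prefilter_scope = "both"`); a
tumour-only mode exists. The halfwidth bound translates to a minimum usable
depth of roughly 45 reads at VAF 0.5.

**FDR families and thresholds.** Truncation and missense sites are corrected
separately (they are reported separately and have different priors), at
FDR ≤ 5% and ≤ 1% respectively. Because practice in this area also uses a
looser FDR ≤ 20% prioritisation tier, every site additionally carries a
`prioritized` flag; the three thresholds are emitted as flags rather than
resolved into one, since they serve different downstream uses (calling
versus candidate widening). Multiple events at one site in different
patients are independent observations and are tested individually.

# Gene-level LOH

For truncations, the tumour VAFs of a candidate gene's sites are compared
with the pooled background of all other tested sites by a pooled two-sample
one-tailed t-test with `df = n₁ + n₂ − 2`. For missense variants this is not
sensitive enough (missense LOH fractions are small); instead the fraction of
a gene's sites with significant LOH at the strict 1% FDR is compared with
the background fraction by a one-tailed Fisher test, restricted to genes
with ≥ 3 significant events and a fractional excess of ≥ 2 percentage
points. Exclusion by these criteria is a recorded result
(`included = FALSE` with a reason), not an error.

# Hotspots of significant LOH

The null hypothesis is that LOH events — significant or not — are placed
uniformly and independently along the protein. A single event is "relevant"
to a window of width `W` on a protein of length `L` if it is significant
(probability `D_s/(D_s + D_n)` under the null) *and* falls in the window
(probability `W/L`); independence of the two conditions gives
`p_b = (W/L) · D_s/(D_s + D_n)`. The count of relevant events among the
protein's `n = D_s + D_n` events is then Binomial(`n`, `p_b`), and a window
holding `k` significant events gets the upper-tail probability `P_S`.

The trial count `n = D_s + D_n` deserves a note: with events i.i.d. under
the null, every event of the protein is a trial that may or may not satisfy
both conditions, which is the reading consistent with the i.i.d. statement;
the Monte-Carlo oracle in the test suite (uniform positions, Bernoulli
significance) confirms the resulting tail probabilities.

Window sizes run 30–200 aa in 1-aa steps; windows are fully contained in
`[1, L]` (no wraparound) and `W > L` is clipped to `L`, so short proteins
are still scanned. `p_b` is constant per (protein, window size) and cached.
Each significant event is assigned the window containing it with the
smallest `P_S`; ties resolve deterministically to the smallest `W`, then the
smallest start. (A per-window exhaustive candidate mode was considered; the
per-event assignment is what the merging step needs, and the exhaustive
minimum is identical — the suite checks the scan minimum against an
exhaustive reduced-range oracle.) Overlapping candidate regions merge to
their union, keeping the constituent statistics of the best `P_S`, and BH
correction runs across the full merged list from all proteins — one family,
since the hotspot list is reported as one list. The scan itself contains no
randomness: identical input gives byte-identical output.

# Germline–somatic interactions

The co-occurrence statistic for a (germline gene, somatic gene) pair is the
number of samples carrying both. The null permutes the germline indicator
across samples with the somatic vector fixed — the simplest scheme that
preserves both marginal counts exactly and the somatic co-occurrence
structure — 10,000 times by default, with add-one-corrected tail p-values
in both directions (large overlap: co-occurrence; small: mutual
exclusivity). Permutation can be stratified within cancer types; the test
suite demonstrates why this matters by planting a type-confounded pair whose
pan-cohort exclusivity vanishes under stratification. Somatic genes are
expected to be pre-filtered for recurrence (≥ 5 mutations pan-cancer or
≥ 2 within a type) by the caller.

Carrier effects on somatic mutation burden use a one-tailed Wilcoxon
rank-sum test (exact for tie-free groups of ≤ 10, normal approximation with
tie correction otherwise; fully tied data returns p = 0.5 since the rank-sum
variance is zero). Age-of-onset associations fit `age ~ carrier +
cancer_type` by ordinary least squares with a one-tailed p for a negative
carrier coefficient; a Gaussian linear model is the deliberate default since
nothing in the age response motivates another family, and a Wilcoxon
alternative is emitted alongside for the gene-set style of analysis.

# The synthetic cohort generator

`simulate_cohort()` emulates the features the tests rely on:

* **Cohort structure**: 3,000 cases / 1,000 controls over 200 genes by
  default — the scale at which the burden design is powered; cases carry a
  cancer-type label from a configurable set.
* **Carrier model**: per-gene carrier indicators at a 0.1% baseline
  frequency, multiplied by a relative risk (default 20) in planted genes
  for cases only. Carrier records are spread over a small recurrent allelic
  series (20 sites per gene), so that individual variants are rare enough
  to survive the pooled-MAF rule yet recurrent enough to pass the
  minimum-observation rule — the same tension real rare-variant data
  exhibits.
* **Read counts**: depths are negative-binomial around `depth_mean = 110`
  (matching typical exome coverage; `depth_size = Inf` selects a Poisson
  fallback), normal alt counts are Binomial(depth, 0.5), and tumour alt
  counts are Binomial(depth, `expected_tumour_vaf(ρ, mode)`) with
  `E[v_t] = 0.5` (none), `1/(2 − ρ)` (deletion), `(1 + ρ)/2`
  (copy-neutral). Purity defaults to 0.8.
* **Somatic background**: VAFs from a mixture of binomials at cellular
  fractions {0.1, …, 0.5}, mimicking subclonal structure.
* **Ages**: two-component normal mixtures per cancer type, echoing the
  bimodal age-of-onset distributions seen in several tumour types, so the
  age model has realistic covariate structure.
* **Truth labels**: planted burden genes, per-record LOH modes and purity,
  and planted hotspot intervals, all referencing emitted records.

What the generator does *not* emulate: linkage structure, realistic gene
lengths, mutational signatures, sequencing error beyond binomial sampling,
or ancestry stratification. Passing recovery tests on these cohorts
demonstrates that the statistics behave as designed under their own
assumptions — not that those assumptions hold in any particular real
cohort.

# Numerical and degenerate-input policy

* p-values of exactly 0 entering the combination are clamped to the
  smallest positive double with a warning.
* Empirical p-values always use add-one correction, so they live in
  `(0, 1]`.
* Wilson endpoints at 0 or `trials` successes are pinned exactly to 0 / 1.
* `vaf_ratio` is undefined (error) at normal VAF 0; such sites are not
  heterozygous calls in the first place.
* A cohort with no sites surviving the pre-filter returns an empty result
  with a warning, not an error; a missense gene failing inclusion criteria
  is an excluded row, not an error.
* Zero pooled variance or groups smaller than 2 abort the gene-level
  t-test.

# Problem sizes used in the test suite

Calibration tests use 10,000 diploid-neutral sites, a 200-gene null cohort
at 1,500/1,500, and 200 null proteins (type-I error at or below nominal
within 3 Monte-Carlo standard errors). Recovery tests use the generator's
default 3,000/1,000 cohort (5 replicates), 50 planted deletion-LOH events
at purities 0.8 and 1.0 against 150 neutral sites, and 8-event 50-aa
hotspot plantings (5 replicates). Exact-test oracle checks enumerate every
2×2 table with total at most 50. These sizes keep the full suite under a
minute while leaving the Monte-Carlo bounds meaningful.

# Known limitations

* The burden tests are unadjusted exact tests: no covariates, no ancestry
  principal components, no SKAT-style variance components.
* Tumour purity is a simulation parameter, not something estimated from
  data; copy-number segmentation and phasing are out of scope.
* The permutation null treats background ref and alt counts as exchangeable
  across events; depth/VAF correlation in the background is ignored.
* The hotspot scan is 1-D in protein coordinates; 3-D structural clustering
  is out of scope.
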