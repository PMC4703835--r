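Package: lohscan
Title: Rare Germline Variant Burden Testing and Tumour Loss-of-Heterozygosity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for detecting rare germline cancer-susceptibility
    variants and their somatic selection in tumour/normal sequencing cohorts.
    Implements rare-variant filtering with carrier-frequency summaries, exact
    one-tailed burden tests (total frequency test and cohort allelic sum test)
    with Benjamini-Hochberg ranking, a combined Fisher-exact plus empirical
    permutation test of allelic enrichment (loss of heterozygosity) at
    germline-heterozygous sites with Wilson-interval pre-conditioning,
    gene-level enrichment tests, a sliding-window binomial scan for hotspots of
    significant allelic imbalance in protein coordinates, germline-somatic
    co-occurrence and mutual-exclusivity permutation tests, and a synthetic
    tumour/normal cohort generator with ground-truth labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
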