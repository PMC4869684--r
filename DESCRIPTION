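Package: haplometa
Title: Two-Stage Meta-Analysis of Haplotype Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype association testing for quantitative traits across
    multiple cohorts that cannot share individual-level data. Stage one fits,
    within each cohort, a linear mixed model with expected haplotype dosages
    (inferred from unphased genotypes by an EM algorithm) as fixed effects and
    a pedigree-derived kinship random effect, so family-based, unrelated and
    mixed cohorts are all accommodated. Stage two pools the cohort-level
    haplotype effect vectors and covariance matrices by multivariate
    generalized least squares, allowing haplotype sets that only partially
    overlap across cohorts, and provides a global Wald test of haplotype-trait
    association together with per-haplotype contrasts against a baseline
    haplotype. Also included are a gene-dropping simulator for nuclear-family
    and unrelated study designs, and single-variant (inverse-variance min-P),
    burden and SKAT meta-analysis comparators for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
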