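Package: exburden
Title: Rare-Variant Collapsing Burden Tests with Mendelian Randomization
    and Colocalization Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level collapsing burden association for rare coding
    variants in biobank-scale case-control cohorts: genotype-level quality
    control (depth/quality gating and an exact binomial allele-balance
    test), multi-allelic splitting and left-alignment, transcript and
    consequence prioritization into collapsing masks (high-confidence
    protein-truncating variants, REVEL- and CADD-thresholded missense,
    synonymous negative controls), a three-step generalised linear burden
    model with genomic-inflation and heterogeneity diagnostics, a
    two-sample Mendelian randomization estimator suite (IVW, Egger,
    weighted and penalised weighted median, radial outlier and Steiger
    filtering, multivariable MR), Bayes-factor colocalization of two
    summary-statistic tracks, and a synthetic-cohort generator for
    calibration and power studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
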