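Package: kinspan
Title: Kin-Cohort Survival Analysis of Parental Lifespan from Offspring Genotype
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kin-cohort genome-wide association analysis of lifespan,
    in which parental survival is regressed on offspring genotype. Implements
    Cox proportional-hazards survival scores via Breslow-baseline Martingale
    residuals, rank-based inverse-normal transformation, a fast per-variant
    residual scan with conditional (sentinel-adjusted) analysis, the
    Mendelian dosage-expectation rescaling from the offspring to the parental
    allele scale, age-window (frailty versus longevity) record transforms,
    inverse-variance fixed-effect meta-analysis with sex and age-window
    contrast tests, and Kaplan-Meier restricted-mean life-year summaries.
    Includes a trio-structured synthetic cohort generator (Hardy-Weinberg
    parental genotypes, Mendelian transmission, Gompertz mortality from age
    40, interview censoring, phenotype contamination) so the whole pipeline
    is testable without access-controlled biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
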