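Package: igfmr
Title: Two-Sample Mendelian Randomization Pipeline for IGF-Axis Biomarkers
    and Prostate Cancer
Version: 0.1.0
Authors@R:
    person("igfmr", "maintainers", email = "igfmr@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable two-sample Mendelian randomization (MR)
    pipeline built around the IGF axis and prostate cancer: genotype quality
    control (Hardy-Weinberg testing, allele accounting, dosage-based LD r2),
    validation of genetic variants as instruments for circulating biomarkers
    (per-allele effects, partial F and incremental R2, confounder screens,
    pleiotropy matrices), per-study case-control and survival association
    models with cluster-robust standard errors, fixed- and random-effects
    meta-analysis with heterogeneity statistics, and SD-scaled Wald-ratio
    causal estimation with delta-method and Fieller intervals. A synthetic
    multi-study consortium generator with known genotype-biomarker-outcome
    causal structure provides ground truth for every stage, and a small
    command-line pipeline sequences simulate, QC, validate, associate,
    meta-analyse and MR into one reproducible run.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
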