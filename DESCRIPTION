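Package: targetMR
Title: Brain eQTL Mendelian Randomization and Colocalization for Drug
    Target Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-sample Mendelian randomization pipeline that uses
    cis-acting brain eQTLs as genetic instruments to estimate causal
    effects of gene expression on neurological and psychiatric disease
    risk. Implements instrument selection (MHC masking, significance
    filtering, greedy LD clumping, effect standardization, Cragg-Donald
    instrument strength), Wald-ratio and multi-SNP MR estimators,
    Bayesian colocalization over cis regions with five-hypothesis
    posteriors, Steiger directionality filtering and reverse MR,
    phenome-wide pleiotropy screening with permutation and enrichment
    tests, fixed-effects meta-analysis with Cochran's Q heterogeneity,
    GWAS-by-proxy rescaling, rule-based drug-target prioritization, and
    a synthetic summary-statistics generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sumstats-io.R'
    'harmonize.R'
    'instruments.R'
    'mr.R'
    'coloc.R'
    'steiger.R'
    'meta.R'
    'pleiotropy.R'
    'simulate.R'
    'prioritize.R'
    'pipeline.R'
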