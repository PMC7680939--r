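Package: gxegain
Title: Genetic Gain Estimation from Multi-Environment Wheat Trials with
    Factor-Analytic Genotype-by-Environment Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating annual genetic yield gains from series of
    international multi-environment wheat yield trials. Fits single-location
    alpha-lattice mixed models by restricted maximum likelihood (REML) with a
    line-mean heritability filter, and multi-environment mixed models with a
    factor-analytic covariance structure for genotype-by-environment effects;
    extracts best linear unbiased predictions (BLUPs), expresses the yield of
    the top decile of lines relative to long-term and local check cultivars,
    and regresses those ratios on trial years to estimate annual gains.
    Includes megaenvironment classification of trial locations from climate
    and management metadata, site-regression (SREG/GGE) biplot decomposition
    with which-won-where polygons, a synthetic trial-series generator with
    known ground truth for validation, and a deterministic end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
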