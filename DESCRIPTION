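Package: metGP
Title: Factor-Analytic Genomic Prediction for Multi-Environment Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction of grain yield across multi-environment wheat
    trials. Implements SNP marker quality control ({1,0,-1} coding, missingness
    and minor-allele-frequency filters, EM imputation), VanRaden-type additive
    genomic relationship matrices and their Hadamard-square additive-by-additive
    epistatic counterparts, REML estimation of factor-analytic (FA) mixed models
    over sites with one or two genomic kernel terms (FA, FA+G, FA+GG, FA+G+GG),
    BLUP prediction of genotype-within-site genetic values, and the CV1/CV2/CV3
    cross-validation schemes used to measure per-site prediction accuracy. A
    synthetic multi-environment trial generator with known ground truth supports
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools
Suggests: testthat (>= 3.0.0), lme4, vcfR, jsonlite, yaml, withr, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'markers.R'
    'kernels.R'
    'famm-engine.R'
    'famm.R'
    'cv.R'
    'io.R'
    'metGP-package.R'
    'methods-accessors.R'
    'simdata.R'
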