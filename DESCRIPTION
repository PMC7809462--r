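Package: cohertraj
Title: Developmental Trajectories of Polygenic Risk Associations with EEG Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking polygenic risk scores built
    from GWAS summary statistics to age-resolved, sex-stratified associations
    with resting-state EEG coherence phenotypes. Provides magnitude-squared
    coherence estimation between bipolar electrode-pair derivations of the
    10-20 montage, polygenic scoring with quality control, allele alignment,
    greedy LD clumping and p-value thresholding, locally weighted
    age-trajectory regression with observation weights for repeated measures
    and family clustering, Benjamini-Hochberg FDR masking, and a synthetic
    multi-generation family cohort generator with planted, age- and
    sex-localized genetic effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
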