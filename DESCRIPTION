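Package: admixaudit
Title: Cohort Auditing for Admixed Population-Genomic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to audit population-genomic cohorts with unequal group
    sizes and array-ascertained genotype content. Provides a seeded
    Balding-Nichols simulator for admixed cohorts with a European-ascertained
    array subset, per-variant and per-sample quality control (call rate, MAF,
    Levene-Haldane exact Hardy-Weinberg test, method-of-moments IBD pruning),
    quantification of SNP-array ascertainment bias against whole-genome
    variant sets (capture rate, MAF-spectrum distortion, chromosomal bias),
    Ts/Tv-based variant validation with a conservative mixture error bound,
    and sample-size-bias-corrected population structure through
    inverse-group-size weighted PCA with stratified bootstrap stability,
    Hudson FST and unweighted polygenic risk scores.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vegan,
    vcfR
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
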