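Package: fusioncoal
Title: Coalescent Tests of Speciation by Fusion from the Joint Site
    Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic inference for three-deme hybrid-speciation problems.
    Simulates unlinked biallelic SNPs under strictly bifurcating,
    introgression, and speciation-by-fusion scenarios (with ancestral,
    contemporary, or full gene flow) using a backward-time structured
    coalescent; builds folded joint site frequency spectra with
    hypergeometric projection; fits models by simulation-based composite
    likelihood with multi-start optimization; compares models by AIC and
    Akaike weights; computes percentile parametric-bootstrap confidence
    intervals; and runs four-taxon ABBA/BABA D-statistic tests of
    introgression with locus-bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
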