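Package: metahet
Title: Heterozygosity, Demography, and Extinction Risk in Butterfly
    Metapopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how genome-wide heterozygosity, demography,
    and environment jointly predict local extinction and overwinter nest
    mortality in a classical butterfly metapopulation. Provides a synthetic
    metapopulation generator (stochastic patch occupancy dynamics with
    SNP genotypes, full-sib larval nests, and an inbreeding-load survival
    process), small-sample-corrected heterozygosity estimation at the nest
    and population level, incidence-function-model connectivity and
    demographic covariate construction, a self-contained fixed-effect
    logistic regression engine with Wald inference, heterozygosity-based
    inbreeding-load (haploid lethal equivalents) estimation, and
    Monte-Carlo power analysis for heterozygosity effects on mortality
    and extinction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
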