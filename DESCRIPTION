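Package: privburden
Title: Burden of Private Mutations Under Demographic Models and in Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the per-individual burden of private mutations: the
    proportion of heterozygous sites in a newly sequenced diploid genome that
    are singletons (present in a single copy) in the combined sample with n
    previously sequenced individuals. Provides exact coalescent expectations of
    branch lengths and folded site frequency spectra under piecewise demographic
    histories (constant size, bottlenecks, recent exponential growth), the
    closed-form and general expected burden, hypergeometric projection
    (probabilistic subsampling) of folded site-frequency data to a common
    chromosome count, simulation of diploid genotype panels with paired
    missingness, and empirical per-individual estimators with individual
    downsampling and SNV-bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
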