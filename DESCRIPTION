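Package: waxwane
Title: Geographic Range Evolution, Sympatry and Diversification of Fossil Clades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the waxing and waning of animal clades from
    fossil occurrence records. Builds per-bin and cumulative species, clade and
    average geographic range curves from minimum convex polygon areas on
    equal-area projections, quantifies the degree of sympatry as the ratio of
    summed species ranges to the clade union range, locates trend shift points
    on range, sympatry and net-diversification curves by BIC-penalised
    piecewise-linear changepoint search with a randomisation test for their
    temporal coincidence, estimates origination and extinction times of
    lineages under a Poisson fossil-preservation model by MCMC, and fits a
    birth-death model in which speciation and extinction rates depend
    exponentially on the degree of sympatry. A synthetic fossil-clade
    generator with spatially explicit species ranges supports end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
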