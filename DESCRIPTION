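Package: cdnmkit
Title: Clustered De Novo Mutation Detection and Dose-Response Modelling in Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clustered de novo mutations (cDNMs) in
    whole-genome-sequenced parent-offspring trio cohorts: posterior scoring
    and heuristic filtering of de novo mutation candidates from joint VCF
    calls, window-based assembly of mutation clusters with repeat and
    mapability target masks, read-backed parent-of-origin phasing, age
    matching of cohorts by minimum-weight bipartite assignment, negative
    binomial regression of mutation counts on parental age, cohort and
    paternal radiation dose, exact binomial validation statistics, a
    binomial-thinning robustness simulation for imperfect positive
    predictive value, and a synthetic trio-cohort generator that emulates
    the statistical structure of such studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    vcfR,
    IRanges,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
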