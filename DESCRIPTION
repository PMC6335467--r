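Package: phyloturnover
Title: Phylogenetic Turnover in Environmental Space
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies true phylogenetic turnover (the Simpson component of
    phylogenetic beta diversity) among species assemblages sampled from
    gridded occurrence data, removes the effect of geographic land distance
    (least-cost paths with a sea penalty) by logit-scale regression, maps the
    residual turnover into a two-dimensional environmental space
    (temperature x moisture), and decomposes its macroecological drivers
    (species richness, relative phylogenetic diversity, niche size) with LMG
    variable-importance shares. Includes Pagel delta branch-length rescaling
    and depth truncation of phylogenies, a Turc-equation moisture index,
    equal-width environmental stratification with log-proportional stratified
    random sampling, scattered-data linear interpolation into environmental
    space, and a synthetic-data generator (Yule trees, Brownian niche
    evolution, Gaussian suitability ranges) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
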