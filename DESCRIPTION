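Package: linkrisk
Title: Risk of Interaction Loss in Mutualistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the risk that the loss of individual plant-animal
    links poses to mutualistic communities. Computes a per-link
    vulnerability index from link frequency and generalisation, the
    per-link contribution to the feasibility domain of a generalized
    Lotka-Volterra mutualism model (structural-stability analysis via
    solid-angle and centroid-perturbation estimators), variance-based
    null models of taxonomic consistency of link properties, and the
    mixed-effects regression relating vulnerability to feasibility
    contribution. Includes a synthetic metaweb generator with planted
    ground truth for end-to-end validation, and readers for
    web-of-life-style weighted incidence matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
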