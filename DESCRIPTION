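Package: elevrich
Title: Species Richness and Climate Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing species richness along mountain elevational
    gradients from species elevational-range tables. Interpolates ranges into
    fixed-width vertical bands, computes per-band richness by taxon group and
    log-area-corrected species density, fits standardized first- and
    second-order polynomial regressions of richness on bioclimatic variables,
    partitions explained variation among two or three predictor sets by
    partial regression on the adjusted R-squared scale, and selects best
    climate models by exhaustive all-subsets AICc search. Includes a synthetic
    community generator with known ground truth, emulating a Himalayan
    pteridophyte gradient, so the whole pipeline can be exercised and
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
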