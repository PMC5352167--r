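Package: gridsuff
Title: Grid-Level Sampling Sufficiency of Species Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses how completely plant-species inventories sample a
    landscape when quadrat records are aggregated onto degree fishnets.
    Occurrence records are gridded onto nested latitude-longitude cells,
    sample-based species-accumulation curves are built per cell, the Clench
    saturation model S(x) = a*x/(1 + b*x) is fitted by damped Gauss-Newton
    least squares, observed richness is compared with the fitted asymptote
    a/b across a ladder of sufficiency thresholds, the theoretical effort
    n_q = q/(b*(1-q)) needed to reach a target completeness is computed,
    and under-sampled cells are ranked for resurvey by a weighted min-max
    score over vegetation heterogeneity and vegetation area. A synthetic
    landscape-and-survey generator with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    minpack.lm,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
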