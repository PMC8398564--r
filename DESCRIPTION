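Package: transitsim
Title: Simulation of Gastric-to-Intestinal Transit Dissolution, Permeation
    and f2-Based Bioequivalence Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico twin of a single-chamber stomach-to-intestine
    transfer device for oral drug products. Designs biorelevant fluids
    (FaSSGF, FaSSIF and the concentrated infusate that converts one into the
    other) by exact per-species mass balance, computes the pH of arbitrary
    buffer mixtures by polyprotic charge balance, and integrates tablet
    disintegration, dissolution, supersaturation/precipitation and biphasic
    permeation into an octanol receiver over the infusion-driven pH and
    volume shift. Includes pH- and chloride-dependent solubility of weak
    bases (Henderson-Hasselbalch with a common-ion solubility-product cap),
    a scenario grid over gastrointestinal physiology (initial gastric pH,
    gastric emptying time, agitation strength), calibrated drug archetype
    fixtures, synthetic noisy observations, and the Ta-based four-point f2
    similarity pipeline for calling bioequivalence between two formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
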