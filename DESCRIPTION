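Package: leafgmin
Title: Leaf Minimum Conductance and Residual Canopy Transpiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying leaf minimum conductance (g_min) from
    mass-loss drydown experiments on detached leaves, fitting its temperature
    response (exponential and segmented bi-linear models with breakpoint
    detection), relating g_min to stomatal and cuticular leaf traits, and
    simulating residual whole-tree canopy transpiration at full stomatal
    closure (E_min_canop) over measured or artificially heated diurnal climate
    records. Includes seeded synthetic-data generators for drydown curves,
    diurnal climate days and species trait tables so the full analysis chain
    can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
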