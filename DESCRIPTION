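Package: lakephoto
Title: Lake Browning Trends and Photochemical Singlet-Oxygen Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking long-term lake browning (rising
    dissolved organic carbon and water colour) to photochemical
    singlet-oxygen production in lake surface waters. Provides seasonal
    Mann-Kendall trend tests with Sen's slopes and k-means browning
    classification, Morlet wavelet coherence with band aggregation, phase
    classification and surrogate significance for DOC-driver synchrony,
    CDOM optical metrics (E2:E3, spectral slopes, SUVA254), apparent
    singlet-oxygen quantum yields from furfuryl-alcohol probe kinetics
    with p-nitroanisole/pyridine actinometry, a depth-averaged
    steady-state singlet-oxygen light-field model, and contaminant
    half-life screening against lake flushing. A seeded synthetic-data
    module generates every input the pipeline consumes.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
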