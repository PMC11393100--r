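Package: superdo
Title: Superstatistical Analysis of Dissolved-Oxygen Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency dissolved-oxygen (DO) records
    from tidal rivers. Provides sensor quality control, additive and
    multiplicative detrending by seasonal moving averages or empirical mode
    decomposition, maximum-likelihood fitting of q-Gaussian (Tsallis)
    distributions to DO fluctuations, chi-squared superstatistical
    simulation, spatial trends of fitted parameters against distance to sea,
    naive forecasting baselines with MAE/SMAPE evaluation, and a synthetic
    generator of DO-like multi-site series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
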