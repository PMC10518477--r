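Package: hrvfill
Title: Forecast-Based Gap Filling for Heart Rate Variability RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects artifacts (gaps) in heart-rate-variability RR-interval
    series by forecasting-based gap filling with ARIMA models and
    epsilon-insensitive support vector regression using chained multi-step
    prediction, and compares them against classical fillers (linear and cubic
    spline interpolation, deletion, differenced Gaussian noise). Computes the
    standard time-domain (RMSSD, SDNN) and frequency-domain (VLF, LF, HF, TP)
    HRV metrics from evenly resampled tachograms, evaluates fillers by
    relative metric error on a fixed test-window protocol, and selects
    hyperparameters by grid search minimising the summed LF and HF band-power
    errors. Includes a seeded synthetic RR-interval generator so the whole
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
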