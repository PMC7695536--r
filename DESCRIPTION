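Package: pirvae
Title: Household Routine Modelling and Anomaly Detection from Ambient Motion Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised modelling of household activity routines from ambient
    passive-infrared (PIR) motion sensors. Binarizes multi-sensor 5-minute
    activation streams into daily 48-slot motion sequences, learns each
    household's regular activity pattern with a long short-term memory (LSTM)
    variational autoencoder, flags anomalous days by a median-plus-IQR
    reconstruction-loss threshold, and derives public-health indicators
    (wake/sleep times, sleep duration, minutes at home, weekend versus weekday
    contrasts). Includes a synthetic-household generator with ground-truth
    anomaly labels so the full pipeline is testable without proprietary
    smart-thermostat data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
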