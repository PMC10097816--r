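Package: walkstress
Title: Location-Based Collective Pedestrian Distress from Geocoded Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for capturing location-based collective pedestrian
    distress from geocoded wearable biosignals (electrodermal activity, gait
    accelerometry, blood volume pulse). Implements per-channel preprocessing
    (Bateman smoothing and quality screening of EDA, Butterworth filtering and
    walking-interruption detection for IMU, wavelet artifact removal and heart
    rate estimation for BVP), raw and saliency (PSC) feature extraction with
    bottom-up time-series segmentation, stimulus-anchored window statistics
    (linear mixed-effects models and per-type t-tests over 5-240 s windows),
    and street-segment level classification of self-reported negative
    environmental stimuli (Gaussian naive Bayes, fivefold cross-validation,
    unweighted average recall, 1-150 m segment-length sweep). Ships a
    deterministic synthetic study generator so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    broom,
    readr,
    xml2
Config/testthat/edition: 3
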