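Package: phasorckm
Title: Circadian Light-Activity Phasor Analysis and Cardio-Kidney-Metabolic Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies circadian alignment between ambient light exposure and
    physical activity from minute-level actigraphy using phasor analysis
    (circular cross-correlation and its 24-hour Fourier component), stages
    participants on the cardio-kidney-metabolic (CKM) 0-4 continuum by explicit
    clinical rules including KDIGO chronic kidney disease risk categories, and
    estimates survey-weighted associations of phasor-magnitude quartiles with
    advanced CKM syndrome and with all-cause, cardiovascular and premature
    mortality via design-based logistic and Cox proportional-hazards regression
    with Taylor-linearized variance, restricted cubic splines, stratified fits
    and predicted survival curves. A synthetic-data module generates actigraphy,
    clinical, survival and survey-design data with known ground truth so the
    whole pipeline is testable end to end.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    foreign,
    sandwich,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
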