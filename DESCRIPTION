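Package: circacm
Title: Ambulatory Circadian Monitoring with the Integrated TAP Variable
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for week-long ambulatory circadian monitoring
    (ACM) recordings of wrist skin temperature and arm tilt. Reads device-style
    logs, derives motor activity and body position from tilt angles, filters
    and regularizes all channels onto a common 10-minute grid, integrates them
    into the TAP variable (inverted Temperature, Activity, Position), and
    computes the non-parametric circadian parameters (interdaily stability,
    intradaily variability, relative amplitude, circadian function index,
    M10/L5 and their phase markers). Includes a one-decision information-gain
    threshold screener with repeated train/test split evaluation and ROC/AUC,
    and a seeded simulator of sleep-disordered-breathing phenotypes (arousal
    bursts at an AHI-linked Poisson rate, day-to-day phase jitter, CPAP
    attenuation) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
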