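Package: vaemonitor
Title: Automated Venous Air Embolism Detection from Chest Impedance Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Time-domain analysis of transthoracic electrical impedance for
    automated intraoperative venous air embolism (VAE) monitoring. Converts
    raw voltage-divider measurements to impedance, tracks the respiratory
    cycle with wavelet-based peak detection, summarises each breath with
    robust percentile estimates of end-inspiratory and end-expiratory
    impedance, and scores two complementary signatures of air entrainment:
    brief impedance "blips" from large boluses and gradual matched rises in
    both end-inspiratory and end-expiratory impedance. A heuristic signal
    quality index gates alarms, an absolute-rise path covers unventilated
    (apnoeic) periods, and a seeded waveform simulator generates ventilated
    traces with injectable VAE events, ventilator maneuvers and artifacts
    for development and testing. Includes a streaming analysis mode and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
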