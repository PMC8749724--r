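Package: apneasim
Title: Digital-Twin Simulation and Validation of Multisensor Neonatal
    Apnea Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Software twin of a mechatronic test bench for neonatal apnea
    monitors. Generates synthetic abdominal breathing motion (triangular
    stepper displacement with scheduled apnea pauses), impulsive hammer
    vibration noise coupled into ceiling, bed and body accelerometer
    channels, a 12-bit quantized accelerometer chain, and an
    inverse-distance infrared proximity channel. Classifies each breath
    episode as detected or unusable by amplitude comparison against the
    noise reference, optionally rescuing episodes with the infrared
    channel, and tallies nine condition grids (three body angles by three
    displacements). Computes the validation statistics: per-condition
    error odds, displacement-level and overall means with sample
    standard deviations, pooled 2x2 chi-square and odds ratio, checked
    against a packaged reference tally. Includes the deterministic
    monitoring state machine with apnea-alert and rescue timing, caregiver
    survey triage, risk colour coding and 8Ws-structured alert records,
    plus a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
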