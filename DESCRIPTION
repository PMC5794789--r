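Package: flotone
Title: Audio-Based Assessment of Pressurised Metered Dose Inhaler User
    Technique
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Frame-based classification of pressurised metered dose
    inhaler (pMDI) sound events (actuation, inhalation, exhalation,
    noise) by quadratic discriminant analysis with per-recording noise
    estimation and inhalation-model adaptation; acoustic estimation of
    peak inspiratory flow rate (PIFR) and inhaled volume from the
    harmonic Flo-Tone mouthpiece sound via a fitted power-law model;
    sequential forward feature selection under a weighted event-level
    performance measure; detection of the two critical user-technique
    errors (poor actuation coordination and inhaling faster than 90
    L/min); and a seeded synthetic recording generator with known flow
    profiles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
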