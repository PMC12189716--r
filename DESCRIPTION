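Package: lenstock
Title: Length-Based Stock Assessment for Data-Limited Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for length-based assessment of exploited fish populations:
    length-weight allometry and von Bertalanffy growth fitting, derived growth
    quantities (inflection-point age, critical age, growth performance index),
    Beverton-Holt mean-length total mortality and Pauly empirical natural
    mortality, relative yield- and biomass-per-recruit analysis with E-max,
    E-0.1 and E-0.5 reference points, yield isopleths over length at first
    capture, and minimum-catchable-length advice. Includes an individual-based
    simulator of exploited populations for end-to-end validation against known
    truth, and ANCOVA-style homogeneity tests for comparing relationships
    across river or stock groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
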