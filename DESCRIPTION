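Package: asgo
Title: Scoring and Psychometric Validation of the ASGO Hospital Dependence Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes the General Assessment of the Hospitalised Patient (ASGO),
    a 10-variable weighted checklist of non-medical functions, together with the
    Barthel Index of activities of daily living, and provides the psychometric
    validation pipeline used to compare the two instruments: Spearman rank
    correlation, Cronbach's alpha, ROC analysis with the Youden optimal
    cut-off, sensitivity and specificity, Kaiser-Meyer-Olkin sampling
    adequacy, Bartlett's sphericity test, and principal-component exploratory
    factor analysis with varimax rotation. A synthetic-cohort generator with a
    latent dependence trait and planted two-factor structure allows the full
    pipeline to be exercised and tested without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
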