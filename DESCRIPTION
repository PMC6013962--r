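Package: maprmod
Title: Multi-Attribute Preference Response Measurement of Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates values of multi-attribute health states and of
    patients' own health status on a common latent scale from binary
    better/worse preference responses.  Implements the holistic
    multi-attribute preference response (MAPR) model as a Rasch model
    fitted by conditional maximum likelihood via elementary symmetric
    functions, and its attribute-parameterized variant as a linear
    logistic test model (LLTM) in which state values are linear in
    dummy-coded attribute levels.  Includes person-parameter maximum
    likelihood estimation with asymptotic standard errors, Andersen's
    likelihood-ratio test, nested Rasch-versus-LLTM likelihood-ratio
    tests, response-matrix conditioning checks, Guttman scalogram
    summaries, adaptive comparator selection, ranking-to-binary
    conversion, and a seeded simulator for model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
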