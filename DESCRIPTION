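Package: dairydisagg
Title: Disaggregation of Dairy from Composite Foods in Dietary Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes composite foods into dairy ingredients via a
    hierarchical recipe database, estimates survey-weighted per-capita dairy
    intake with and without disaggregation, and converts intakes into
    milk-equivalent litres and annual greenhouse-gas emissions. Includes a
    synthetic-data generator with recorded ground truth for testing the
    full pipeline without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
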