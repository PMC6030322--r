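Package: floodmark
Title: Waterlogging Damage-Severity Marker Genes from Two-Library RNA-Seq and qPCR Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for selecting stress damage-severity marker
    genes in grapevine under waterlogging: replicate-free two-library
    differential expression via the MA-plot random-sampling binomial model
    with an exact conditional oracle and Benjamini-Hochberg FDR control,
    2^-ddCt qPCR quantification with standard-curve support, monotone
    (continual) trend screening of expression time courses with a
    discriminability filter, recovery-assay critical-time estimation with a
    logistic survival model, sharp-signal marker designation aligned to the
    critical time, and a recoverable/irrecoverable damage prediction rule.
    Includes a synthetic-data generator reproducing the statistical
    structure each stage assumes, so the whole pipeline runs and is tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
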