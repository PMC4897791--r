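Package: rumblr
Title: Source-Filter Acoustic Analysis of Male Elephant Rumbles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing low-frequency elephant rumble
    vocalizations under the source-filter framework: fundamental
    frequency contour tracing and feature extraction, LPC-based formant
    estimation with vocal tract length, potential-of-individual-coding
    (PIC) and ANOVA variable screening, PCA reduction with varimax
    rotation, and permuted discriminant function analysis (pDFA) for
    nested and restricted designs. Includes a synthetic source-filter
    rumble generator and cohort simulator with known ground truth so
    the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
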