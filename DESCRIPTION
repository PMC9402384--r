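Package: lymphri
Title: Age-Partitioned Reference Intervals for Pediatric Lymphocyte Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Establishes and verifies clinical reference intervals for
    peripheral blood lymphocyte subsets in children, following the CLSI
    EP28-A3c workflow: skewness/kurtosis normality screening, Box-Cox
    transformation of skewed analytes, Tukey-fence outlier elimination,
    sex and age partition testing with the Harris-Boyd z* criterion,
    nonparametric 2.5th/97.5th percentile interval estimation, and
    40-per-group cohort verification. Includes a split-lognormal synthetic
    cohort generator parameterized from published pediatric
    immunophenotyping percentiles so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
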