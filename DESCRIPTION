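Package: jedr
Title: Jackknife Expression Difference Diagnostics for Expression Preprocessing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for between-array numerical dependence introduced by
    microarray preprocessing methods. Implements the Jackknife Expression
    Difference (JED), a per-gene, per-array-pair statistic computed by
    re-running a preprocessing method with each array left out in turn,
    together with built-in preprocessing methods (a strictly per-array
    summarizer, a quantile-normalization plus median-polish pipeline, and the
    MINDEP two-way ANOVA method whose summary covariance has a closed form),
    the negative-summary reset rule and sign-change bookkeeping, a power
    analysis contrasting ordinary and weighted least squares under
    compound-symmetric dependence, seeded synthetic probe-level data
    generators, and delimited-text readers, writers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
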