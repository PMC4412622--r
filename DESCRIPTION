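Package: binpat
Title: Binary Expression Patterning of Staged RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes into binary expression patterns across an
    ordered series of experimental stages (for example the four stages of
    the crustacean molt cycle) from a raw read-count matrix. Implements
    median-of-ratios library-size normalization, per-gene negative-binomial
    dispersion estimation with a mean-dispersion trend, conditional
    negative-binomial exact tests for all pairwise stage contrasts, binary
    pattern assignment under significance and minimum-read cutoffs with an
    explicit grey-area outcome, pattern-abundance summaries, and per-pattern
    term over-representation with an FDR-then-nominal significance fallback
    and reduction to most-specific terms. A negative-binomial simulator with
    planted patterns and planted term enrichments supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
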