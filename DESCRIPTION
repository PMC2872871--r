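Package: congenicDE
Title: Differential Expression and Concordance Analysis for Reciprocal
    Congenic Strain Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cis-regulated candidate genes inside an introgressed
    QTL interval from paired reciprocal congenic expression experiments.
    Provides probe-set classification by genomic interval (cis/trans/unplaced),
    detection-call filtering, per-region and region-averaged two-group testing
    (Student, Welch, and a moderated t with moment-matched variance shrinkage),
    Benjamini-Hochberg FDR control per testing family, signed fold-change
    conventions, cross-experiment concordance filtering with dual-significance
    and direction-consistency rules, a probe-level screen for SNP-driven
    hybridization artifacts, and a synthetic-data generator that emulates the
    paired congenic designs with known ground truth.
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
    limma,
    optparse
Config/testthat/edition: 3
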