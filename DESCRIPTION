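Package: mitoscreen
Title: Label-Free Spectral-Count Screen for Sperm Mitophagy Candidate Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative proteomics pipeline for cell-free co-incubation
    experiments that screen for post-fertilization sperm-mitophagy candidate
    proteins. Converts per-replicate protein spectral-count tables into a
    classified candidate inventory: per-sample detection filtering, two-stage
    normalization (outer-dense-fiber reference scaling followed by mean
    scaling), paired t-tests of primed-control versus extract-treated sperm
    across biological replicates, presence/absence protein classification
    (extract-derived binders, increased, and degraded proteins),
    cross-timepoint inventory merging with overlap accounting, and functional
    category summaries. Includes a negative-binomial spectral-count simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
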