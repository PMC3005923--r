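Package: seqtileqc
Title: Spatial and Cycle-Resolved Quality Control for Deep Sequencing Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control for deep sequencing runs performed on
    two-dimensional surfaces (Illumina flowcell tiles, SOLiD slide panels).
    Computes spatial base/color-code composition maps, per-cycle composition
    and quality trends, cross-tile stacked x-y summaries that expose
    repetitive optical or fluidic artifacts, a fixed-grid chi-square
    unevenness score for ranking problematic tiles, alignment-derived hit
    tallies and per-cycle mismatch rates, paired-end/mate-pair library QC
    with chimera classification and strand-split insert-size distributions,
    and spatial mapping of user-defined read lists against the whole-sample
    distribution. Includes a synthetic flowcell generator with known
    injected biases for validation, a static three-layer HTML report, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    Biostrings,
    Rsamtools,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
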