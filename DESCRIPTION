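Package: hydrolnc
Title: Hydrotime Germination Modelling and lncRNA Discovery for Drought
    Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying drought response during seed germination
    and its transcriptomic basis. Implements the hydrotime threshold model
    of germination (per-seed base water potentials, probit-linearised
    parameter estimation across water potentials), germination-curve
    summary metrics (t50, U7525, AUC), a long non-coding RNA
    identification filter cascade with positional classification,
    FPKM quantification and differential-expression calling with
    Benjamini-Hochberg control, expression-correlation target prediction
    with bipartite regulatory-network assembly, 2^-ddCT qPCR
    quantification, and seeded synthetic-data generators with
    ground-truth ledgers for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
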