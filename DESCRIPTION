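Package: selexkit
Title: HT-SELEX Library Design Checks and Exhaustive K-Mer Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput sequencing SELEX (HT-SELEX) experiments
    that determine DNA-binding protein specificities in vitro. Models the SELEX
    and Illumina sequencing-library constructs (in-silico PCR of templates and
    primers, i7 barcode extraction and validation, demultiplexing), re-implements
    the read pre-processing used for 20 bp random-insert libraries (quality tail
    trimming, hard trim to insert length), quantifies the abundance of all 4^k
    k-mers per sample, computes cycle-0-normalised fold changes with no-protein
    negative controls and A/T-content category summaries, determines sufficient
    sequencing depth by sub-sampling rank concordance (Spearman R squared), and
    generates fully seeded synthetic multi-cycle SELEX datasets so the entire
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
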