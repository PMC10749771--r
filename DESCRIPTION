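Package: hostsweep
Title: Host Read Decontamination for Microbial Sequencing Data
Version: 0.1.0
Authors@R:
    person("hostsweep", "developers", email = "dev@hostsweep.invalid",
           role = c("aut", "cre"))
Description: Removes host (human) reads from short- and long-read microbial
    FASTQ data by subtractive alignment against a host reference genome,
    with pair-aware mate removal, optional integer read renaming,
    conservation-checked accounting and JSON run reports. Includes a
    microbe-masked reference builder, deterministic Illumina-like and
    nanopore-like read simulators with truth-labelled read names, and a
    truth-based retention/removal evaluation harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
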