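Package: methylign
Title: Three-Letter Bisulfite Read Alignment and Methylation Profiling
Version: 0.1.0
Authors@R:
    person("Methylign", "Developers", email = "methylign@example.org",
           role = c("aut", "cre"))
Description: Aligns bisulfite-treated sequencing reads with the three-letter
    strategy: the reference genome is transformed into four converted genomes
    (Watson/Crick x C-to-T/G-to-A), reads are converted in silico and mapped
    against the compatible genomes, and the uniquely-least-mismatch placement
    is retained while ambiguous reads are discarded. Per-read methylation is
    called against the unconverted reference in CpG/CHG/CHH contexts and
    written as SAM plus per-site level tables. Includes a deterministic
    hash-partitioned execution engine with optional load rebalancing, a
    bisulfite read simulator with truth records and a positional
    exponential-decay error model, and mapping-quality evaluation metrics
    (mappability, precision, sensitivity, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
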