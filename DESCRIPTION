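Package: hairpinMeth
Title: Double-Stranded CpG Methylation Analysis from Hairpin-Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analyses hairpin-bisulfite amplicon sequencing of CpG dyads:
    linker detection and bisulfite-aware alignment of both strands of each
    molecule, discrimination of unmethylated, hemimethylated, fully methylated
    and mutated (CpG-to-TpG) dyads, non-CpG (CpA) methylation statistics, and a
    hidden Markov model of methylation inheritance across cell generations that
    estimates per-enzyme (Dnmt1/Dnmt3a/Dnmt3b) maintenance and de novo
    methylation efficiencies by joint maximum likelihood over knockout cell
    lines. Includes a ground-truthed synthetic-data generator for dyad-state
    populations and rendered hairpin reads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    MASS,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
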