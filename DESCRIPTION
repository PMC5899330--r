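Package: neoprior
Title: Neoepitope Novelty Metrics and Immunogenicity Modeling
Version: 0.1.0
Authors@R:
    person("Morgan", "Reed", email = "morgan.reed@example.org",
           role = c("aut", "cre"))
Description: Prioritization of candidate tumor neoepitopes by peptide novelty.
    Implements four novelty metrics for missense-derived MHC class I
    neoepitopes: the tumor vs. paired normal binding-affinity difference with
    a putatively-novel-binding-change classifier, anchor-masked self-normalized
    BLOSUM62 sequence similarity, and exact ungapped fixed-length homology
    search against human, bacterial, and viral peptide databases with tie
    retention and gene-of-origin match status. Also provides population-level
    accounting (cross-patient neoepitope recurrence, random six-allele HLA-set
    binding-overlap spectra, a simulated-neoepitope null), a linear
    (probability) model of peptide-specific immunogenicity with rank-based
    AUROC evaluation, deterministic synthetic-data generators for desk-scale
    testing, and a file-based command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
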