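Package: parvoscreen
Title: Discovery and Classification of Parvovirus-Related Sequences in
    Transcriptomes and Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A planted-truth-validated pipeline for discovering
    parvovirus-related sequences (PRSs) in transcriptome and genome
    assemblies and classifying them as extant-virus candidates, intact
    endogenous integrations, or degraded endogenous "fossil" elements.
    Provides a seeded six-frame translated homology search with
    Karlin-Altschul E-value statistics, reciprocal-hit confirmation
    against a decoy-augmented reference panel, genomic cross-referencing
    with stop-codon, frameshift and transposable-element flank evidence
    gathering, identity-bin and host-lineage contamination triage, and
    SF3-helicase-domain phylogenetics (progressive multiple alignment,
    neighbor joining, bootstrap support, outgroup rooting). Includes a
    fully seeded synthetic benchmark generator that plants viral
    transcripts, intact and degraded integrations, and cross-host
    contaminants with a machine-readable truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
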