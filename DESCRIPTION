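Package: panfam
Title: Pan-Genome Gene Family Analysis: Presence/Absence, Selection,
    Structural Variation and Expression Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a gene family across a pan-genome of
    related diploid genomes. Identifies typical and atypical family
    members from profile-HMM domain hit tables, classifies genes into
    core, variable and genome-specific presence/absence (PAV) classes,
    estimates Ka, Ks and their ratio for ortholog CDS pairs by the
    Nei-Gojobori (1986) counting method with Jukes-Cantor correction,
    annotates structural variants (DEL/INS/DUP/INV/TRA) against
    2-kb-extended gene territories split into seven region categories,
    tests SV-expression associations and spatiotemporal expression
    patterns in ovule and root samples, builds transcription-factor
    co-expression networks, and counts IUPAC cis-regulatory elements in
    2000-bp promoters. A seeded simulator generates a complete synthetic
    pan-genome fixture (GFF3, FASTA, domtblout, SV and expression tables)
    with known ground truth so every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
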