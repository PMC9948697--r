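Package: lipomine
Title: Mining and Classification of Pseudomonas Lipopeptide NRPS Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects lipopeptide biosynthetic gene clusters in annotated
    Pseudomonas genomes by their diagnostic nonribosomal peptide synthetase
    (NRPS) architecture (tandem thioesterase termination, absence of
    standalone epimerization domains) and flanking-gene synteny
    (LuxR-family regulators, pleABC export genes), predicts the encoded
    peptide from adenylation-domain homology under the collinearity rule,
    assigns products to the 13 chemical lipopeptide families and their
    superfamilies, quantifies congruence between NRPS and rpoD phylogenies,
    detects module-level diversification events (duplication, deletion,
    exchange), and dereplicates products by HSQC CH-alpha fingerprint
    matching. Ships a versioned knowledge base of family definitions and
    peptide variants plus seeded synthetic-data generators so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
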