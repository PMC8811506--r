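Package: homeologdiv
Title: Homeolog Expression and Sequence Divergence in Allotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fate of duplicated genes (homeologs) after
    allopolyploid whole-genome duplication, developed around the chemokine
    ligand/receptor repertoire of the allotetraploid frog Xenopus laevis.
    Provides subgenome retention and pair/singleton accounting from a packaged
    gene catalog; a two-clutch transcriptome correlation workflow that floors
    and log-transforms TPM expression profiles and classifies homeolog pairs
    into high/no-correlation by same/different-expression categories (Pearson
    correlation and paired t tests) with cross-replicate reconciliation; a
    pairwise dN/dS estimator based on equal-pathway synonymous/nonsynonymous
    counting with Jukes-Cantor correction for positive-selection screening; and
    seeded simulators for homeolog expression matrices and codon alignments
    evolved under a target dN/dS, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
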