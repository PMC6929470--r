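Package: omegak
Title: Selection-Intensity and Branch-Site Selection Analysis on Codon
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood codon-model tests for shifts in selective
    pressure on designated foreground (test) branches of a phylogeny. Fits
    an MG94xHKY mixture model in which every dN/dS category omega is raised
    to a branch-class exponent k on test branches (k < 1 relaxed, k > 1
    intensified selection), plus a simplified adaptive branch-site test for
    episodic diversifying selection. Includes an orthogroup construction
    and filtering pipeline for transcriptome-derived coding sequences,
    downstream Gene Ontology statistics (per-term k tests, Fisher
    enrichment, overlap hypergeometrics, permutation GSEA on transformed k
    scores), and a seeded forward simulator of codon alignments and whole
    synthetic orthogroup studies with planted selection classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
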