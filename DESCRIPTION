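Package: rnasmc
Title: Structural Element Comparison of RNA Secondary Structures and
    SNP-Induced Structural Disruption Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how single-nucleotide variants and haplotypes perturb
    RNA secondary structure. Secondary structures (Vienna dot-bracket or CT
    files) are decomposed into five element kinds (stem, hairpin, interior
    loop, bulge, multibranch loop); two decompositions are compared with the
    RNAsmc similarity score, a 0-10 statistic summing a positional Jaccard
    term and an element-count ratio per kind. Two empirical significance
    schemes rank the observed wild-type/mutant score against permutation
    backgrounds: RS1 shuffles the sequence flanking the variant sites, RS2
    enumerates all 3N single-point mutants. A deterministic Nussinov-style
    base-pair-maximization folder is built in, with an adapter contract for
    external thermodynamic folders. SNPs given as 25-nt dbSNP-style flank
    reads are repositioned onto transcripts by exact matching with the
    flank-start distance rule. A fixture generator produces reproducible
    synthetic transcripts, planted SNPs, and flank reads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
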