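Package: HomoeoDel
Title: Deletion Stacking Genetics and Homoeologue-Specific Deletion Calling
    in Hexaploid Wheat
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse genetics with physically induced deletions in
    allohexaploid bread wheat. Models the segregation of homoeologous
    deletions through crosses under a hemizygote-blind detection assay and
    tests observed F2 progeny counts for incompatibility with per-class
    chi-square goodness of fit; calls homoeologue-specific SNPs and gene
    deletions from amplicon sequencing reads using wild-type and
    nullisomic-tetrasomic aneuploid controls; infers minimum and maximum
    deletion-interval sizes from the intactness of a synteny-anchored
    flanking-marker panel; and classifies synteny conservation from homology
    hit tables. A seeded synthetic-data generator produces homoeologous
    reference triplets, control and mutant genotypes, amplicon reads, and F2
    populations with known ground truth so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, VariantDetection, Software
RoxygenNote: 7.3.3
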