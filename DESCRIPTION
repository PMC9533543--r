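Package: karyevol
Title: Ancestral Karyotype Reconstruction, Chromosome Rearrangement
    Classification, and Gene-Tree Discordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying karyotype evolution from gene order data:
    a genome-evolution simulator (polyploidy, chromosome fusions and
    fissions, inversions, fractionation, multispecies-coalescent gene
    trees, GTR sequence evolution, synonymous-divergence emission),
    collinear-block detection and collinearity-ratio matrices, ancestral
    karyotype reconstruction by chromosome clustering and reference
    augmentation, karyotype projection with copy labelling, fusion-type
    classification (end-end joining, reciprocal arm translocation,
    nested fusion) with shared-versus-independent fusion tests,
    syntenic-depth and Ks-peak polyploidy inference, and per-node
    decomposition of gene-tree discordance into estimation error,
    incomplete lineage sorting, and hybridization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
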