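Package: ecag
Title: Environmental Clusters of Adjacent Genes from Metagenomic Gene
    Co-Abundance and Genome Synteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the gene repertoires of marine picocyanobacteria
    (Prochlorococcus, Synechococcus) to their oceanic niches. Provides
    read-count normalization to single-copy-marker (petB) relative gene
    abundance, Bray-Curtis/Ward station clustering with Mantel congruence
    tests against taxon (ESTU) profiles, weighted gene co-abundance
    network analysis (soft-thresholded adjacency, topological overlap,
    module eigengenes, module-trait correlation), gene-order synteny
    edges across reference genomes, and the delineation of eCAGs:
    environmental clusters of adjacent genes that are both syntenic in
    reference genomes and co-distributed in situ. A synthetic pangenome
    and community generator with recorded ground truth makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    igraph,
    mclust,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
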