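Package: superscaf
Title: Homology-Guided Super-Scaffolding of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processes de novo transcriptome assemblies for organisms
    without a reference genome. Transcript fragments that share significant
    protein homology (BLAST hits against a protein database) are joined into
    annotated super-contigs by clustering the bipartite fragment-protein hit
    graph with iterative minimum-label propagation. Each cluster is annotated
    with its nearest homolog (lowest e-value hit) and edge-weight statistics,
    and per-cluster expression is estimated by aggregating assembler
    read-on-contig records. Includes a planted-truth fixture generator, a
    command-line interface, and ggplot2/broom-style methods for results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
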