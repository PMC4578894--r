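# superscaf

Homology-guided "super-scaffolding" for de novo transcriptome assemblies of
organisms without a reference genome.

De novo assemblers (SOAPdenovo-Trans, Trinity, Velvet/Oases, ...) join reads
only where nucleotide context overlaps, so low coverage, high polymorphism or
poor RNA quality leave a transcriptome shattered into hundreds of thousands
of fragments. Many of those fragments, however, encode different parts of the
same protein — or of homologous proteins in distantly related species. A
translated BLAST search of the fragments against a protein database (e.g.
SwissProt) makes that relation explicit, and `superscaf` uses it to brace
non-overlapping fragments into annotated super-contigs.

## The model

Each retained BLAST hit is an edge of a bipartite graph connecting a query
fragment vertex to a database-protein vertex. Hits with e-value above the
cutoff (default 0.001, inclusive: keep *e* ≤ 0.001) are discarded, and
duplicated edges — a second hit between the same query and the same subject,
pointing at a different homologous region — are collapsed to the
lowest-e-value representative.

Clustering is iterative minimum-label propagation: all *N* edges start with
labels 1..*N*; in each sweep, any two edges sharing a vertex both take the
smaller of their two labels (if the edge labeled 45 shares a protein vertex
with the edge labeled 328, both become 45). Sweeps repeat until no label
changes, then labels are renumbered consecutively 1..*K*. The converged
partition is exactly the connected components of the fragment–protein graph:
all fragments linked — directly or through intermediate proteins and
fragments — form one super-contig. Each cluster is annotated with its
**nearest homolog**, the subject of its lowest-e-value hit, and with
min/max/mean edge weight (−log₁₀ e-value, capped at 300). Expression is
estimated crudely by counting the assembler's read-on-contig records per
fragment and summing them over each cluster's members.

The known tradeoff: closely related paralogs and splice forms can merge into
one cluster. That is acceptable for a first functional map of an unknown
transcriptome, and separating them is out of scope here.

## Worked example

Everything is tabular and pipe-friendly. On a synthetic instance with five
planted clusters:

```r
library(superscaf)

inst <- simulate_instance(n_components = 5, seed = 1)
et <- filter_edges(inst$edges)      # e-value cutoff + duplicate collapse
edge_provenance(et)
#>               raw threshold_removed duplicate_removed          retained
#>                36                 3                12                21

cl <- cluster_edges(et)
glance(cl)
#>   n_edges n_fragments n_proteins n_clusters n_iterations
#> 1      21          13         11          5            3

records <- annotate_clusters(cl,
  read_counts = quantify_clusters(inst$read_records, cl))
dplyr::select(records, cluster_id, n_fragments, nearest_homolog,
              nearest_evalue, n_edges, read_count)
#>   cluster_id n_fragments nearest_homolog nearest_evalue n_edges read_count
#> 1          1           2 sp|P0002_01           7.51e-47       2         13
#> 2          2           2 sp|P0001_03           7.39e-39       5         27
#> 3          3           5 sp|P0005_01           5.14e-48       5         34
#> 4          4           2 sp|P0003_01           2.26e-35       5         13
#> 5          5           2 sp|P0004_02           9.25e-36       4         22
```

Of 36 raw hit lines, 3 exceeded the 0.001 cutoff and 12 were duplicates,
leaving 21 edges that converged in 3 sweeps into the 5 planted clusters. Each
row is one super-contig: its member fragment count, the protein that best
identifies it, the strength of that best hit, and its total read count (the
abundance estimate). `write_cluster_table(records, "clusters.tsv")` writes
the tab-delimited output table; `autoplot(cl)` and
`plot_expression_profile(records)` show cluster sizes and the abundance
distribution.

For real data, start from your own files instead of the generator:

```r
edges <- read_blast_tabular("blast_hits.tsv")     # blastx -outfmt 6
reads <- read_read_matches("readOnContig.gz", dialect = "soap")
```

or from a shell:

```sh
Rscript inst/scripts/superscaf.R quantify \
  --blast blast_hits.tsv --reads readOnContig.gz --out clusters.tsv
```

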