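# Build a minimal valid edge tibble from id vectors; other columns get
# plausible constants unless overridden.
make_edges <- function(query_id, subject_id, evalue = 1e-10,
                       bit_score = 100) {
  n <- length(query_id)
  tibble::tibble(
    query_id = query_id,
    subject_id = subject_id,
    percent_identity = rep_len(90, n),
    alignment_length = rep_len(100L, n),
    mismatches = rep_len(5L, n),
    gap_opens = rep_len(0L, n),
    q_start = rep_len(1L, n),
    q_end = rep_len(300L, n),
    s_start = rep_len(1L, n),
    s_end = rep_len(100L, n),
    evalue = rep_len(evalue, n),
    bit_score = rep_len(bit_score, n)
  )
}

# Canonical form of a labelled partition: sorted member sets, ordered by
# their smallest member, so two labelings compare as set partitions.
partition_sets <- function(ids, labels) {
  s <- lapply(split(ids, labels), function(x) sort(unique(x)))
  unname(s[order(vapply(s, `[[`, character(1L), 1L))])
}

# Combined fragment+protein partition of a clustering, as canonical sets.
clustering_partition <- function(cl) {
  ids <- c(cl$fragment_clusters$query_id, cl$protein_clusters$subject_id)
  labels <- c(cl$fragment_clusters$cluster, cl$protein_clusters$cluster)
  partition_sets(ids, labels)
}

oracle_partition <- function(edges) {
  comp <- oracle_components(edges)
  partition_sets(comp$vertex_id, comp$component)
}
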