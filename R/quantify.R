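#' Count read placements per fragment
#'
#' Each deduplicated `(read_id, contig_id)` record contributes one count to
#' its contig — or, when a contig-to-scaffold membership table is supplied,
#' to the scaffold the contig belongs to (contigs absent from the membership
#' table count for themselves). Fragments with zero records are absent from
#' the result.
#'
#' @param reads Read-match tibble from [read_read_matches()].
#' @param contig_to_scaffold Optional membership tibble (`contig_id`,
#'   `scaffold_id`) from [read_scaffold_members()]. A contig mapped to two
#'   scaffolds is an error.
#' @return A tibble with columns `fragment_id` and `n_reads`.
#' @export
count_reads_per_fragment <- function(reads, contig_to_scaffold = NULL) {
  recs <- dplyr::distinct(reads, .data$read_id, .data$contig_id)
  if (!is.null(contig_to_scaffold)) {
    dup <- contig_to_scaffold |>
      dplyr::distinct() |>
      dplyr::count(.data$contig_id) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup) > 0L) {
      stop("contig '", dup$contig_id[1L],
           "' is assigned to more than one scaffold", call. = FALSE)
    }
    recs <- recs |>
      dplyr::left_join(dplyr::distinct(contig_to_scaffold),
                       by = "contig_id") |>
      dplyr::mutate(
        fragment_id = dplyr::coalesce(.data$scaffold_id, .data$contig_id)
      )
  } else {
    recs <- dplyr::mutate(recs, fragment_id = .data$contig_id)
  }
  dplyr::count(recs, .data$fragment_id, name = "n_reads")
}

#' Aggregate fragment counts to clusters
#'
#' Every fragment braced into a super-contig contributes its read count to
#' that cluster's total. Clusters whose fragments all have zero placements
#' still appear, with count 0. Counts for fragments that belong to no
#' cluster (no retained homology evidence) are summed into an `unassigned`
#' attribute rather than dropped, so counts are conserved:
#' `sum(read_count) + unassigned == sum(counts$n_reads)`.
#'
#' @param counts Per-fragment counts from [count_reads_per_fragment()].
#' @param clustering A `supercontig_clusters` object.
#' @return A tibble `cluster_id`, `read_count` (one row per cluster 1..K)
#'   with attribute `unassigned` (integer total for unclustered fragments).
#' @export
aggregate_to_clusters <- function(counts, clustering) {
  joined <- clustering$fragment_clusters |>
    dplyr::left_join(counts, by = c(query_id = "fragment_id")) |>
    dplyr::mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L))
  per_cluster <- joined |>
    dplyr::group_by(cluster_id = .data$cluster) |>
    dplyr::summarise(read_count = as.integer(sum(.data$n_reads)),
                     .groups = "drop")
  all_clusters <- tibble::tibble(
    cluster_id = seq_len(clustering$n_clusters)
  ) |>
    dplyr::left_join(per_cluster, by = "cluster_id") |>
    dplyr::mutate(read_count = dplyr::coalesce(.data$read_count, 0L))
  unassigned <- counts |>
    dplyr::anti_join(clustering$fragment_clusters,
                     by = c(fragment_id = "query_id")) |>
    dplyr::pull(.data$n_reads) |>
    sum() |>
    as.integer()
  structure(all_clusters, unassigned = unassigned)
}

#' Reads with no cluster assignment
#'
#' @param cluster_counts Result of [aggregate_to_clusters()] or
#'   [quantify_clusters()].
#' @return Integer: total read records on fragments outside every cluster.
#' @export
unassigned_reads <- function(cluster_counts) {
  u <- attr(cluster_counts, "unassigned")
  if (is.null(u)) {
    stop("no unassigned attribute; was this produced by ",
         "aggregate_to_clusters()?", call. = FALSE)
  }
  u
}

#' Per-cluster expression estimate from read placements
#'
#' Convenience wrapper chaining [count_reads_per_fragment()] and
#' [aggregate_to_clusters()]. The estimate is deliberately crude: raw record
#' counts, no length or depth normalization. A read whose records land on
#' contigs in different clusters is counted once in each (multi-mapping is
#' not resolved); the total of such reads is reported in the
#' `multi_cluster_reads` attribute so inflation can be judged.
#'
#' @inheritParams count_reads_per_fragment
#' @param clustering A `supercontig_clusters` object.
#' @return As [aggregate_to_clusters()], with an extra attribute
#'   `multi_cluster_reads`.
#' @examples
#' inst <- simulate_instance(n_components = 3, seed = 11)
#' cl <- filter_edges(inst$edges) |> cluster_edges()
#' quantify_clusters(inst$read_records, cl)
#' @export
quantify_clusters <- function(reads, clustering, contig_to_scaffold = NULL) {
  counts <- count_reads_per_fragment(reads, contig_to_scaffold)
  out <- aggregate_to_clusters(counts, clustering)
  recs <- dplyr::distinct(reads, .data$read_id, .data$contig_id)
  if (!is.null(contig_to_scaffold)) {
    recs <- recs |>
      dplyr::left_join(dplyr::distinct(contig_to_scaffold),
                       by = "contig_id") |>
      dplyr::mutate(
        fragment_id = dplyr::coalesce(.data$scaffold_id, .data$contig_id)
      )
  } else {
    recs <- dplyr::mutate(recs, fragment_id = .data$contig_id)
  }
  multi <- recs |>
    dplyr::inner_join(clustering$fragment_clusters,
                      by = c(fragment_id = "query_id")) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$cluster),
                     .groups = "drop") |>
    dplyr::filter(.data$k > 1L) |>
    nrow()
  attr(out, "multi_cluster_reads") <- as.integer(multi)
  out
}
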