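#' Edge weight from a BLAST e-value
#'
#' The strength of a homology edge is `-log10(evalue)`, capped at 300 for
#' e-values of zero (or below 1e-300): larger weight means stronger evidence
#' that the two endpoints belong together. Per-cluster minimum / maximum /
#' mean of this weight are the "shortest edge", "longest edge" and "average
#' edge length" statistics in the cluster table.
#'
#' @param evalue Numeric vector of e-values (>= 0).
#' @return Numeric vector of weights in (0, 300].
#' @examples
#' edge_weight(c(1e-50, 0.001, 0))
#' @export
edge_weight <- function(evalue) {
  if (any(evalue < 0, na.rm = TRUE)) {
    stop("e-values must be non-negative", call. = FALSE)
  }
  pmin(-log10(pmax(evalue, 1e-300)), 300)
}

#' Annotate clusters with nearest homologs and edge statistics
#'
#' Builds one record per super-contig cluster: its member fragments and
#' proteins, the nearest homolog — the database protein of the cluster's
#' lowest-e-value hit, the proxy for the cluster's identity — and
#' min/max/mean edge weight. Ties on e-value are broken by larger bit score,
#' then lexicographically smallest subject id, so output is deterministic
#' across platforms. Member fragment and protein lists are comma-joined in
#' sorted order.
#'
#' @param clustering A `supercontig_clusters` object from [cluster_edges()].
#' @param edges Edge tibble the clustering was computed on; defaults to the
#'   edges carried inside `clustering`. Must align row-for-row with the
#'   cluster labels.
#' @param read_counts Optional per-cluster counts (tibble `cluster_id`,
#'   `read_count` from [quantify_clusters()]); clusters without counts get 0.
#' @return A tibble with one row per cluster 1..K and columns `cluster_id`,
#'   `n_fragments`, `fragments`, `n_proteins`, `nearest_homolog`,
#'   `nearest_evalue`, `n_edges`, `edge_weight_min`, `edge_weight_max`,
#'   `edge_weight_mean`, `read_count`.
#' @examples
#' inst <- simulate_instance(n_components = 3, seed = 7)
#' filter_edges(inst$edges) |> cluster_edges() |> annotate_clusters()
#' @export
annotate_clusters <- function(clustering, edges = clustering$edges,
                              read_counts = NULL) {
  if (!inherits(clustering, "supercontig_clusters")) {
    stop("clustering must be a supercontig_clusters object", call. = FALSE)
  }
  if (nrow(edges) != nrow(clustering$labels)) {
    stop("edge table (", nrow(edges), " rows) does not match the cluster ",
         "assignment (", nrow(clustering$labels), " labels)", call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    return(empty_cluster_records())
  }
  records <- edges |>
    dplyr::mutate(
      cluster_id = clustering$labels$cluster,
      weight = edge_weight(.data$evalue)
    ) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bit_score),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::summarise(
      n_fragments = dplyr::n_distinct(.data$query_id),
      fragments = paste(sort(unique(.data$query_id)), collapse = ","),
      n_proteins = dplyr::n_distinct(.data$subject_id),
      nearest_homolog = dplyr::first(.data$subject_id),
      nearest_evalue = dplyr::first(.data$evalue),
      n_edges = dplyr::n(),
      edge_weight_min = min(.data$weight),
      edge_weight_max = max(.data$weight),
      edge_weight_mean = mean(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster_id)
  if (is.null(read_counts)) {
    records$read_count <- 0L
  } else {
    records <- records |>
      dplyr::left_join(
        read_counts[, c("cluster_id", "read_count")], by = "cluster_id"
      ) |>
      dplyr::mutate(read_count = dplyr::coalesce(.data$read_count, 0L))
  }
  records
}

#' Expression-profile plot for annotated clusters
#'
#' Per-cluster read counts against cluster rank, on a log10 y axis: the
#' overview used to place transcripts into highly expressed, intermediate
#' and low-expressed categories.
#'
#' @param object Cluster-record tibble from [annotate_clusters()] with
#'   read counts filled in.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_expression_profile <- function(object, ...) {
  dat <- object |>
    dplyr::filter(.data$read_count > 0L) |>
    dplyr::arrange(dplyr::desc(.data$read_count)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$read_count)) +
    ggplot2::geom_point(alpha = 0.5, colour = "darkred") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "cluster rank by abundance", y = "read count (log scale)",
      title = "Estimated transcript abundance per super-contig"
    ) +
    ggplot2::theme_minimal()
}
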