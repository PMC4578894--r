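#' Keep hits at or below an e-value threshold
#'
#' The clustering substrate excludes hits with e-value *higher than* the
#' cutoff (default 0.001), so equality is retained. Input order is preserved.
#'
#' @param edges Edge tibble (see [read_blast_tabular()]).
#' @param max_evalue Inclusive e-value cutoff; must be >= 0.
#' @return The retained rows, in input order.
#' @export
filter_by_evalue <- function(edges, max_evalue = 0.001) {
  if (!is.numeric(max_evalue) || length(max_evalue) != 1L ||
      is.na(max_evalue) || max_evalue < 0) {
    stop("max_evalue must be a single non-negative number", call. = FALSE)
  }
  dplyr::filter(edges, .data$evalue <= max_evalue)
}

#' Collapse duplicated edges
#'
#' A duplicated edge is a second hit between the same query fragment and the
#' same database protein (pointing at a different homologous region of the
#' same pair). Exactly one edge is kept per `(query_id, subject_id)` pair:
#' the lowest e-value representative, ties broken by larger bit score, then
#' first occurrence. Output is ordered by each pair's first occurrence, so
#' deduplication is idempotent and order-stable.
#'
#' @param edges Edge tibble.
#' @return One row per distinct `(query_id, subject_id)` pair.
#' @export
deduplicate_edges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(edges)
  }
  edges |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::mutate(.first = min(.data$.row)) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bit_score), .data$.row,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.first) |>
    dplyr::select(-".row", -".first")
}

#' Filter and deduplicate hits into a clustering-ready edge table
#'
#' Applies the e-value cutoff then collapses duplicated edges, recording
#' provenance counts (raw, removed by threshold, removed as duplicates,
#' retained) as an attribute retrievable with [edge_provenance()].
#'
#' @inheritParams filter_by_evalue
#' @return The retained edge tibble with attributes `provenance`
#'   (named integer vector) and `max_evalue`.
#' @examples
#' edges <- simulate_instance(n_components = 3, seed = 1)$edges
#' et <- filter_edges(edges)
#' edge_provenance(et)
#' @export
filter_edges <- function(edges, max_evalue = 0.001) {
  raw <- nrow(edges)
  thresholded <- filter_by_evalue(edges, max_evalue)
  retained <- deduplicate_edges(thresholded)
  structure(
    retained,
    provenance = c(
      raw = raw,
      threshold_removed = raw - nrow(thresholded),
      duplicate_removed = nrow(thresholded) - nrow(retained),
      retained = nrow(retained)
    ),
    max_evalue = max_evalue
  )
}

#' Provenance counts of a filtered edge table
#'
#' @param edges Result of [filter_edges()].
#' @return Named integer vector: `raw`, `threshold_removed`,
#'   `duplicate_removed`, `retained`.
#' @export
edge_provenance <- function(edges) {
  p <- attr(edges, "provenance")
  if (is.null(p)) {
    stop("no provenance attribute; was this produced by filter_edges()?",
         call. = FALSE)
  }
  p
}
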