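#' @importFrom rlang .data
NULL

# Map fragment/protein ids to a shared integer vertex space.
edge_vertex_index <- function(edges) {
  frag_levels <- unique(edges$query_id)
  prot_levels <- unique(edges$subject_id)
  list(
    v1 = match(edges$query_id, frag_levels),
    v2 = length(frag_levels) + match(edges$subject_id, prot_levels),
    n_vertices = length(frag_levels) + length(prot_levels),
    frag_levels = frag_levels,
    prot_levels = prot_levels
  )
}

# Minimum current edge label per vertex, over incident edges.
vertex_min_labels <- function(labels, idx) {
  v <- c(idx$v1, idx$v2)
  l <- c(labels, labels)
  o <- order(v, l)
  first <- !duplicated(v[o])
  vlab <- rep.int(.Machine$integer.max, idx$n_vertices)
  vlab[v[o][first]] <- l[o][first]
  vlab
}

# One asynchronous (Gauss-Seidel) sweep over the edge indices `rows`,
# updating labels and vertex labels in place semantics via return value.
sweep_chunk <- function(labels, vlab, v1, v2, rows) {
  for (i in rows) {
    m <- labels[i]
    a <- vlab[v1[i]]
    if (a < m) m <- a
    b <- vlab[v2[i]]
    if (b < m) m <- b
    if (m < labels[i]) labels[i] <- m
    if (m < vlab[v1[i]]) vlab[v1[i]] <- m
    if (m < vlab[v2[i]]) vlab[v2[i]] <- m
  }
  list(labels = labels, vlab = vlab)
}

propagate_sweep <- function(labels, idx, workers = 1L) {
  n <- length(labels)
  if (n == 0L) {
    return(list(labels = labels, changed = FALSE))
  }
  vlab0 <- vertex_min_labels(labels, idx)
  workers <- max(1L, as.integer(workers))
  if (workers == 1L) {
    res <- sweep_chunk(labels, vlab0, idx$v1, idx$v2, seq_len(n))
    new_labels <- res$labels
  } else {
    # Equal contiguous shares; each share sweeps against the iteration-start
    # vertex labels (as concurrent workers would), merged by elementwise min.
    shares <- split(seq_len(n), cut(seq_len(n), breaks = min(workers, n),
                                    labels = FALSE))
    new_labels <- labels
    for (rows in shares) {
      res <- sweep_chunk(labels, vlab0, idx$v1, idx$v2, rows)
      new_labels[rows] <- pmin(new_labels[rows], res$labels[rows])
    }
  }
  list(labels = new_labels, changed = any(new_labels < labels))
}

#' One label-propagation sweep
#'
#' All edges are initially labeled 1..N. A sweep visits edges in ascending
#' index order; whenever two edges share a vertex (the same query fragment or
#' the same database protein), both take the smaller of their two labels —
#' e.g. if the edge labeled 45 shares a protein vertex with the edge labeled
#' 328, both end the sweep labeled 45. Labels never increase, so repeated
#' sweeps converge.
#'
#' Because the sweep is asynchronous, a label can travel along a chain of
#' shared vertices within a single sweep; the converged partition is
#' independent of sweep order (see [cluster_edges()]).
#'
#' @param labels Integer vector of current edge labels, one per edge row.
#' @param edges Edge tibble (filtered and deduplicated; see [filter_edges()]).
#' @param workers Number of equal data shares to sweep independently before
#'   merging by minimum. Any value yields the same converged partition.
#' @return A list with `labels` (updated vector) and `changed` (`TRUE` iff
#'   any label decreased).
#' @export
propagate_labels_once <- function(labels, edges, workers = 1L) {
  if (length(labels) != nrow(edges)) {
    stop("labels must have one entry per edge row", call. = FALSE)
  }
  propagate_sweep(as.integer(labels), edge_vertex_index(edges), workers)
}

#' Renumber converged labels consecutively
#'
#' Distinct labels are sorted ascending and mapped to ranks 1..K, so clusters
#' keep the order of their smallest pre-relabel label (with initial labels
#' equal to edge indices, that is the order of each cluster's first edge).
#' The partition itself is unchanged.
#'
#' @param labels Integer vector of converged edge labels.
#' @return Integer vector over 1..K with no gaps.
#' @export
relabel_consecutive <- function(labels) {
  match(labels, sort(unique(labels)))
}

#' Cluster homology edges into super-contigs
#'
#' Runs iterative minimum-label propagation over the fragment-protein hit
#' graph until no label changes, then renumbers clusters 1..K. Two edges end
#' in the same cluster exactly when they are connected through shared
#' vertices, so the final partition equals the connected components of the
#' bipartite graph: all fragments that share a match to at least one common
#' database protein (directly or through intermediates) form one
#' super-contig.
#'
#' @param edges Edge tibble, already threshold-filtered and deduplicated
#'   (see [filter_edges()]).
#' @param workers Number of equal data shares per sweep; the result is
#'   identical for every value (the shares are merged by minimum), only the
#'   number of sweeps to convergence may differ.
#' @return An object of class `supercontig_clusters` with components
#'   \describe{
#'     \item{labels}{tibble `edge_index`, `cluster` (final 1..K label).}
#'     \item{fragment_clusters}{tibble `query_id`, `cluster`.}
#'     \item{protein_clusters}{tibble `subject_id`, `cluster`.}
#'     \item{n_clusters}{K.}
#'     \item{n_iterations}{sweeps executed, including the final sweep that
#'       observes no change.}
#'     \item{edges}{the input edge tibble, carried for annotation.}
#'   }
#' @examples
#' inst <- simulate_instance(n_components = 4, seed = 42)
#' cl <- filter_edges(inst$edges) |> cluster_edges()
#' cl
#' glance(cl)
#' @export
cluster_edges <- function(edges, workers = 1L) {
  n <- nrow(edges)
  idx <- edge_vertex_index(edges)
  labels <- seq_len(n)
  n_iterations <- 0L
  repeat {
    if (n == 0L) break
    res <- propagate_sweep(labels, idx, workers)
    n_iterations <- n_iterations + 1L
    labels <- res$labels
    if (!res$changed) break
  }
  cluster <- if (n == 0L) integer() else relabel_consecutive(labels)
  frag_first <- !duplicated(idx$v1)
  prot_first <- !duplicated(idx$v2)
  structure(
    list(
      labels = tibble::tibble(edge_index = seq_len(n), cluster = cluster),
      fragment_clusters = tibble::tibble(
        query_id = edges$query_id[frag_first],
        cluster = cluster[frag_first]
      ),
      protein_clusters = tibble::tibble(
        subject_id = edges$subject_id[prot_first],
        cluster = cluster[prot_first]
      ),
      n_clusters = length(unique(cluster)),
      n_iterations = n_iterations,
      workers = as.integer(workers),
      edges = tibble::as_tibble(edges)
    ),
    class = "supercontig_clusters"
  )
}

#' Connected components of the fragment-protein graph (reference route)
#'
#' Computes the bipartite graph's connected components directly with igraph.
#' This is an independent reference for [cluster_edges()] — the two must
#' always produce the same partition — and is used by the test suite as the
#' verification oracle.
#'
#' @param edges Edge tibble.
#' @return A tibble with columns `vertex_id`, `type` (`"fragment"` or
#'   `"protein"`), and `component` (arbitrary but consistent numbering).
#' @export
oracle_components <- function(edges) {
  if (nrow(edges) == 0L) {
    return(tibble::tibble(vertex_id = character(), type = character(),
                          component = integer()))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("query_id", "subject_id")], directed = FALSE
  )
  comp <- igraph::components(g)
  ids <- names(comp$membership)
  tibble::tibble(
    vertex_id = ids,
    type = ifelse(ids %in% edges$query_id, "fragment", "protein"),
    component = as.integer(unname(comp$membership))
  )
}

#' @export
print.supercontig_clusters <- function(x, ...) {
  cat("Super-contig clustering\n")
  cat("  edges:      ", nrow(x$labels), "\n", sep = "")
  cat("  fragments:  ", nrow(x$fragment_clusters), "\n", sep = "")
  cat("  proteins:   ", nrow(x$protein_clusters), "\n", sep = "")
  cat("  clusters:   ", x$n_clusters, "\n", sep = "")
  cat("  iterations: ", x$n_iterations, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering: one row per edge with its cluster
#'
#' @param x A `supercontig_clusters` object.
#' @param ... Unused.
#' @return A tibble with `edge_index`, `query_id`, `subject_id`, `evalue`,
#'   `cluster`.
#' @export
tidy.supercontig_clusters <- function(x, ...) {
  tibble::tibble(
    edge_index = x$labels$edge_index,
    query_id = x$edges$query_id,
    subject_id = x$edges$subject_id,
    evalue = x$edges$evalue,
    cluster = x$labels$cluster
  )
}

#' One-row clustering summary
#'
#' @param x A `supercontig_clusters` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_edges`, `n_fragments`, `n_proteins`,
#'   `n_clusters`, `n_iterations`.
#' @export
glance.supercontig_clusters <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$labels),
    n_fragments = nrow(x$fragment_clusters),
    n_proteins = nrow(x$protein_clusters),
    n_clusters = x$n_clusters,
    n_iterations = x$n_iterations
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cluster-size distribution plot
#'
#' Histogram of edges per cluster on a log10 x axis; cluster sizes in this
#' kind of data span several orders of magnitude (from singleton hits to
#' large gene families collapsed by shared homology).
#'
#' @param object A `supercontig_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.supercontig_clusters <- function(object, ...) {
  sizes <- dplyr::count(object$labels, .data$cluster, name = "n_edges")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$n_edges)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "edges per cluster (log scale)", y = "clusters",
      title = "Super-contig cluster sizes"
    ) +
    ggplot2::theme_minimal()
}
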