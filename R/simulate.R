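#' Generate a planted homology-graph instance
#'
#' Builds a synthetic BLAST hit table with known cluster structure, plus
#' matching read-on-contig records, so the whole pipeline can be verified
#' against ground truth. Each planted component is a connected bipartite
#' graph of transcript fragments and database proteins (a random spanning
#' tree plus extra random within-component hits); components are
#' vertex-disjoint by construction. Two kinds of noise are injected, neither
#' of which changes the planted partition once the standard filter runs:
#'
#' * duplicate lines — the same query/subject pair re-reported with different
#'   aligned coordinates, at `duplicate_rate`;
#' * super-threshold hits — e-values drawn above the 0.001 cutoff (log-uniform
#'   on `noise_evalue_range`), at `superthreshold_rate`, with endpoints
#'   anywhere in the instance (the filter removes them).
#'
#' True-edge e-values are log-uniform on `evalue_range`
#' (default \[1e-50, 1e-4\]), cleanly separated from the noise range
#' (default \[1e-2, 1\]) around the 0.001 cutoff so the planted truth is
#' unambiguous. `merge_noise_rate` optionally adds *sub*-threshold edges
#' between different components; these do change the connected components,
#' so with it enabled results should be compared against
#' [oracle_components()] rather than the planted partition.
#'
#' @param n_components Number of planted clusters (>= 0).
#' @param fragments_per_component,proteins_per_component Length-2 integer
#'   ranges sampled uniformly per component.
#' @param duplicate_rate,superthreshold_rate,merge_noise_rate Noise rates in
#'   \[0, 1\], as a fraction of the true edge count.
#' @param extra_edge_rate Extra random within-component hits per component
#'   vertex, beyond the spanning tree (density knob).
#' @param evalue_range,noise_evalue_range Log-uniform e-value ranges for true
#'   and super-threshold edges.
#' @param reads_per_fragment Length-2 integer range: reads placed on each
#'   fragment, sampled uniformly.
#' @param seed Required integer seed; output is byte-identical for equal
#'   seeds (the caller's RNG state is untouched).
#' @return A `planted_instance` list: `edges` (hit tibble, shuffled row
#'   order), `true_partition` (tibble `fragment_id`, `component`),
#'   `read_records` (tibble `read_id`, `contig_id`, `position`),
#'   `true_counts` (tibble `component`, `read_count`), `params`.
#' @examples
#' inst <- simulate_instance(n_components = 5, seed = 1)
#' nrow(inst$edges)
#' @export
simulate_instance <- function(n_components = 50,
                              fragments_per_component = c(2L, 6L),
                              proteins_per_component = c(1L, 3L),
                              duplicate_rate = 0.1,
                              superthreshold_rate = 0.1,
                              merge_noise_rate = 0,
                              extra_edge_rate = 0.5,
                              evalue_range = c(1e-50, 1e-4),
                              noise_evalue_range = c(1e-2, 1),
                              reads_per_fragment = c(0L, 20L),
                              seed) {
  if (missing(seed)) {
    stop("a seed is required for reproducible instance generation",
         call. = FALSE)
  }
  rates <- c(duplicate_rate, superthreshold_rate, merge_noise_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_components < 0) {
    stop("n_components must be >= 0", call. = FALSE)
  }
  params <- list(
    n_components = n_components,
    fragments_per_component = fragments_per_component,
    proteins_per_component = proteins_per_component,
    duplicate_rate = duplicate_rate,
    superthreshold_rate = superthreshold_rate,
    merge_noise_rate = merge_noise_rate,
    extra_edge_rate = extra_edge_rate,
    evalue_range = evalue_range,
    noise_evalue_range = noise_evalue_range,
    reads_per_fragment = reads_per_fragment,
    seed = seed
  )
  withr::with_seed(seed, build_instance(params))
}

rint <- function(range, n = 1L) {
  if (range[1] == range[2]) rep.int(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

log_uniform <- function(n, range) {
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

build_instance <- function(p) {
  n_comp <- as.integer(p$n_components)
  if (n_comp == 0L) {
    return(structure(
      list(
        edges = empty_edges(),
        true_partition = tibble::tibble(fragment_id = character(),
                                        component = integer()),
        read_records = tibble::tibble(read_id = character(),
                                      contig_id = character(),
                                      position = integer()),
        true_counts = tibble::tibble(component = integer(),
                                     read_count = integer()),
        params = p
      ),
      class = "planted_instance"
    ))
  }
  comp_q <- vector("list", n_comp)
  comp_s <- vector("list", n_comp)
  partition <- vector("list", n_comp)
  for (k in seq_len(n_comp)) {
    nf <- rint(p$fragments_per_component)
    np <- rint(p$proteins_per_component)
    frags <- sprintf("frag%04d_%02d", k, seq_len(nf))
    prots <- sprintf("sp|P%04d_%02d", k, seq_len(np))
    # random spanning tree over the bipartite vertex set: each new vertex
    # attaches to a random already-placed vertex of the opposite type
    qs <- character(0)
    ss <- character(0)
    in_f <- frags[1L]
    in_p <- prots[1L]
    qs <- frags[1L]
    ss <- prots[1L]
    rest <- sample(c(frags[-1L], prots[-1L]))
    for (v in rest) {
      if (v %in% frags) {
        qs <- c(qs, v)
        ss <- c(ss, if (length(in_p) == 1L) in_p else sample(in_p, 1L))
        in_f <- c(in_f, v)
      } else {
        qs <- c(qs, if (length(in_f) == 1L) in_f else sample(in_f, 1L))
        ss <- c(ss, v)
        in_p <- c(in_p, v)
      }
    }
    n_extra <- round(p$extra_edge_rate * (nf + np))
    if (n_extra > 0L) {
      qs <- c(qs, sample(frags, n_extra, replace = TRUE))
      ss <- c(ss, sample(prots, n_extra, replace = TRUE))
    }
    comp_q[[k]] <- qs
    comp_s[[k]] <- ss
    partition[[k]] <- tibble::tibble(fragment_id = frags, component = k)
  }
  query_id <- unlist(comp_q)
  subject_id <- unlist(comp_s)
  n_true <- length(query_id)
  evalue <- log_uniform(n_true, p$evalue_range)
  true_partition <- dplyr::bind_rows(partition)

  # duplicate lines: same pair, different coordinates / e-value
  n_dup <- round(p$duplicate_rate * n_true)
  if (n_dup > 0L) {
    pick <- sample.int(n_true, n_dup, replace = TRUE)
    query_id <- c(query_id, query_id[pick])
    subject_id <- c(subject_id, subject_id[pick])
    evalue <- c(evalue, log_uniform(n_dup, p$evalue_range))
  }

  # super-threshold noise: removed by the 0.001 filter, endpoints anywhere
  n_noise <- round(p$superthreshold_rate * n_true)
  if (n_noise > 0L) {
    query_id <- c(query_id, sample(unique(unlist(comp_q)), n_noise,
                                   replace = TRUE))
    subject_id <- c(subject_id, sample(unique(unlist(comp_s)), n_noise,
                                       replace = TRUE))
    evalue <- c(evalue, log_uniform(n_noise, p$noise_evalue_range))
  }

  # optional sub-threshold cross-component edges (alter the true components)
  n_merge <- if (n_comp >= 2L) round(p$merge_noise_rate * n_true) else 0L
  if (n_merge > 0L) {
    ka <- sample.int(n_comp, n_merge, replace = TRUE)
    kb <- ((ka + sample.int(n_comp - 1L, n_merge, replace = TRUE) - 1L) %%
             n_comp) + 1L
    query_id <- c(query_id,
                  vapply(ka, function(k) sample(unique(comp_q[[k]]), 1L),
                         character(1L)))
    subject_id <- c(subject_id,
                    vapply(kb, function(k) sample(unique(comp_s[[k]]), 1L),
                           character(1L)))
    evalue <- c(evalue, log_uniform(n_merge, p$evalue_range))
  }

  n <- length(query_id)
  alignment_length <- sample(30:200, n, replace = TRUE)
  percent_identity <- round(stats::runif(n, 35, 100), 1)
  mismatches <- as.integer(round(alignment_length *
                                   (1 - percent_identity / 100)))
  q_start <- sample.int(500L, n, replace = TRUE)
  s_start <- sample.int(300L, n, replace = TRUE)
  edges <- tibble::tibble(
    query_id = query_id,
    subject_id = subject_id,
    percent_identity = percent_identity,
    alignment_length = alignment_length,
    mismatches = mismatches,
    gap_opens = sample(0:3, n, replace = TRUE),
    q_start = q_start,
    q_end = q_start + alignment_length * 3L - 1L,
    s_start = s_start,
    s_end = s_start + alignment_length - 1L,
    evalue = evalue,
    bit_score = round(30 + 1.8 * edge_weight(evalue) +
                        stats::rnorm(n, 0, 4), 1)
  )
  edges <- edges[sample.int(n), ]

  frag_ids <- true_partition$fragment_id
  n_reads_per <- rint(p$reads_per_fragment, length(frag_ids))
  contig_id <- rep(frag_ids, n_reads_per)
  total_reads <- length(contig_id)
  read_records <- tibble::tibble(
    read_id = sprintf("read%07d", seq_len(total_reads)),
    contig_id = contig_id,
    position = sample(0:500, total_reads, replace = TRUE)
  )
  true_counts <- true_partition |>
    dplyr::mutate(n_reads = n_reads_per) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(read_count = as.integer(sum(.data$n_reads)),
                     .groups = "drop")

  structure(
    list(
      edges = edges,
      true_partition = true_partition,
      read_records = read_records,
      true_counts = true_counts,
      params = p
    ),
    class = "planted_instance"
  )
}

#' @export
print.planted_instance <- function(x, ...) {
  cat("Planted homology instance\n")
  cat("  components: ", x$params$n_components, "\n", sep = "")
  cat("  hit lines:  ", nrow(x$edges), "\n", sep = "")
  cat("  fragments:  ", nrow(x$true_partition), "\n", sep = "")
  cat("  reads:      ", nrow(x$read_records), "\n", sep = "")
  invisible(x)
}

#' Write a planted instance as pipeline input files
#'
#' Emits `hits.tsv` (BLAST tabular), `reads.txt` (soap-dialect read matches)
#' and `truth.tsv` (fragment-to-component table, `#`-headed TSV) into a
#' directory.
#'
#' @param instance A `planted_instance`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_instance <- function(instance, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  hits <- file.path(dir, "hits.tsv")
  reads <- file.path(dir, "reads.txt")
  truth <- file.path(dir, "truth.tsv")
  write_blast_tabular(instance$edges, hits)
  writeLines(
    paste(instance$read_records$read_id, instance$read_records$contig_id,
          instance$read_records$position),
    reads, useBytes = TRUE
  )
  writeLines(
    c("#fragment_id\tcomponent",
      paste(instance$true_partition$fragment_id,
            instance$true_partition$component, sep = "\t")),
    truth, useBytes = TRUE
  )
  invisible(c(hits = hits, reads = reads, truth = truth))
}
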