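#' Read standard BLAST tabular output
#'
#' Parses the standard 12-column tabular layout produced by
#' `blastx/blastp -outfmt 6` and friends: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. Each hit is one
#' homology edge connecting a query fragment to a database protein. Lines
#' beginning with `#` are skipped; columns beyond the twelfth are ignored.
#'
#' Identifier comparison downstream is case-sensitive and exact-string, so
#' identifiers are kept verbatim. Fragment and protein identifiers must come
#' from disjoint namespaces: an id that appears both as a query and as a
#' subject would silently merge unrelated graph vertices, so this is rejected
#' at load time.
#'
#' @param path Path to a BLAST tabular file (plain text or `.gz`).
#' @return A tibble with one row per hit and columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`, in file
#'   order. An empty file yields a zero-row tibble.
#' @seealso [write_blast_tabular()], [filter_edges()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200", tf)
#' read_blast_tabular(tf)
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) {
    stop("BLAST tabular file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_edges())
  }
  fields <- strsplit(sub("[ \t\r]+$", "", lines), "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("line ", lineno[bad], ": expected >= 12 tab-separated fields, found ",
         nf[bad], call. = FALSE)
  }
  mat <- vapply(fields, function(f) f[1:12], character(12L))
  num <- function(col, what, integerish = FALSE) {
    x <- suppressWarnings(as.numeric(mat[col, ]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1L]
      stop("line ", lineno[bad], ": non-numeric ", what, " field '",
           mat[col, bad], "'", call. = FALSE)
    }
    x
  }
  edges <- tibble::tibble(
    query_id = mat[1L, ],
    subject_id = mat[2L, ],
    percent_identity = num(3L, "percent-identity"),
    alignment_length = as.integer(num(4L, "alignment-length")),
    mismatches = as.integer(num(5L, "mismatch")),
    gap_opens = as.integer(num(6L, "gap-open")),
    q_start = as.integer(num(7L, "qstart")),
    q_end = as.integer(num(8L, "qend")),
    s_start = as.integer(num(9L, "sstart")),
    s_end = as.integer(num(10L, "send")),
    evalue = num(11L, "e-value"),
    bit_score = num(12L, "bit-score")
  )
  validate_edges(edges, lineno)
  edges
}

empty_edges <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bit_score = numeric()
  )
}

validate_edges <- function(edges, lineno = seq_len(nrow(edges))) {
  fail <- function(idx, msg) {
    stop("line ", lineno[idx], ": ", msg, call. = FALSE)
  }
  if (any(!nzchar(edges$query_id))) {
    fail(which(!nzchar(edges$query_id))[1L], "empty query id")
  }
  if (any(!nzchar(edges$subject_id))) {
    fail(which(!nzchar(edges$subject_id))[1L], "empty subject id")
  }
  if (any(edges$evalue < 0)) {
    fail(which(edges$evalue < 0)[1L], "negative e-value")
  }
  bad_pid <- edges$percent_identity < 0 | edges$percent_identity > 100
  if (any(bad_pid)) fail(which(bad_pid)[1L], "percent identity outside [0, 100]")
  if (any(edges$alignment_length < 1L)) {
    fail(which(edges$alignment_length < 1L)[1L], "alignment length < 1")
  }
  shared <- intersect(unique(edges$query_id), unique(edges$subject_id))
  if (length(shared) > 0L) {
    stop("identifier namespace clash: ", shared[1L],
         " appears as both a query fragment and a database protein",
         call. = FALSE)
  }
  invisible(edges)
}

# %.17g round-trips doubles exactly through as.numeric()
fmt_num <- function(x) sprintf("%.17g", x)

#' Write homology edges as BLAST tabular text
#'
#' Writes the 12 standard columns tab-delimited, no header, so the file is
#' interchangeable with real `-outfmt 6` output and round-trips exactly
#' through [read_blast_tabular()].
#'
#' @param edges Edge tibble as returned by [read_blast_tabular()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(edges, path) {
  lines <- paste(
    edges$query_id, edges$subject_id, fmt_num(edges$percent_identity),
    edges$alignment_length, edges$mismatches, edges$gap_opens,
    edges$q_start, edges$q_end, edges$s_start, edges$s_end,
    fmt_num(edges$evalue), fmt_num(edges$bit_score),
    sep = "\t"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.read_dialects <- list(
  soap = list(
    description = "whitespace-separated: read_id contig_id position [extra ignored]",
    min_fields = 3L, has_position = TRUE
  ),
  tsv2col = list(
    description = "two columns: read_id contig_id",
    min_fields = 2L, has_position = FALSE
  )
)

#' List registered read-on-contig dialects
#'
#' Assemblers differ in how (and whether) they record which raw read was
#' placed on which contig; each supported layout is registered as a named
#' dialect.
#'
#' @return A tibble with columns `dialect` and `description`.
#' @export
list_read_dialects <- function() {
  tibble::tibble(
    dialect = names(.read_dialects),
    description = vapply(.read_dialects, `[[`, character(1L), "description")
  )
}

#' Read read-to-contig match records
#'
#' Parses an assembler's intermediate read-on-contig file (for SOAPdenovo,
#' the `readOnContig` output) into one record per read placement. Duplicate
#' `(read_id, contig_id)` pairs collapse to the first occurrence, so a read
#' contributes at most once per contig when counting.
#'
#' @param path Path to the read-match file (plain text or `.gz`).
#' @param dialect One of [list_read_dialects()]; default `"soap"`.
#' @return A tibble with columns `read_id`, `contig_id`, `position`
#'   (0 when the dialect carries no position).
#' @export
read_read_matches <- function(path, dialect = "soap") {
  if (!dialect %in% names(.read_dialects)) {
    stop("unknown read-match dialect '", dialect, "'; registered dialects: ",
         paste(names(.read_dialects), collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("read-match file not found: ", path, call. = FALSE)
  }
  spec <- .read_dialects[[dialect]]
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(read_id = character(), contig_id = character(),
                          position = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < spec$min_fields)) {
    bad <- which(nf < spec$min_fields)[1L]
    stop("line ", lineno[bad], ": expected >= ", spec$min_fields,
         " fields for dialect '", dialect, "', found ", nf[bad], call. = FALSE)
  }
  read_id <- vapply(fields, `[[`, character(1L), 1L)
  contig_id <- vapply(fields, `[[`, character(1L), 2L)
  if (spec$has_position) {
    pos_chr <- vapply(fields, `[[`, character(1L), 3L)
    position <- suppressWarnings(as.integer(as.numeric(pos_chr)))
    if (anyNA(position)) {
      bad <- which(is.na(position))[1L]
      stop("line ", lineno[bad], ": non-numeric position field '",
           pos_chr[bad], "'", call. = FALSE)
    }
    if (any(position < 0L)) {
      bad <- which(position < 0L)[1L]
      stop("line ", lineno[bad], ": negative position", call. = FALSE)
    }
  } else {
    position <- rep(0L, length(read_id))
  }
  bad_ids <- !nzchar(read_id) | !nzchar(contig_id)
  if (any(bad_ids)) {
    stop("line ", lineno[which(bad_ids)[1L]], ": empty read or contig id",
         call. = FALSE)
  }
  tibble::tibble(read_id = read_id, contig_id = contig_id,
                 position = position) |>
    dplyr::distinct(.data$read_id, .data$contig_id, .keep_all = TRUE)
}

#' Read a contig-to-scaffold membership table
#'
#' Two-column TSV (`contig_id`, `scaffold_id`); `#` lines skipped. The mapping
#' must be a function: a contig listed under two different scaffolds is an
#' error.
#'
#' @param path Path to the membership table.
#' @return A tibble with columns `contig_id` and `scaffold_id`.
#' @export
read_scaffold_members <- function(path) {
  if (!file.exists(path)) {
    stop("scaffold membership file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(contig_id = character(), scaffold_id = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("line ", lineno[which(nf < 2L)[1L]],
         ": expected 2 fields (contig_id, scaffold_id)", call. = FALSE)
  }
  members <- tibble::tibble(
    contig_id = vapply(fields, `[[`, character(1L), 1L),
    scaffold_id = vapply(fields, `[[`, character(1L), 2L)
  ) |>
    dplyr::distinct()
  dup <- members |>
    dplyr::count(.data$contig_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("contig '", dup$contig_id[1L],
         "' is assigned to more than one scaffold", call. = FALSE)
  }
  members
}

cluster_table_cols <- c(
  "cluster_id", "n_fragments", "fragments", "n_proteins",
  "nearest_homolog", "nearest_evalue", "n_edges",
  "edge_weight_min", "edge_weight_max", "edge_weight_mean", "read_count"
)

#' Write the super-contig cluster table
#'
#' Tab-delimited UTF-8 text with a single `#`-prefixed header line; one row
#' per cluster: id, member-fragment count and comma-joined members, member
#' protein count, nearest homolog and its e-value, edge count, min/max/mean
#' edge weight, and read count. Round-trips losslessly through
#' [read_cluster_table()].
#'
#' @param records Cluster-record tibble from [annotate_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(records, path) {
  header <- paste0("#", paste(cluster_table_cols, collapse = "\t"))
  if (nrow(records) == 0L) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  body <- paste(
    records$cluster_id, records$n_fragments, records$fragments,
    records$n_proteins, records$nearest_homolog,
    fmt_num(records$nearest_evalue), records$n_edges,
    fmt_num(records$edge_weight_min), fmt_num(records$edge_weight_max),
    fmt_num(records$edge_weight_mean), records$read_count,
    sep = "\t"
  )
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a super-contig cluster table written by [write_cluster_table()]
#'
#' @param path Path to the cluster table.
#' @return A cluster-record tibble with the same columns and types as
#'   [annotate_clusters()] output.
#' @export
read_cluster_table <- function(path) {
  if (!file.exists(path)) {
    stop("cluster table not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(empty_cluster_records())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cluster_table_cols))) {
    stop("malformed cluster table row: expected ",
         length(cluster_table_cols), " fields", call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  tibble::tibble(
    cluster_id = as.integer(col(1L)),
    n_fragments = as.integer(col(2L)),
    fragments = col(3L),
    n_proteins = as.integer(col(4L)),
    nearest_homolog = col(5L),
    nearest_evalue = as.numeric(col(6L)),
    n_edges = as.integer(col(7L)),
    edge_weight_min = as.numeric(col(8L)),
    edge_weight_max = as.numeric(col(9L)),
    edge_weight_mean = as.numeric(col(10L)),
    read_count = as.integer(col(11L))
  )
}

empty_cluster_records <- function() {
  tibble::tibble(
    cluster_id = integer(), n_fragments = integer(), fragments = character(),
    n_proteins = integer(), nearest_homolog = character(),
    nearest_evalue = numeric(), n_edges = integer(),
    edge_weight_min = numeric(), edge_weight_max = numeric(),
    edge_weight_mean = numeric(), read_count = integer()
  )
}
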