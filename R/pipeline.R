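stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

log_msg <- function(quiet, ...) {
  if (!quiet) message(...)
}

#' Run the full super-scaffolding pipeline
#'
#' Filter BLAST hits at the e-value cutoff, collapse duplicated edges,
#' cluster the fragment-protein graph into super-contigs, annotate each
#' cluster with its nearest homolog and edge statistics, optionally estimate
#' per-cluster expression from read-on-contig records, and write the cluster
#' table. Provenance (raw/retained/duplicate edge counts, cluster count,
#' iterations, unassigned reads) is logged to stderr.
#'
#' With identical inputs and configuration the outputs are byte-identical:
#' there is no randomness anywhere downstream of input files.
#'
#' @param blast Path to BLAST tabular input.
#' @param out Path for the output cluster table.
#' @param reads Optional path to a read-on-contig file.
#' @param dialect Read-match dialect, see [list_read_dialects()].
#' @param scaffolds Optional path to a contig-to-scaffold membership TSV.
#' @param max_evalue Inclusive e-value cutoff (default 0.001).
#' @param workers Data shares per clustering sweep (result-invariant).
#' @param quiet Suppress progress messages.
#' @return The annotated cluster-record tibble, invisibly.
#' @export
run_pipeline <- function(blast, out, reads = NULL, dialect = "soap",
                         scaffolds = NULL, max_evalue = 0.001,
                         workers = 1L, quiet = FALSE) {
  edges <- stage("read", read_blast_tabular(blast))
  if (!is.null(reads) && !file.exists(reads)) {
    stop("[read] read-match file not found: ", reads, call. = FALSE)
  }
  read_tbl <- if (!is.null(reads)) {
    stage("read", read_read_matches(reads, dialect))
  }
  members <- if (!is.null(scaffolds)) {
    stage("read", read_scaffold_members(scaffolds))
  }

  et <- stage("filter", filter_edges(edges, max_evalue))
  prov <- edge_provenance(et)
  log_msg(quiet, "filter: ", prov[["raw"]], " raw hits, ",
          prov[["threshold_removed"]], " above e-value ", max_evalue, ", ",
          prov[["duplicate_removed"]], " duplicates removed, ",
          prov[["retained"]], " edges retained")

  cl <- stage("cluster", cluster_edges(et, workers = workers))
  log_msg(quiet, "cluster: ", cl$n_clusters, " clusters in ",
          cl$n_iterations, " iterations")

  counts <- NULL
  if (!is.null(read_tbl)) {
    counts <- stage("quantify", quantify_clusters(read_tbl, cl, members))
    log_msg(quiet, "quantify: ", sum(counts$read_count),
            " reads assigned, ", unassigned_reads(counts), " unassigned, ",
            attr(counts, "multi_cluster_reads"),
            " reads spanning multiple clusters")
  }
  records <- stage("annotate", annotate_clusters(cl, read_counts = counts))
  stage("write", write_cluster_table(records, out))
  log_msg(quiet, "wrote ", out)
  invisible(records)
}

cli_parse <- function(option_list, args, usage) {
  parser <- optparse::OptionParser(usage = usage, option_list = option_list)
  optparse::parse_args(parser, args = args)
}

require_opt <- function(opt, name) {
  if (is.null(opt[[name]])) {
    stop("missing required option --", name, call. = FALSE)
  }
  opt[[name]]
}

#' Command-line entry point
#'
#' Dispatches the subcommands `cluster`, `annotate`, `quantify`, `simulate`
#' and `stats`; invoked by the `superscaf` script
#' (`inst/scripts/superscaf.R`). `annotate` implies clustering; `quantify`
#' additionally folds in read counts. Errors propagate as R conditions; the
#' wrapper script converts them to a nonzero exit status.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return 0 invisibly on success.
#' @export
superscaf_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("cluster", "annotate", "quantify", "simulate", "stats")
  if (length(args) == 0L || !args[1L] %in% subcommands) {
    stop("usage: superscaf <", paste(subcommands, collapse = "|"),
         "> [options]", call. = FALSE)
  }
  cmd <- args[1L]
  rest <- args[-1L]
  common <- list(
    optparse::make_option("--blast", type = "character",
                          help = "BLAST tabular input"),
    optparse::make_option("--max-evalue", type = "double", default = 0.001,
                          dest = "max_evalue",
                          help = "inclusive e-value cutoff [default %default]"),
    optparse::make_option("--workers", type = "integer", default = 1L,
                          help = "data shares per sweep [default %default]"),
    optparse::make_option("--out", type = "character", help = "output path"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE,
                          help = "suppress progress messages")
  )
  if (cmd %in% c("cluster", "annotate")) {
    opt <- cli_parse(common, rest, paste("superscaf", cmd, "[options]"))
    blast <- require_opt(opt, "blast")
    out <- require_opt(opt, "out")
    if (cmd == "cluster") {
      et <- filter_edges(read_blast_tabular(blast), opt$max_evalue)
      cl <- cluster_edges(et, workers = opt$workers)
      log_msg(opt$quiet, "cluster: ", cl$n_clusters, " clusters in ",
              cl$n_iterations, " iterations")
      tt <- tidy(cl)
      writeLines(
        c("#edge_index\tquery_id\tsubject_id\tcluster",
          paste(tt$edge_index, tt$query_id, tt$subject_id, tt$cluster,
                sep = "\t")),
        out, useBytes = TRUE
      )
    } else {
      run_pipeline(blast, out, max_evalue = opt$max_evalue,
                   workers = opt$workers, quiet = opt$quiet)
    }
  } else if (cmd == "quantify") {
    opts <- c(common, list(
      optparse::make_option("--reads", type = "character",
                            help = "read-on-contig file"),
      optparse::make_option("--dialect", type = "character",
                            default = "soap",
                            help = "read-match dialect [default %default]"),
      optparse::make_option("--scaffolds", type = "character",
                            help = "contig-to-scaffold membership TSV")
    ))
    opt <- cli_parse(opts, rest, "superscaf quantify [options]")
    run_pipeline(
      blast = require_opt(opt, "blast"),
      out = require_opt(opt, "out"),
      reads = require_opt(opt, "reads"),
      dialect = opt$dialect,
      scaffolds = opt$scaffolds,
      max_evalue = opt$max_evalue,
      workers = opt$workers,
      quiet = opt$quiet
    )
  } else if (cmd == "simulate") {
    opts <- list(
      optparse::make_option("--components", type = "integer", default = 50L,
                            help = "planted components [default %default]"),
      optparse::make_option("--seed", type = "integer",
                            help = "RNG seed (required)"),
      optparse::make_option("--out-dir", type = "character",
                            dest = "out_dir", help = "output directory")
    )
    opt <- cli_parse(opts, rest, "superscaf simulate [options]")
    inst <- simulate_instance(n_components = opt$components,
                              seed = require_opt(opt, "seed"))
    paths <- write_instance(inst, require_opt(opt, "out_dir"))
    message("wrote ", paste(paths, collapse = ", "))
  } else if (cmd == "stats") {
    opts <- list(optparse::make_option("--clusters", type = "character",
                                       help = "cluster table to summarise"))
    opt <- cli_parse(opts, rest, "superscaf stats [options]")
    records <- read_cluster_table(require_opt(opt, "clusters"))
    cat("clusters:        ", nrow(records), "\n", sep = "")
    if (nrow(records) > 0L) {
      cat("fragments:       ", sum(records$n_fragments), "\n", sep = "")
      cat("edges:           ", sum(records$n_edges), "\n", sep = "")
      cat("largest cluster: ", max(records$n_edges), " edges\n", sep = "")
      cat("total reads:     ", sum(records$read_count), "\n", sep = "")
    }
  }
  invisible(0L)
}
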