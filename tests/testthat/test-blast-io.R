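test_that("standard 12-column lines map to edges in file order", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200",
    "# a comment line",
    "c2\tsp|P2\t80\t60\t12\t2\t5\t64\t1\t60\t0.0001\t55.3",
    "c3\tsp|P1\t70\t90\t27\t1\t1\t90\t10\t99\t0.0\t310\textra\tcols"
  ), tf)
  edges <- read_blast_tabular(tf)
  expect_equal(nrow(edges), 3L)
  expect_equal(edges$query_id, c("c1", "c2", "c3"))
  expect_equal(edges$subject_id[1], "sp|P1")
  expect_equal(edges$evalue, c(1e-50, 1e-4, 0))
  expect_equal(edges$bit_score, c(200, 55.3, 310))
  expect_equal(edges$percent_identity[1], 98.5)
  expect_equal(edges$s_start[1], 50L)
})

test_that("empty input gives an empty edge table, not an error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), tf)
  edges <- read_blast_tabular(tf)
  expect_s3_class(edges, "tbl_df")
  expect_equal(nrow(edges), 0L)
})

test_that("malformed lines are rejected with their line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200",
    "c2\tsp|P2\tonly\tthree"
  ), tf)
  expect_error(read_blast_tabular(tf), "line 2")

  writeLines(c(
    "c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\tnot-a-number\t200"
  ), tf)
  expect_error(read_blast_tabular(tf), "line 1.*e-value")
})

test_that("query/subject namespace clash is rejected at load", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200",
    "sp|P1\tsp|P2\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200"
  ), tf)
  expect_error(read_blast_tabular(tf), "namespace")
})

test_that("edges round-trip exactly through write and read", {
  set.seed(5)
  edges <- make_edges(
    sprintf("c%d", 1:20), sprintf("sp|P%d", sample(1:8, 20, replace = TRUE)),
    evalue = 10^runif(20, -60, -1), bit_score = round(runif(20, 30, 400), 2)
  )
  edges$percent_identity <- round(runif(20, 30, 100), 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(edges, tf)
  expect_equal(read_blast_tabular(tf), edges)
})

test_that("parsing tolerates trailing whitespace and a missing final newline", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  # trailing spaces/tab on line 1; no newline after last line
  con <- file(tf, "wb")
  writeChar(paste0(
    "c1\tsp|P1\t98.5\t100\t1\t0\t1\t100\t50\t149\t1e-50\t200  \t\n",
    "c2\tsp|P2\t80\t60\t12\t2\t5\t64\t1\t60\t1E-9\t55"
  ), con, eos = NULL)
  close(con)
  edges <- read_blast_tabular(tf)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$bit_score[1], 200)
  expect_equal(edges$evalue[2], 1e-9)
})

test_that("read-match dialects parse and collapse duplicate placements", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("r9 c2 10", "r9 c2 10 extra", "r1 c1 0", "r2 c1 7"), tf)
  rm <- read_read_matches(tf, dialect = "soap")
  expect_equal(nrow(rm), 3L)
  expect_equal(sum(rm$read_id == "r9"), 1L)

  writeLines(c("r1\tc1", "r2\tc1", "r3\tc2"), tf)
  rm2 <- read_read_matches(tf, dialect = "tsv2col")
  expect_equal(nrow(rm2), 3L)
  expect_equal(rm2$position, c(0L, 0L, 0L))
})

test_that("unknown dialects and malformed read lines are informative errors", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines("r1 c1 0", tf)
  expect_error(read_read_matches(tf, dialect = "nope"),
               "soap.*tsv2col|tsv2col.*soap")
  writeLines(c("r1 c1 0", "r2 c9 notanumber"), tf)
  expect_error(read_read_matches(tf, dialect = "soap"), "line 2")
  writeLines("r1", tf)
  expect_error(read_read_matches(tf, dialect = "soap"), "line 1")
})

test_that("gzip-compressed read matches are detected by suffix", {
  tf <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(tf, "w")
  writeLines(c("r1 c1 0", "r2 c2 5"), con)
  close(con)
  rm <- read_read_matches(tf, dialect = "soap")
  expect_equal(nrow(rm), 2L)
})

test_that("scaffold membership must be a function of contig", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\ts1", "c2\ts1", "c3\ts2"), tf)
  members <- read_scaffold_members(tf)
  expect_equal(nrow(members), 3L)
  writeLines(c("c1\ts1", "c1\ts2"), tf)
  expect_error(read_scaffold_members(tf), "more than one scaffold")
})

test_that("cluster tables round-trip and an empty table is header-only", {
  inst <- simulate_instance(n_components = 4, seed = 3)
  cl <- cluster_edges(filter_edges(inst$edges))
  records <- annotate_clusters(
    cl, read_counts = quantify_clusters(inst$read_records, cl)
  )
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(records, tf)
  lines <- readLines(tf)
  expect_true(startsWith(lines[1], "#"))
  expect_equal(length(lines), nrow(records) + 1L)
  expect_equal(read_cluster_table(tf), records)

  write_cluster_table(records[0, ], tf)
  expect_equal(length(readLines(tf)), 1L)
  expect_equal(nrow(read_cluster_table(tf)), 0L)
})
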