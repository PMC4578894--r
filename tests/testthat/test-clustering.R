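# Edge list in which every edge has its own fragment and protein, except
# that edge `b` shares its protein vertex with edge `a`.
shared_vertex_edges <- function(n, a, b) {
  subj <- sprintf("p%03d", seq_len(n))
  subj[b] <- subj[a]
  make_edges(sprintf("c%03d", seq_len(n)), subj)
}

test_that("one sweep relabels a shared-vertex pair to the smaller label", {
  edges <- shared_vertex_edges(330L, 45L, 328L)
  res <- propagate_labels_once(seq_len(nrow(edges)), edges)
  expect_true(res$changed)
  expect_equal(res$labels[45], 45L)
  expect_equal(res$labels[328], 45L)
  # untouched edges keep their own labels
  expect_equal(res$labels[100], 100L)
})

test_that("a sweep over vertex-disjoint edges is a fixed point", {
  edges <- make_edges(sprintf("c%d", 1:6), sprintf("p%d", 1:6))
  res <- propagate_labels_once(1:6, edges)
  expect_false(res$changed)
  expect_equal(res$labels, 1:6)
})

test_that("labels never increase and chains propagate within a sweep", {
  # path e1-(c1,p1), e2-(c2,p1), e3-(c2,p2): e2 takes 1; e3 ends <= 2
  edges <- make_edges(c("c1", "c2", "c2"), c("p1", "p1", "p2"))
  res <- propagate_labels_once(1:3, edges)
  expect_equal(res$labels[2], 1L)
  expect_lte(res$labels[3], 2L)
  expect_true(all(res$labels <= 1:3))
  # iterating to convergence reaches the single-component fixed point
  cl <- cluster_edges(edges)
  expect_equal(cl$n_clusters, 1L)
})

test_that("clustering finds the bipartite connected components", {
  chain <- make_edges(c("c1", "c2", "c2", "c3"), c("p1", "p1", "p2", "p2"))
  cl <- cluster_edges(chain)
  expect_equal(cl$n_clusters, 1L)
  expect_setequal(cl$fragment_clusters$query_id, c("c1", "c2", "c3"))
  expect_setequal(cl$protein_clusters$subject_id, c("p1", "p2"))

  two <- make_edges(c("c1", "c2"), c("p1", "p2"))
  expect_equal(cluster_edges(two)$n_clusters, 2L)
})

test_that("an empty edge table clusters to an empty assignment", {
  cl <- cluster_edges(make_edges(character(), character()))
  expect_equal(cl$n_clusters, 0L)
  expect_equal(nrow(cl$labels), 0L)
  expect_equal(nrow(cl$fragment_clusters), 0L)
})

test_that("relabeling is consecutive and preserves smallest-label order", {
  expect_equal(relabel_consecutive(c(45L, 45L, 2L, 2L, 97L)),
               c(2L, 2L, 1L, 1L, 3L))
  expect_equal(relabel_consecutive(rep(7L, 4)), rep(1L, 4))
  lab <- relabel_consecutive(c(10L, 3L, 10L, 99L, 3L))
  expect_equal(sort(unique(lab)), seq_len(length(unique(lab))))
})

test_that("a planted 10-component instance is recovered exactly", {
  inst <- simulate_instance(n_components = 10, duplicate_rate = 0,
                            superthreshold_rate = 0, seed = 99)
  cl <- cluster_edges(filter_edges(inst$edges))
  expect_equal(cl$n_clusters, 10L)
  got <- partition_sets(cl$fragment_clusters$query_id,
                        cl$fragment_clusters$cluster)
  want <- partition_sets(inst$true_partition$fragment_id,
                         inst$true_partition$component)
  expect_equal(got, want)
})

test_that("propagation agrees with the igraph component oracle", {
  set.seed(31)
  for (i in 1:25) {
    inst <- simulate_instance(
      n_components = sample(1:12, 1),
      merge_noise_rate = sample(c(0, 0.1), 1),
      seed = sample.int(1e6, 1)
    )
    et <- filter_edges(inst$edges)
    cl <- cluster_edges(et)
    expect_equal(clustering_partition(cl), oracle_partition(et))
  }
})

test_that("invariants hold: shared-vertex equality, consecutive labels, monotone sweeps", {
  inst <- simulate_instance(n_components = 8, seed = 17)
  et <- filter_edges(inst$edges)
  cl <- cluster_edges(et)
  lab <- cl$labels$cluster
  # consecutive 1..K
  expect_equal(sort(unique(lab)), seq_len(cl$n_clusters))
  # any two edges sharing a vertex carry equal final labels
  for (i in seq_len(nrow(et))) {
    share <- et$query_id == et$query_id[i] | et$subject_id == et$subject_id[i]
    expect_true(all(lab[share] == lab[i]))
  }
  # monotone non-increasing labels across manual sweeps
  labels <- seq_len(nrow(et))
  repeat {
    res <- propagate_labels_once(labels, et)
    expect_true(all(res$labels <= labels))
    if (!res$changed) break
    labels <- res$labels
  }
  expect_lte(cl$n_iterations, nrow(et))
})

test_that("row permutation does not change the partition", {
  inst <- simulate_instance(n_components = 6, seed = 23)
  et <- filter_edges(inst$edges)
  base <- clustering_partition(cluster_edges(et))
  set.seed(1)
  for (i in 1:5) {
    perm <- et[sample.int(nrow(et)), ]
    expect_equal(clustering_partition(cluster_edges(perm)), base)
  }
})

test_that("splitting the sweep into worker shares leaves the result identical", {
  inst <- simulate_instance(n_components = 9, seed = 55)
  et <- filter_edges(inst$edges)
  ref <- cluster_edges(et, workers = 1L)
  for (w in c(2L, 3L, 8L, 64L)) {
    alt <- cluster_edges(et, workers = w)
    expect_equal(alt$labels, ref$labels)
    expect_equal(alt$fragment_clusters, ref$fragment_clusters)
    expect_equal(alt$protein_clusters, ref$protein_clusters)
  }
})

test_that("tidy/glance/autoplot expose the clustering", {
  inst <- simulate_instance(n_components = 4, seed = 2)
  cl <- cluster_edges(filter_edges(inst$edges))
  td <- tidy(cl)
  expect_equal(nrow(td), nrow(cl$labels))
  expect_named(td, c("edge_index", "query_id", "subject_id", "evalue",
                     "cluster"))
  gl <- glance(cl)
  expect_equal(gl$n_clusters, cl$n_clusters)
  expect_equal(gl$n_iterations, cl$n_iterations)
  expect_s3_class(autoplot(cl), "ggplot")
})
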