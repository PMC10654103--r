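chain_matrix <- function() {
  m <- matrix(0.1, 3, 3, dimnames = list(c("A", "B", "C"),
                                         c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 0.9
  m["B", "C"] <- m["C", "B"] <- 0.9
  diag(m) <- 1
  m
}

test_that("greedy agglomeration follows the linkage rule on a chain", {
  m <- chain_matrix()
  ps <- greedy_agglomerate(m, 0.5, "single")
  expect_equal(unname(ps$clusters), list(c("A", "B", "C")))
  pc <- greedy_agglomerate(m, 0.5, "complete")
  expect_equal(sort(unname(lengths(pc$clusters))), c(1L, 2L))
  expect_true(any(vapply(pc$clusters, setequal, logical(1), c("A", "B"))))
  expect_equal(pc$clusters[["C"]], "C")  # singleton named by genome
})

test_that("threshold extremes give one cluster or all singletons", {
  m <- block_matrix(c(4), 0.8, 0)
  p <- greedy_agglomerate(m, 0.5, "complete")
  expect_length(p$clusters, 1L)
  expect_equal(names(p$clusters), "1")

  p2 <- greedy_agglomerate(m, 1.0, "single")
  expect_length(p2$clusters, 4L)
  expect_true(all(lengths(p2$clusters) == 1L))
  expect_error(greedy_agglomerate(m, 0, "single"), "\\(0, 1\\]")
  expect_error(greedy_agglomerate(m, 1.2, "single"), "\\(0, 1\\]")
})

test_that("greedy single linkage equals graph connected components", {
  skip_if_not_installed("igraph")
  set.seed(5150)
  for (trial in 1:10) {
    n <- sample(6:14, 1)
    ids <- sprintf("G%02d", seq_len(n))
    m <- matrix(round(runif(n * n), 2), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    for (thr in c(0.3, 0.6, 0.9)) {
      got <- unname(lapply(greedy_agglomerate(m, thr, "single")$clusters,
                           sort))
      want <- oracle_components(m, thr)
      expect_setequal(got, want)
    }
  }
})

test_that("complete-linkage clusters are cliques at the threshold", {
  set.seed(77)
  for (trial in 1:5) {
    n <- 10
    ids <- sprintf("G%02d", seq_len(n))
    m <- matrix(round(runif(n * n), 2), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    p <- greedy_agglomerate(m, 0.5, "complete")
    for (mem in p$clusters) {
      if (length(mem) > 1) {
        sub <- m[mem, mem]
        expect_gte(min(sub), 0.5)
      }
    }
  }
})

test_that("agglomeration output is a partition at every level", {
  set.seed(88)
  g <- generate_table(fixture_spec(seed = 88))
  m <- build_matrix(g$table, "gcs")
  for (linkage in c("single", "average", "complete")) {
    p <- greedy_agglomerate(m, 0.4, linkage)
    expect_setequal(partition_genomes(p), rownames(m))
    expect_false(anyDuplicated(unlist(p$clusters)) > 0)
  }
  p <- two_step_cluster(m, clustering_config(metric = "gcs"))
  p <- subcluster_partition(p, m, clustering_config(metric = "gcs",
                                                    subcluster_min_size = 2))
  expect_setequal(partition_genomes(p), rownames(m))
  for (cn in names(p$subclusters)) {
    expect_setequal(unlist(p$subclusters[[cn]]), p$clusters[[cn]])
  }
})

test_that("medoid selection maximizes mean similarity with lexical ties", {
  ids <- c("A", "B", "C")
  m <- matrix(c(1, .8, .8, .8, 1, 1, .8, 1, 1), 3, 3,
              dimnames = list(ids, ids))
  # mean similarity: A 0.8, B 0.9, C 0.9 -> tie between B and C -> B
  expect_equal(select_medoid(ids, m), "B")
  expect_equal(select_medoid("A", m), "A")
  flat <- block_matrix(4, 0.5, 0.5, prefix = "Z")
  expect_equal(select_medoid(rownames(flat), flat), rownames(flat)[1])
  expect_error(select_medoid(c("A", "Q"), m), "absent")
})

test_that("two-step clustering merges pre-groups through their medoids", {
  # two tight pre-groups; medoid cross-similarity set just above / below
  # the 0.25 cluster threshold
  build <- function(between) {
    m <- block_matrix(c(3, 3), 0.9, between)
    m
  }
  merged <- two_step_cluster(build(0.30))
  expect_length(merged$clusters, 1L)
  expect_length(merged$clusters[["1"]], 6L)
  split <- two_step_cluster(build(0.10))
  expect_length(split$clusters, 2L)

  single <- matrix(1, 1, 1, dimnames = list("Only", "Only"))
  p1 <- two_step_cluster(single)
  expect_equal(names(p1$clusters), "Only")
})

test_that("cluster naming is by descending size, singletons by genome", {
  m <- block_matrix(c(4, 2, 1), 0.9, 0.05)
  p <- two_step_cluster(m)
  expect_equal(names(p$clusters)[1:2], c("1", "2"))
  expect_length(p$clusters[["1"]], 4L)
  expect_length(p$clusters[["2"]], 2L)
  expect_equal(names(p$clusters)[3], p$clusters[[3]])
})

test_that("subclustering splits at single-linkage components", {
  # one cluster of 5 whose 0.6-graph has two components
  m <- block_matrix(c(3, 2), 0.9, 0.65)
  p <- genome_partition(list(all = rownames(m)))
  cfg <- clustering_config(subcluster_min_size = 5)
  sub <- subcluster_partition(p, m, cfg)
  expect_length(sub$subclusters$all, 1L)  # 0.65 >= 0.6: still connected

  m2 <- block_matrix(c(3, 2), 0.9, 0.4)
  sub2 <- subcluster_partition(p, m2, cfg)
  expect_length(sub2$subclusters$all, 2L)
  expect_equal(names(sub2$subclusters$all), c("all_1", "all_2"))
  expect_equal(lengths(sub2$subclusters$all), c(all_1 = 3L, all_2 = 2L))

  off <- clustering_config(subcluster_enabled = FALSE)
  expect_null(subcluster_partition(p, m2, off)$subclusters)
  small <- clustering_config(subcluster_min_size = 6)
  expect_null(subcluster_partition(p, m2, small)$subclusters)
})

test_that("sweep counts step at the planted boundary and are monotone", {
  m <- block_matrix(c(4, 4), 0.9, 0.6)
  sweep <- subcluster_count_sweep(m, rownames(m),
                                  seq(0.5, 0.7, by = 0.05), "single")
  expect_equal(sweep$n_groups[sweep$threshold <= 0.6], c(1L, 1L, 1L))
  expect_equal(sweep$n_groups[sweep$threshold > 0.6], c(2L, 2L))
  expect_error(subcluster_count_sweep(m, rownames(m), c(0.7, 0.5)),
               "ascending")

  set.seed(99)
  g <- generate_table(fixture_spec(seed = 99))
  mg <- build_matrix(g$table, "gcs")
  for (linkage in c("single", "average", "complete")) {
    sw <- subcluster_count_sweep(mg, rownames(mg),
                                 seq(0.1, 0.9, by = 0.1), linkage)
    if (linkage == "single") {
      expect_true(all(diff(sw$n_groups) >= 0))
    }
  }
})

test_that("clustering is invariant to genome insertion order", {
  set.seed(123)
  g <- generate_table(fixture_spec(seed = 123))
  m <- build_matrix(g$table, "gcs")
  perm <- sample(rownames(m))
  m2 <- m[perm, perm]
  p1 <- two_step_cluster(m)
  p2 <- two_step_cluster(m2)
  expect_equal(p1$clusters, p2$clusters)
})

test_that("partition TSV round trips including subclusters", {
  m <- block_matrix(c(5, 3, 1), 0.9, 0.05)
  p <- two_step_cluster(m)
  p <- subcluster_partition(p, m, clustering_config(subcluster_min_size = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, f)
  p2 <- read_partition_tsv(f)
  expect_equal(p2$clusters[order(names(p2$clusters))],
               p$clusters[order(names(p$clusters))])
  expect_equal(lapply(p2$subclusters, function(x) x[order(names(x))]),
               lapply(p$subclusters, function(x) x[order(names(x))]))
})
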