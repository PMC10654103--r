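test_that("identical partitions give zero error and unit scores", {
  p <- partition_from_labels(setNames(rep(c("x", "y"), c(3, 2)),
                                      sprintf("G%d", 1:5)))
  cc <- pair_confusion(p, p)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp + cc$tn, choose(5, 2))
  ps <- precision_sensitivity(cc)
  expect_equal(ps$precision, 1)
  expect_equal(ps$sensitivity, 1)
  expect_equal(mcc(cc), 1)
})

test_that("splitting one reference cluster yields the product-rule fn", {
  ids <- sprintf("G%04d", seq_len(702))
  ref <- genome_partition(list(A = ids))
  pred <- genome_partition(list(A1 = ids[1:189], A2 = ids[190:702]))
  cc <- pair_confusion(ref, pred)
  expect_equal(cc$fn, 513 * 189)
  expect_equal(cc$tp, choose(189, 2) + choose(513, 2))
  expect_equal(cc$fp, 0)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, choose(702, 2))
})

test_that("all-singleton partitions have no positive pairs", {
  labels <- setNames(sprintf("s%d", 1:6), sprintf("G%d", 1:6))
  p <- partition_from_labels(labels)
  cc <- pair_confusion(p, p)
  expect_equal(cc$tp, 0)
  expect_equal(cc$tn, choose(6, 2))
  w <- capture_warnings(ps <- precision_sensitivity(cc))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(ps$precision) && is.na(ps$sensitivity))
  expect_warning(expect_true(is.na(mcc(cc))), "undefined")
})

test_that("global counts match the brute-force pair enumeration", {
  set.seed(4242)
  for (trial in 1:6) {
    n <- sample(6:12, 1)
    ids <- sprintf("G%02d", seq_len(n))
    lr <- setNames(sample(letters[1:3], n, replace = TRUE), ids)
    lp <- setNames(sample(letters[1:3], n, replace = TRUE), ids)
    got <- pair_confusion(partition_from_labels(lr),
                          partition_from_labels(lp))
    want <- oracle_confusion(lr, lp)
    expect_equal(got, want)
    expect_equal(got$tp + got$tn + got$fp + got$fn, choose(n, 2))
  }
})

test_that("per-cluster rows decompose the global counts exactly", {
  set.seed(555)
  for (trial in 1:5) {
    n <- sample(8:14, 1)
    ids <- sprintf("G%02d", seq_len(n))
    ref <- partition_from_labels(setNames(sample(letters[1:3], n, TRUE),
                                          ids))
    pred <- partition_from_labels(setNames(sample(letters[1:4], n, TRUE),
                                           ids))
    rows <- per_cluster_confusion(ref, pred)
    global <- pair_confusion(ref, pred)
    expect_equal(sum(rows$tp), global$tp)
    expect_equal(sum(rows$fn), global$fn)
    expect_equal(sum(rows$fp), global$fp)  # halves sum exactly
    expect_equal(sum(rows$tn), global$tn)
    # per-row internal-pair identity
    expect_equal(rows$tp + rows$fn, choose(rows$size, 2))
  }
})

test_that("an exactly recovered cluster shows half-weighted tn", {
  # cluster of 359 among 2,121 genomes, recovered identically
  sizes <- c(359, 702, 1060)
  labels <- setNames(rep(c("B", "A", "rest"), sizes),
                     sprintf("G%04d", seq_len(sum(sizes))))
  ref <- partition_from_labels(labels)
  rows <- per_cluster_confusion(ref, ref)
  b <- rows[rows$reference_cluster == "B", ]
  expect_equal(b$tp, choose(359, 2))          # 64,261
  expect_equal(b$tn, 359 * (2121 - 359) / 2)  # 316,279
  expect_equal(b$fp, 0)
  expect_equal(b$fn, 0)

  singleton <- per_cluster_confusion(
    partition_from_labels(setNames(c("s", "t", "t"), c("g1", "g2", "g3"))),
    partition_from_labels(setNames(c("s", "t", "t"), c("g1", "g2", "g3"))))
  s <- singleton[singleton$reference_cluster == "s", ]
  expect_equal(s$tp, 0)
  expect_equal(s$fn, 0)
})

test_that("MCC matches direct formula and brute-force on a 4-genome toy", {
  cc <- confusion_counts(tp = 1, tn = 3, fp = 1, fn = 1)
  expect_equal(mcc(cc), (1 * 3 - 1 * 1) / sqrt(2 * 2 * 4 * 4))  # 0.25
  # cross-check against brute-force enumeration on realizable partitions
  ids <- c("g1", "g2", "g3", "g4", "g5")
  lr <- setNames(c("a", "a", "b", "b", "c"), ids)  # ref pairs: 12, 34
  lp <- setNames(c("a", "a", "b", "c", "b"), ids)  # pred pairs: 12, 35
  got <- pair_confusion(partition_from_labels(lr),
                        partition_from_labels(lp))
  expect_equal(got, oracle_confusion(lr, lp))
  expect_equal(unclass(got)[c("tp", "tn", "fp", "fn")],
               list(tp = 1, tn = 7, fp = 1, fn = 1))
  expect_equal(mcc(got), (1 * 7 - 1 * 1) / sqrt(2 * 2 * 8 * 8))
})

test_that("MCC reaches -1 on perfectly disagreeing pair relations", {
  expect_equal(mcc(confusion_counts(tp = 0, tn = 0, fp = 2, fn = 2)), -1)
})

test_that("MCC is symmetric under reference/prediction swap", {
  set.seed(66)
  ids <- sprintf("G%02d", 1:10)
  lr <- setNames(sample(letters[1:3], 10, TRUE), ids)
  lp <- setNames(sample(letters[1:3], 10, TRUE), ids)
  a <- mcc(pair_confusion(partition_from_labels(lr),
                          partition_from_labels(lp)))
  b <- mcc(pair_confusion(partition_from_labels(lp),
                          partition_from_labels(lr)))
  expect_equal(a, b)
})

test_that("genome-set mismatch is rejected with the symmetric difference", {
  p1 <- partition_from_labels(setNames(c("a", "a"), c("g1", "g2")))
  p2 <- partition_from_labels(setNames(c("a", "a"), c("g1", "g3")))
  expect_error(pair_confusion(p1, p2), "g2.*g3|g3.*g2")
})

test_that("scalar truncation reports 3 decimals toward zero", {
  expect_equal(truncate3(0.7347461), 0.734)
  expect_equal(truncate3(0.9999), 0.999)
  expect_equal(truncate3(1), 1)
})

test_that("evaluation report writes per-cluster table plus summary", {
  ids <- sprintf("G%02d", 1:8)
  ref <- partition_from_labels(setNames(rep(c("a", "b"), each = 4), ids))
  pred <- partition_from_labels(setNames(rep(c("a", "b", "c"), c(4, 2, 2)),
                                         ids))
  ft <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".txt")
  global <- write_evaluation_report(ref, pred, ft, fs)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 3L)  # 2 reference clusters + cumulative
  expect_equal(tab$tp[tab$reference_cluster == "Cumulative"], global$tp)
  summ <- read.delim(fs, header = FALSE)
  expect_true("precision" %in% summ$V1)
})
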