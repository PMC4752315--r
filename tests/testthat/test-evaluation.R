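# LOO-CV confusion counts, confusion metrics, MCC stratification and the
# hypergeometric overlap test.

test_that("LOO with 1NN on the 4-sample hand fixture is perfect", {
  m <- matrix(c(0.1, 0.2, 0.8, 0.9), 1, 4,
              dimnames = list("cg001", sprintf("S%02d", 1:4)))
  M <- methyl_matrix(m)
  lv <- label_vector("G", colnames(m), c("down", "down", "up", "up"))
  # holding out each point, its nearest neighbour shares its label
  counts <- loo_confusion(classifier_spec("knn", 1), "cg001", M, lv)
  expect_equal(unclass(counts)[c("tp", "tn", "fp", "fn")],
               list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
})

test_that("LOO on a separable planted probe has no errors", {
  fx <- planted_fixture(n_samples = 14, n_noise = 3)
  counts <- loo_confusion(classifier_spec("knn", 1), fx$planted, fx$M,
                          fx$labels)
  expect_equal(counts$fp + counts$fn, 0)
})

test_that("LOO on a constant probe matches exhaustive enumeration", {
  m <- matrix(rep(0.5, 4), 1, 4,
              dimnames = list("cg001", c("S01", "S02", "S03", "S04")))
  M <- methyl_matrix(m)
  lv <- label_vector("G", colnames(m), c("down", "down", "down", "up"))
  counts <- loo_confusion(classifier_spec("knn", 1), "cg001", M, lv)
  # all distances tie, so each held-out sample gets the label of the
  # lowest remaining sample id: S01 predicts S02's label "down", others
  # predict S01's "down"; every prediction is "down"
  expect_equal(unclass(counts)[c("tp", "tn", "fp", "fn")],
               list(tp = 3L, tn = 0L, fp = 1L, fn = 0L))
})

test_that("metrics match the printed formulas on worked confusion tables", {
  perfect <- metrics_from_confusion(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)

  worst <- metrics_from_confusion(confusion_counts(0, 0, 10, 10))
  expect_equal(worst$mcc, -1)

  r <- metrics_from_confusion(confusion_counts(4, 3, 2, 1))
  expect_equal(r$mcc, 10 / sqrt(600))
  expect_equal(r$precision, 4 / 6)
  expect_equal(r$recall, 4 / 5)
  expect_equal(r$specificity, 3 / 5)

  # zero-denominator convention
  expect_equal(metrics_from_confusion(confusion_counts(5, 0, 0, 5))$mcc, 0)
  # undefined precision is a missing-value sentinel
  expect_true(is.na(metrics_from_confusion(
    confusion_counts(0, 5, 0, 5))$precision))
  expect_error(metrics_from_confusion(confusion_counts(0, 0, 0, 0)),
               "empty")
})

test_that("MCC is symmetric under the class swap (TP<->TN, FP<->FN)", {
  set.seed(2)
  for (i in 1:25) {
    c1 <- sample(0:6, 4, replace = TRUE)
    a <- metrics_from_confusion(confusion_counts(c1[1], c1[2], c1[3],
                                                 c1[4]))
    b <- metrics_from_confusion(confusion_counts(c1[2], c1[1], c1[4],
                                                 c1[3]))
    if (sum(c1) > 0) {
      expect_equal(a$mcc, b$mcc)
    }
  }
})

test_that("MCC stratification uses strict cutoffs", {
  rec <- tibble::tibble(gene_id = c("G1", "G2", "G3", "G4", "G5"),
                        mcc = c(0.61, 0.6, 0.19, 0.2, NA))
  s <- stratify_by_mcc(rec)
  expect_equal(s$high, "G1")
  expect_equal(s$low, "G3")
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(s$high, path)
  expect_equal(readLines(path), "G1")
})

test_that("hypergeometric overlap matches enumeration, phyper and MC", {
  # |U| = 10, |A| = 4, |B| = 5, overlap 3:
  # (C(4,3)C(6,2) + C(4,4)C(6,1)) / C(10,5) = 66/252
  u <- paste0("g", 1:10)
  a <- u[1:4]
  b <- u[c(1, 2, 3, 5, 6)]
  p <- hypergeometric_overlap(a, b, u)
  expect_equal(p, 66 / 252)
  # independent route: upper-tail phyper
  expect_equal(p, stats::phyper(2, 4, 6, 5, lower.tail = FALSE))
  # Monte-Carlo agreement within 3 standard errors
  set.seed(7)
  n_mc <- 1e5
  hits <- vapply(seq_len(n_mc), function(i) {
    length(intersect(a, sample(u, 5))) >= 3
  }, logical(1))
  se <- sqrt(p * (1 - p) / n_mc)
  expect_lt(abs(mean(hits) - p), 3 * se)

  # degenerate tails
  expect_equal(hypergeometric_overlap(u[1:4], u[5:10], u), 1) # overlap 0
  expect_equal(hypergeometric_overlap(u[1:4], u, u), 1) # forced overlap
  expect_error(hypergeometric_overlap("g1", "g2", character(0)),
               "universe")
  expect_error(hypergeometric_overlap("zz", "g1", u), "subsets")
})

test_that("summaries aggregate per method, skipping undefined metrics", {
  rec <- dplyr::bind_rows(
    metrics_from_confusion(confusion_counts(4, 3, 2, 1)),
    metrics_from_confusion(confusion_counts(0, 5, 0, 5)))
  rec$gene_id <- c("G1", "G2")
  rec$method <- "sfs_1nn"
  rec$classifier <- "1nn"
  s <- summarize_evaluations(rec)
  expect_equal(s$n_genes, 2L)
  # undefined precision of G2 excluded from the mean
  expect_equal(s$precision_mean, 4 / 6)
  expect_equal(s$mcc_mean, mean(c(10 / sqrt(600), 0)))

  hist <- probe_count_histogram(
    tibble::tibble(gene_id = c("G1", "G2", "G3"),
                   probes = list("a", "b", c("c", "d"))))
  expect_equal(hist$n_selected, c(1L, 2L))
  expect_equal(hist$n_genes, c(2L, 1L))
})

test_that("evaluate_selection returns one tidy row per gene", {
  fx <- planted_fixture(n_samples = 12, n_noise = 2)
  row <- evaluate_selection(classifier_spec("knn", 1), fx$planted, fx$M,
                            fx$labels, method = "sfs_1nn")
  expect_equal(nrow(row), 1L)
  expect_equal(row$mcc, 1)
  expect_equal(row$n_probes, 1L)
  expect_equal(tidy(loo_confusion(classifier_spec("knn", 1), fx$planted,
                                  fx$M, fx$labels))$mcc, 1)
})
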