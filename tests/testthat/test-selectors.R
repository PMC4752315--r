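# SVM-RFE, ReliefF, GA-KNN, controls and annotation-driven selectors.

test_that("class weights solve n0*w0 = n1*w1 with w1 = 1", {
  lv <- label_vector("G", sprintf("S%02d", 1:40),
                     c(rep("down", 10), rep("up", 30)))
  w <- balance_weights(lv)
  expect_equal(w$w0, 3)
  expect_equal(w$w1, 1)
  expect_identical(w$n0 * w$w0, w$n1 * w$w1)

  even <- balance_weights(label_vector("G", sprintf("S%02d", 1:8),
                                       rep(c("down", "up"), 4)))
  expect_equal(even$w0, 1)
  expect_error(balance_weights(label_vector("G", sprintf("S%02d", 1:4),
                                            rep("up", 4))),
               "both classes")
})

test_that("SVM-RFE ranks a separating probe above a constant one", {
  fx <- planted_fixture(n_samples = 20, n_noise = 0)
  m <- rbind(unclass(fx$M), cg_const = rep(0.5, 20))
  M <- methyl_matrix(m)
  ranking <- svm_rfe_rank(c("cg_planted", "cg_const"), M, fx$labels)
  expect_equal(ranking, c("cg_planted", "cg_const"))
})

test_that("SVM-RFE returns a complete ranking with index tie-breaks", {
  set.seed(14)
  base <- runif(16)
  m <- rbind(cgA = base, cgB = runif(16), cgC = base) # cgC duplicates cgA
  colnames(m) <- sprintf("S%02d", 1:16)
  M <- methyl_matrix(m)
  lv <- label_vector("G", colnames(m), rep(c("down", "up"), 8))
  ranking <- svm_rfe_rank(rownames(m), M, lv)
  expect_setequal(ranking, rownames(m))
  expect_equal(anyDuplicated(ranking), 0L)
  # duplicated columns score identically -> adjacent ranks, lower
  # candidate index first
  ia <- match("cgA", ranking)
  ic <- match("cgC", ranking)
  expect_equal(ic, ia + 1L)
})

test_that("ReliefF hand update matches the printed formula", {
  # three samples on one feature: instance x = 0.5 (down), its nearest
  # hit at 0.4, nearest miss at 0.8; single iteration, no normalization
  m <- matrix(c(0.5, 0.4, 0.8), 1, 3,
              dimnames = list("cg001", c("A", "B", "C")))
  M <- methyl_matrix(m)
  lv <- label_vector("G", c("A", "B", "C"), c("down", "down", "up"))
  st <- relieff_weights("cg001", M, lv, k_neighbors = 1, instances = "A")
  expect_equal(unname(st$weights), -(0.5 - 0.4)^2 + (0.5 - 0.8)^2)
  expect_equal(unname(st$weights), 0.08)
})

test_that("ReliefF update is zero when hit and miss equal the instance", {
  m <- matrix(c(0.5, 0.5, 0.5, 0.9), 1, 4,
              dimnames = list("cg001", c("A", "B", "C", "D")))
  # instance A (down): hit B at 0.5, miss C at 0.5 -> zero update
  M <- methyl_matrix(m)
  lv <- label_vector("G", c("A", "B", "C", "D"),
                     c("down", "down", "up", "up"))
  st <- relieff_weights("cg001", M, lv, k_neighbors = 1, instances = "A")
  expect_equal(unname(st$weights), 0)
})

test_that("a perfectly separating feature earns the top positive weight", {
  fx <- planted_fixture(n_samples = 16, n_noise = 4, seed = 30)
  st <- relieff_weights(fx$candidates, fx$M, fx$labels, k_neighbors = 1,
                        seed = 1)
  expect_gt(st$weights[[fx$planted]], 0)
  expect_equal(relieff_rank(st)[1], fx$planted)
  td <- tidy(st)
  expect_equal(td$probe_id[td$rank == 1], fx$planted)
})

test_that("GA fitness follows resubLoss / (N - S) with degenerate guards", {
  expect_equal(ga_fitness(0.2, 10, 2), 0.025)
  expect_equal(ga_fitness(0, 10, 3), 0)
  expect_identical(ga_fitness(0.1, 10, 10), Inf)
  expect_identical(ga_fitness(0.1, 10, 0), Inf)
})

test_that("the GA finds a zero-loss subset on the planted fixture", {
  fx <- planted_fixture(n_samples = 16, n_noise = 4, seed = 8)
  cfg <- ga_config(population_size = 20, n_generations = 20, seed = 99)
  sel <- ga_knn_select(fx$candidates, fx$M, fx$labels, cfg)
  expect_gt(length(sel$selected), 0)
  expect_lt(length(sel$selected), length(fx$candidates)) # S = N excluded
  expect_equal(sel$final_cv_error, 0) # 1NN resubstitution on distinct rows
  # deterministic given the seed
  sel2 <- ga_knn_select(fx$candidates, fx$M, fx$labels, cfg)
  expect_identical(sel$selected, sel2$selected)
})

test_that("top-k trims rankings and flags out-of-range k", {
  expect_equal(select_top_k(c("a", "b", "c"), 2), c("a", "b"))
  expect_equal(select_top_k(c("a", "b", "c"), 3), c("a", "b", "c"))
  expect_warning(out <- select_top_k(c("a", "b"), 5), "exceeds")
  expect_equal(out, c("a", "b"))
  expect_error(select_top_k(c("a", "b"), 0), ">= 1")
})

test_that("random control is seeded, uniform and exhaustive at k = n", {
  cands <- paste0("cg", 1:4)
  expect_setequal(control_random(cands, 4, seed = 1), cands)
  expect_identical(control_random(cands, 2, seed = 5),
                   control_random(cands, 2, seed = 5))
  draws <- vapply(1:4000, function(s) control_random(cands, 1, seed = s),
                  character(1))
  freq <- table(draws) / 4000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("top-two-correlated picks the largest |r| probes", {
  set.seed(31)
  e <- rnorm(12)
  names(e) <- sprintf("S%02d", 1:12)
  noise <- function(sd) rnorm(12, 0, sd)
  m <- rbind(cg_pos = (e - min(e)) / (max(e) - min(e)), # r = +1
             cg_neg = 0.5 - 0.04 * e + 0.001 * noise(1),
             cg_flat = runif(12),
             cg_const = rep(0.3, 12))
  colnames(m) <- names(e)
  M <- methyl_matrix(m, permissive = TRUE)
  top <- control_top_two_correlated(rownames(m), M, e)
  expect_setequal(top, c("cg_pos", "cg_neg"))
  # probe equal to (rescaled) expression has |r| = 1 and is always kept
  expect_true("cg_pos" %in% top)
  # fewer than two candidates: return them all
  expect_equal(control_top_two_correlated("cg_pos", M, e), "cg_pos")
})

test_that("annotation selectors honour region, island, window and SD rules", {
  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    gene = "G1",
    region_group = c("TSS200", "Body", "5'UTR", "Body"),
    island_relation = c("Island", "Island", "OpenSea", "Shore"),
    chromosome = "chr1",
    position = 1:4 * 100L,
    tss_distance = c(-150L, 2500L, -900L, 2501L))
  cands <- ann$probe_id
  expect_equal(select_annotation_based("all", "G1", cands, ann), cands)
  # island + upstream region required: cg2 is Island but Body -> excluded
  expect_equal(select_annotation_based("upstream_cpg_island", "G1", cands,
                                       ann), "cg1")
  # inclusive 2500 bp boundary
  expect_equal(select_annotation_based("tss_window", "G1", cands, ann),
               c("cg1", "cg2", "cg3"))
  m <- rbind(cg1 = rep(0.5, 6), cg2 = c(0.1, 0.9, 0.1, 0.9, 0.1, 0.9),
             cg3 = c(0.4, 0.6, 0.4, 0.6, 0.4, 0.6),
             cg4 = rep(0.2, 6))
  colnames(m) <- sprintf("S%02d", 1:6)
  M <- methyl_matrix(m)
  expect_equal(select_annotation_based("top_sd", "G1", cands, ann, M),
               "cg2")
  # empty result set warns and returns empty
  ann2 <- ann
  ann2$island_relation <- "OpenSea"
  expect_warning(
    out <- select_annotation_based("upstream_cpg_island", "G1", cands,
                                   ann2),
    "no probe")
  expect_length(out, 0)
})
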