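# Fit/predict contract across the classifier families.

train4 <- function() {
  x <- matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1,
              dimnames = list(sprintf("S%02d", 1:4), "cg001"))
  list(x = x, y = c("down", "down", "up", "up"))
}

test_that("1NN memorizes training points and votes by nearest neighbour", {
  tr <- train4()
  model <- fit_classifier(classifier_spec("knn", 1), tr$x, tr$y)
  expect_equal(as.character(predict_classifier(model, tr$x)),
               tr$y) # resubstitution with distinct points is exact
  expect_equal(as.character(predict_classifier(
    model, matrix(0.15, 1, 1))), "down")
})

test_that("3NN takes the majority of the three nearest labels", {
  x <- matrix(c(0.1, 0.2, 0.9, 0.85), ncol = 1,
              dimnames = list(sprintf("S%02d", 1:4), "cg001"))
  model <- fit_classifier(classifier_spec("knn", 3), x,
                          c("up", "up", "down", "down"))
  # neighbours of 0.25: 0.2 (up), 0.1 (up), 0.85 (down) -> up
  expect_equal(as.character(predict_classifier(
    model, matrix(0.25, 1, 1))), "up")
})

test_that("KNN distance ties break on sample id, not input order", {
  x <- matrix(c(0.4, 0.6, 0.5), ncol = 1,
              dimnames = list(c("S01", "S02", "S03"), "cg001"))
  y <- c("down", "up", "up")
  test <- matrix(0.5, 1, 1)
  # S03 is at distance 0 -> its label wins regardless of row order
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    model <- fit_classifier(classifier_spec("knn", 1),
                            x[perm, , drop = FALSE], y[perm])
    expect_equal(as.character(predict_classifier(model, test)), "up")
  }
  # equidistant neighbours (S01 at 0.1, S02 at 0.1): lower sample id wins
  model <- fit_classifier(classifier_spec("knn", 1),
                          x[1:2, , drop = FALSE], y[1:2])
  expect_equal(as.character(predict_classifier(model, test)), "down")
})

test_that("KNN matches a brute-force distance table on random data", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    p <- sample(1:4, 1)
    x <- matrix(runif(n * p), n, p,
                dimnames = list(sprintf("S%02d", 1:n), NULL))
    y <- sample(c("down", "up"), n, replace = TRUE)
    test <- matrix(runif(3 * p), 3, p)
    model <- fit_classifier(classifier_spec("knn", 1), x, y)
    expect_equal(as.character(predict_classifier(model, test)),
                 oracle_1nn(x, y, rownames(x), test))
  }
})

test_that("scaling one feature changes neighbours as brute force predicts", {
  set.seed(9)
  x <- matrix(runif(16), 8, 2, dimnames = list(sprintf("S%02d", 1:8), NULL))
  y <- rep(c("down", "up"), 4)
  test <- matrix(runif(4), 2, 2)
  x2 <- x
  x2[, 2] <- x2[, 2] * 10
  test2 <- test
  test2[, 2] <- test2[, 2] * 10
  model <- fit_classifier(classifier_spec("knn", 1), x2, y)
  expect_equal(as.character(predict_classifier(model, test2)),
               oracle_1nn(x2, y, rownames(x2), test2))
})

test_that("KNN prediction is invariant to probe (column) ordering", {
  set.seed(3)
  x <- matrix(runif(30), 10, 3, dimnames = list(sprintf("S%02d", 1:10),
                                                paste0("cg", 1:3)))
  y <- rep(c("down", "up"), 5)
  test <- matrix(runif(6), 2, 3)
  m1 <- fit_classifier(classifier_spec("knn", 3), x, y)
  m2 <- fit_classifier(classifier_spec("knn", 3),
                       x[, c(3, 1, 2)], y)
  expect_equal(predict_classifier(m1, test),
               predict_classifier(m2, test[, c(3, 1, 2)]))
})

test_that("a tree too small to split predicts the majority class", {
  set.seed(5)
  x <- matrix(runif(8), 8, 1, dimnames = list(sprintf("S%02d", 1:8),
                                              "cg001"))
  y <- c(rep("down", 5), rep("up", 3))
  model <- fit_classifier(classifier_spec("decision_tree"), x, y)
  # min_parent = 10 > 8 samples: root is a leaf
  pred <- predict_classifier(model, matrix(runif(6), 6, 1))
  expect_true(all(pred == "down"))
})

test_that("the tree splits a separable feature when large enough", {
  tr <- planted_fixture(n_samples = 24, n_noise = 0)
  x <- t(unclass(tr$M))
  model <- fit_classifier(classifier_spec("decision_tree"), x,
                          as.character(tr$labels$labels))
  expect_equal(as.character(predict_classifier(model, x)),
               as.character(tr$labels$labels))
})

test_that("kernel naive Bayes survives constant features via the bandwidth floor", {
  x <- cbind(const = rep(0.5, 8), good = c(0.1, 0.15, 0.2, 0.12,
                                           0.8, 0.85, 0.9, 0.82))
  rownames(x) <- sprintf("S%02d", 1:8)
  y <- c(rep("down", 4), rep("up", 4))
  model <- fit_classifier(classifier_spec("naive_bayes"), x, y)
  pred <- predict_classifier(model, x)
  expect_equal(as.character(pred), y)
})

test_that("SVM refuses a single-class training fold", {
  x <- matrix(runif(6), 6, 1, dimnames = list(sprintf("S%02d", 1:6),
                                              "cg001"))
  expect_error(fit_classifier(classifier_spec("svm_linear"), x,
                              rep("up", 6)),
               "degenerate fold")
})

test_that("linear SVM separates the planted fixture", {
  tr <- planted_fixture(n_samples = 20, n_noise = 0)
  x <- t(unclass(tr$M))
  model <- fit_classifier(classifier_spec("svm_linear"), x,
                          as.character(tr$labels$labels))
  expect_equal(misclassification_count(model, x, tr$labels$labels), 0)
})

test_that("misclassification counts span 0 to n and check dimensions", {
  tr <- train4()
  model <- fit_classifier(classifier_spec("knn", 1), tr$x, tr$y)
  expect_equal(misclassification_count(model, tr$x, tr$y), 0)
  flipped <- ifelse(tr$y == "up", "down", "up")
  expect_equal(misclassification_count(model, tr$x, flipped), 4)
  expect_error(predict_classifier(model, matrix(0.5, 1, 2)),
               "dimension")
})

test_that("training-row permutation leaves predictions unchanged", {
  set.seed(11)
  x <- matrix(runif(24), 12, 2, dimnames = list(sprintf("S%02d", 1:12),
                                                NULL))
  y <- rep(c("down", "up"), 6)
  test <- matrix(runif(8), 4, 2)
  perm <- sample(12)
  for (fam in list(classifier_spec("knn", 3),
                   classifier_spec("naive_bayes"),
                   classifier_spec("decision_tree"))) {
    m1 <- fit_classifier(fam, x, y)
    m2 <- fit_classifier(fam, x[perm, , drop = FALSE], y[perm])
    expect_equal(predict_classifier(m1, test), predict_classifier(m2, test),
                 info = fam$family)
  }
})
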