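# Uniform fit/predict contract over the classifier families plugged into
# the SFS wrapper and the LOO-CV harness: KNN (Euclidean), decision tree
# (Gini, rpart), kernel-density naive Bayes, and linear / Gaussian SVM
# (e1071). Feature matrices are samples x probes; labels are down/up
# factors with "down" first.
#
# KNN and the kernel naive Bayes are implemented here because their
# contracts pin down details generic library implementations leave open:
# KNN breaks distance ties by a stable sort on (distance, sample id) and
# vote ties by the label of the single nearest neighbour, so predictions
# are invariant to training-row permutation; the naive Bayes uses a
# Gaussian kernel with Silverman's-rule bandwidth floored at 1e-3 beta
# units so constant features do not degenerate.

#' Specify a classifier
#'
#' @param family One of `"knn"`, `"decision_tree"`, `"naive_bayes"`,
#'   `"svm_linear"`, `"svm_gaussian"`.
#' @param k_neighbors Neighbourhood size for KNN; odd positive (1, 3 and 5
#'   are the usual choices).
#' @param min_parent,min_leaf Decision tree: minimum node size to attempt a
#'   split, and minimum leaf size. Defaults 10 and 1.
#' @param class_weights Optional named vector `c(down = w0, up = w1)` of
#'   misclassification weights (SVMs only).
#' @param cost SVM box constraint C (default 1).
#' @param bandwidth_floor Naive Bayes: lower bound on the kernel bandwidth,
#'   in beta units.
#' @param seed Seed routed to any stochastic sub-step (none of the shipped
#'   families is stochastic; kept for the contract).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("knn", "decision_tree", "naive_bayes",
                                       "svm_linear", "svm_gaussian"),
                            k_neighbors = 1L, min_parent = 10L,
                            min_leaf = 1L, class_weights = NULL, cost = 1,
                            bandwidth_floor = 1e-3, seed = NULL) {
  family <- match.arg(family)
  assert_scalar_count(k_neighbors, "k_neighbors")
  if (k_neighbors %% 2 == 0) {
    abort("k_neighbors must be odd")
  }
  if (!is.null(class_weights)) {
    if (!all(sort(names(class_weights)) == c("down", "up")) ||
        any(class_weights <= 0)) {
      abort("class_weights must be positive and named 'down'/'up'")
    }
  }
  structure(list(family = family, k_neighbors = as.integer(k_neighbors),
                 min_parent = as.integer(min_parent),
                 min_leaf = as.integer(min_leaf),
                 class_weights = class_weights, cost = cost,
                 bandwidth_floor = bandwidth_floor, seed = seed),
            class = "classifier_spec")
}

#' Short label for a classifier spec (e.g. "1nn", "dt", "svm")
#' @param spec A [classifier_spec()].
#' @return A string.
#' @export
classifier_label <- function(spec) {
  switch(spec$family,
         knn = paste0(spec$k_neighbors, "nn"),
         decision_tree = "dt",
         naive_bayes = "nb",
         svm_linear = "svm",
         svm_gaussian = "svm_rbf")
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric matrix, samples in rows, probes in columns; rownames
#'   are sample ids (used for deterministic KNN tie-breaking).
#' @param y Labels (`"down"`/`"up"`), one per row of `x`.
#' @return A `fitted_classifier` holding the spec, the training dimension
#'   and the fitted state.
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x))
  y <- as_label_factor(y)
  if (nrow(x) != length(y)) {
    abort("x and y differ in length")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("s%04d", seq_len(nrow(x)))
  }
  n_class <- length(unique(y))
  model <- switch(
    spec$family,
    knn = list(x = x, y = y),
    decision_tree = fit_tree(spec, x, y),
    naive_bayes = {
      if (n_class < 2) abort("naive Bayes needs both classes in training data")
      fit_kernel_nb(spec, x, y)
    },
    svm_linear = ,
    svm_gaussian = {
      if (n_class < 2) {
        abort("degenerate fold: SVM training data contains a single class")
      }
      fit_svm(spec, x, y)
    })
  structure(list(spec = spec, d = ncol(x), model = model,
                 levels = levels(y)),
            class = "fitted_classifier")
}

fit_tree <- function(spec, x, y) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(
                 minsplit = spec$min_parent, minbucket = spec$min_leaf,
                 cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0,
                 usesurrogate = 0))
}

fit_kernel_nb <- function(spec, x, y) {
  classes <- levels(y)
  per_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    bw <- apply(xc, 2, function(v) silverman_bw(v, spec$bandwidth_floor))
    list(x = xc, bw = bw, prior = nrow(xc) / nrow(x))
  })
  setNames(per_class, classes)
}

# Silverman's rule of thumb with a hard floor for degenerate (constant or
# near-constant) features.
silverman_bw <- function(v, floor_bw) {
  n <- length(v)
  s <- stats::sd(v)
  iqr <- stats::IQR(v) / 1.34
  spread <- if (s > 0 && iqr > 0) min(s, iqr) else max(s, iqr)
  h <- 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h < floor_bw) floor_bw else h
}

fit_svm <- function(spec, x, y) {
  kernel <- if (spec$family == "svm_linear") "linear" else "radial"
  cw <- spec$class_weights
  args <- list(x = x, y = y, kernel = kernel, cost = spec$cost,
               scale = FALSE)
  if (!is.null(cw)) {
    args$class.weights <- cw
  }
  do.call(e1071::svm, args)
}

#' Predict labels with a fitted classifier
#'
#' @param model A `fitted_classifier`.
#' @param newx Numeric matrix, samples in rows; must have the training
#'   dimension.
#' @return Factor of predicted labels (levels `down`, `up`).
#' @export
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "fitted_classifier"))
  if (!is.matrix(newx)) {
    newx <- matrix(newx, nrow = 1)
  }
  if (ncol(newx) != model$d) {
    abort(sprintf("feature dimension %d does not match training dimension %d",
                  ncol(newx), model$d))
  }
  pred <- switch(
    model$spec$family,
    knn = predict_knn(model, newx),
    decision_tree = {
      df <- as.data.frame(newx)
      colnames(df) <- paste0("V", seq_len(ncol(newx)))
      as.character(stats::predict(model$model, newdata = df, type = "class"))
    },
    naive_bayes = predict_kernel_nb(model, newx),
    svm_linear = ,
    svm_gaussian = as.character(stats::predict(model$model, newx)))
  factor(pred, levels = LABEL_LEVELS)
}

predict_knn <- function(model, newx) {
  train <- model$model$x
  y <- model$model$y
  k <- min(model$spec$k_neighbors, nrow(train))
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(newx^2), rowSums(train^2), "+") -
    2 * tcrossprod(newx, train)
  d2[d2 < 0] <- 0
  sid <- rownames(train)
  apply(d2, 1, function(drow) {
    # stable order on (distance, sample id): permutation-invariant ties
    ord <- order(drow, sid)
    nn <- ord[seq_len(k)]
    votes <- table(y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # vote tie (possible after distance-tie truncation): defer to the
      # single nearest neighbour
      as.character(y[ord[1L]])
    } else {
      top
    }
  })
}

predict_kernel_nb <- function(model, newx) {
  classes <- names(model$model)
  loglik <- vapply(classes, function(cl) {
    st <- model$model[[cl]]
    ll <- rep(log(st$prior), nrow(newx))
    for (j in seq_len(ncol(newx))) {
      dens <- vapply(newx[, j], function(v) {
        mean(stats::dnorm(v, mean = st$x[, j], sd = st$bw[[j]]))
      }, numeric(1))
      ll <- ll + log(pmax(dens, .Machine$double.xmin))
    }
    ll
  }, numeric(nrow(newx)))
  loglik <- matrix(loglik, nrow = nrow(newx))
  # tie -> first class level ("down"), a fixed documented rule
  classes[max.col(loglik, ties.method = "first")]
}

#' Count misclassified test samples
#'
#' @param model A `fitted_classifier`.
#' @param x Test feature matrix (samples x probes).
#' @param y True labels.
#' @return Integer count in `[0, nrow(x)]`.
#' @export
misclassification_count <- function(model, x, y) {
  y <- as_label_factor(y)
  sum(predict_classifier(model, x) != y)
}
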