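# Cross-validation plans and the CV error score driving the SFS wrapper.
#
# One plan is built per gene (seeded from the global seed and the gene id)
# and reused for every candidate evaluation within that gene, so the
# greedy argmin compares candidates on identical folds.

#' Build a stratified k-fold cross-validation plan
#'
#' Samples are shuffled within class and dealt cyclically across folds, so
#' fold sizes differ by at most one and per-fold class counts stay within
#' one sample of the global proportions. When fewer samples than folds are
#' available the fold count is reduced to the sample count.
#'
#' @param labels A [label_vector()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify folds by class (default TRUE).
#' @return A `cv_plan`: list with `n_folds`, integer `fold` assignment
#'   named by sample id, `stratified`, `seed`.
#' @export
make_cv_plan <- function(labels, n_folds = 10, seed = 450,
                         stratified = TRUE) {
  stopifnot(inherits(labels, "label_vector"))
  n <- length(labels$labels)
  if (n < 2) {
    abort("need at least 2 labeled samples for cross-validation")
  }
  counts <- table(labels$labels)
  if (any(counts < 1)) {
    abort("both classes must be present to build a CV plan")
  }
  if (n < n_folds) {
    inform(sprintf("reducing folds from %d to %d (sample count)",
                   n_folds, n))
    n_folds <- n
  }
  idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(LABEL_LEVELS, function(cl) {
        members <- which(labels$labels == cl)
        if (length(members) > 1) sample(members) else members
      }), use.names = FALSE)
    } else {
      sample(n)
    }
  })
  fold <- integer(n)
  fold[idx] <- rep_len(seq_len(n_folds), n)
  structure(list(n_folds = as.integer(n_folds),
                 fold = setNames(fold, labels$sample_ids),
                 stratified = stratified, seed = seed),
            class = "cv_plan")
}

#' Cross-validated classification error for a probe subset
#'
#' For each fold, fits the classifier on the out-of-fold samples and counts
#' the misclassified in-fold samples (`O`); the score is the mean of `O`
#' over folds — a mean per-fold misclassification *count*, not a rate.
#' Because folds differ in size by at most one, this is proportional to the
#' misclassification rate; [cv_error_rate()] rescales it to a fraction.
#'
#' A training fold that collapses to a single class (possible for SVMs,
#' which cannot fit then) falls back to predicting the majority training
#' label for that fold.
#'
#' @param spec A [classifier_spec()].
#' @param probes Character vector of probe ids (non-empty).
#' @param M A [methyl_matrix()] containing those probes.
#' @param labels A [label_vector()]; its samples must be columns of `M`.
#' @param plan A [make_cv_plan()] over the same samples.
#' @return Mean per-fold misclassification count (numeric scalar).
#' @export
cv_error <- function(spec, probes, M, labels, plan) {
  if (length(probes) == 0) {
    abort("probes must be non-empty")
  }
  x <- t(unclass(M)[probes, labels$sample_ids, drop = FALSE])
  y <- labels$labels
  fold <- plan$fold[labels$sample_ids]
  o <- vapply(seq_len(plan$n_folds), function(f) {
    test <- fold == f
    fold_error(spec, x[!test, , drop = FALSE], y[!test],
               x[test, , drop = FALSE], y[test])
  }, numeric(1))
  mean(o)
}

fold_error <- function(spec, x_train, y_train, x_test, y_test) {
  if (nrow(x_test) == 0) {
    return(0)
  }
  model <- tryCatch(fit_classifier(spec, x_train, y_train),
                    error = function(e) NULL)
  if (is.null(model)) {
    # degenerate training fold: majority-of-train prediction
    maj <- majority_label(y_train)
    return(sum(y_test != maj))
  }
  sum(predict_classifier(model, x_test) != y_test)
}

majority_label <- function(y) {
  counts <- table(y)
  # tie -> first level ("down"), fixed rule
  names(counts)[which.max(counts)]
}

#' @rdname cv_error
#' @return `cv_error_rate()` returns the corresponding misclassified
#'   fraction of samples, in `[0, 1]`.
#' @export
cv_error_rate <- function(spec, probes, M, labels, plan) {
  cv_error(spec, probes, M, labels, plan) * plan$n_folds /
    length(labels$labels)
}
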