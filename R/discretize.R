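# Discretization of continuous expression into up/down/baseline labels.
#
# Two designs are supported: paired ratios (e.g. mock vs aza-treated cell
# lines, one ratio per sample) thresholded at 1.1-fold, and
# median-referenced absolute expression (e.g. tumour panels) thresholded at
# 1.2-fold against the per-gene median across samples. Thresholds act on
# the linear-ratio scale with reciprocal symmetry: up when r >= t, down
# when r <= 1/t, baseline otherwise. Baseline samples are removed.

#' Discretization settings
#'
#' @param mode `"paired_ratio"`: each value is already a per-sample
#'   expression ratio; `"median_reference"`: each value is an absolute
#'   measurement, referenced to the gene's median across samples.
#' @param fold_threshold Fold-change threshold `t > 1`. Defaults to 1.1 for
#'   paired ratios (cell-line design) and 1.2 for median-referenced data
#'   (tissue design, where more noise is expected).
#' @param scale Scale the input values are on: `"linear_ratio"`, `"log2"`
#'   or `"log10"`. Log-scale inputs are converted to linear ratios before
#'   thresholding.
#' @return A `discretization_config` list.
#' @export
discretization_config <- function(mode = c("paired_ratio",
                                           "median_reference"),
                                  fold_threshold = NULL,
                                  scale = c("linear_ratio", "log2",
                                            "log10")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (is.null(fold_threshold)) {
    fold_threshold <- if (mode == "paired_ratio") 1.1 else 1.2
  }
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      fold_threshold <= 1) {
    abort("fold_threshold must be a single number > 1")
  }
  structure(list(mode = mode, fold_threshold = fold_threshold,
                 scale = scale),
            class = "discretization_config")
}

to_linear <- function(values, scale) {
  switch(scale,
         linear_ratio = values,
         log2 = 2^values,
         log10 = 10^values)
}

#' Discretize one gene's expression into up/down labels
#'
#' Converts values to linear-scale ratios (dividing by the per-gene median
#' in `median_reference` mode), labels each sample up (`r >= t`), down
#' (`r <= 1/t`) or baseline, and drops the baseline samples.
#'
#' @param values Numeric vector of expression values for one gene, named by
#'   sample id (or provide `sample_ids`).
#' @param config A [discretization_config()].
#' @param gene_id Gene identifier stored in the result.
#' @param sample_ids Sample ids aligned to `values`; defaults to
#'   `names(values)`.
#' @return A [label_vector()] over the non-baseline samples; empty when all
#'   samples are baseline (callers must check [usable_gene()]).
#' @export
discretize_gene <- function(values, config, gene_id = "gene",
                            sample_ids = names(values)) {
  stopifnot(inherits(config, "discretization_config"))
  if (is.null(sample_ids)) {
    abort("values must be named by sample id (or pass sample_ids)")
  }
  if (length(sample_ids) != length(values)) {
    abort("sample_ids and values differ in length")
  }
  lin <- to_linear(values, config$scale)
  if (config$mode == "median_reference") {
    if (length(lin) < 3) {
      warn(sprintf("gene %s: median reference over fewer than 3 samples",
                   gene_id))
    }
    if (any(lin <= 0)) {
      abort(sprintf(
        "gene %s: non-positive linear-scale values under median_reference",
        gene_id))
    }
    r <- lin / stats::median(lin)
  } else {
    r <- lin
  }
  t <- config$fold_threshold
  lab <- rep(NA_character_, length(r))
  lab[r >= t] <- "up"
  lab[r <= 1 / t] <- "down"
  keep <- !is.na(lab)
  label_vector(gene_id, sample_ids[keep], lab[keep])
}

#' Discretize every gene of an expression matrix
#'
#' @param expression An [expr_matrix()]; its `mode` attribute selects the
#'   discretization design unless `config` is supplied.
#' @param config Optional [discretization_config()] overriding the
#'   defaults.
#' @return Named list of [label_vector()]s, one per gene (possibly empty
#'   vectors for all-baseline genes).
#' @export
discretize_expression <- function(expression, config = NULL) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (is.null(config)) {
    config <- discretization_config(mode = attr(expression, "mode"))
  }
  genes <- rownames(expression)
  out <- lapply(genes, function(g) {
    discretize_gene(unclass(expression)[g, ], config, gene_id = g)
  })
  setNames(out, genes)
}

#' Is a gene usable for selection and evaluation?
#'
#' A gene is usable when enough non-baseline samples remain and both
#' classes are represented. The defaults (10 samples, 2 per class) keep
#' 10-fold cross-validation meaningful.
#'
#' @param labels A [label_vector()].
#' @param min_samples Minimum total labeled samples.
#' @param min_per_class Minimum samples in each of up/down.
#' @return `TRUE` or `FALSE`.
#' @export
usable_gene <- function(labels, min_samples = 10, min_per_class = 2) {
  stopifnot(inherits(labels, "label_vector"))
  n <- length(labels$labels)
  if (n < min_samples) {
    return(FALSE)
  }
  counts <- table(labels$labels)
  all(counts >= min_per_class)
}
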