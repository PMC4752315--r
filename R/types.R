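# Core containers: beta-value and expression matrices, per-gene label
# vectors. Matrices are plain numeric matrices (rows = probes or genes,
# columns = samples) carrying a class attribute for validation and printing.

#' Construct a methylation (beta-value) matrix
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   both dimnames set. Beta values must lie in `[0, 1]` unless
#'   `permissive = TRUE`.
#' @param permissive Allow values outside `[0, 1]` (e.g. slightly negative
#'   background-corrected betas).
#' @return The matrix with class `methyl_matrix`.
#' @export
methyl_matrix <- function(values, permissive = FALSE) {
  values <- validate_id_matrix(values, "probe")
  if (anyNA(values)) {
    abort("beta matrix contains missing values; handle them at load time")
  }
  if (!permissive && (min(values) < 0 || max(values) > 1)) {
    abort("beta values outside [0, 1]; use permissive = TRUE to keep them")
  }
  structure(values, class = c("methyl_matrix", class(matrix())))
}

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   both dimnames set.
#' @param mode `"paired_ratio"` for paired (e.g. mock/aza) ratios, or
#'   `"median_reference"` for absolute values to be referenced to the
#'   per-gene median at discretization time.
#' @return The matrix with class `expr_matrix` and a `mode` attribute.
#' @export
expr_matrix <- function(values, mode = c("paired_ratio", "median_reference")) {
  mode <- match.arg(mode)
  values <- validate_id_matrix(values, "gene")
  if (anyNA(values)) {
    abort("expression matrix contains missing values")
  }
  structure(values, mode = mode,
            class = c("expr_matrix", class(matrix())))
}

validate_id_matrix <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort(paste0(what, " matrix must be a numeric matrix"))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(paste0(what, " matrix needs rownames (", what,
                 " ids) and colnames (sample ids)"))
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort(paste0("duplicate ", what, " or sample ids in matrix"))
  }
  values
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix: %d probes x %d samples>\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix (%s): %d genes x %d samples>\n",
              attr(x, "mode"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' Per-gene binary label vector
#'
#' Holds the up/down labels of one gene after baseline samples were removed.
#'
#' @param gene_id Gene identifier.
#' @param sample_ids Character vector of sample ids (baseline removed).
#' @param labels Character or factor vector of `"up"`/`"down"`, aligned to
#'   `sample_ids`.
#' @return A `label_vector` object.
#' @export
label_vector <- function(gene_id, sample_ids, labels) {
  labels <- as_label_factor(labels)
  if (length(labels) != length(sample_ids)) {
    abort("labels and sample_ids differ in length")
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample ids in label vector")
  }
  structure(list(gene_id = as.character(gene_id),
                 sample_ids = as.character(sample_ids),
                 labels = labels),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_vector %s: %d samples (%d down, %d up)>\n",
              x$gene_id, length(x$labels), tab[["down"]], tab[["up"]]))
  invisible(x)
}

#' @export
length.label_vector <- function(x) length(x$labels)

#' Align methylation and expression matrices on shared samples
#'
#' Restricts both matrices to the intersection of their sample ids, in
#' methylation-matrix order. Non-overlapping samples are dropped with a
#' message.
#'
#' @param methylation A [methyl_matrix()].
#' @param expression An [expr_matrix()].
#' @return A list with elements `methylation` and `expression`.
#' @export
align_samples <- function(methylation, expression) {
  shared <- intersect(colnames(methylation), colnames(expression))
  if (length(shared) == 0) {
    abort("no shared sample ids between methylation and expression")
  }
  dropped <- length(union(colnames(methylation), colnames(expression))) -
    length(shared)
  if (dropped > 0) {
    inform(sprintf("align_samples: dropping %d non-overlapping sample(s)",
                   dropped))
  }
  mode <- attr(expression, "mode")
  list(
    methylation = methyl_matrix(unclass(methylation)[, shared, drop = FALSE],
                                permissive = TRUE),
    expression = expr_matrix(unclass(expression)[, shared, drop = FALSE],
                             mode = mode)
  )
}
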