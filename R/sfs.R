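# Sequential forward selection (SFS) wrapper.
#
# For one gene with candidate probes X: evaluate each candidate alone in a
# k-fold CV, move the argmin-error probe into the selected set S; then
# repeatedly evaluate S u {x} for every remaining candidate and accept the
# argmin only while it strictly improves on the incumbent error (OCE).
# Ties at the argmin go to the lowest candidate index. The same CV plan is
# reused for every evaluation, so comparisons are paired.

#' Select probes for one gene by sequential forward selection
#'
#' @param spec A [classifier_spec()] used inside the CV objective.
#' @param gene_id Gene identifier (stored in the result).
#' @param candidates Ordered character vector of candidate probe ids
#'   (manifest order); must be non-empty.
#' @param M A [methyl_matrix()] containing the candidates.
#' @param labels A [label_vector()] for the gene.
#' @param plan A [make_cv_plan()]; reused across all evaluations.
#' @return A `probe_selection` object: `gene_id`, `method`,
#'   `selected` (ordered probe ids), `final_cv_error` (misclassified
#'   fraction, in `[0, 1]`), and a `trace` tibble with one row per
#'   candidate evaluation (`round`, `candidate`, `cce` — the mean per-fold
#'   misclassification count — and `accepted`).
#' @export
sfs_select <- function(spec, gene_id, candidates, M, labels, plan) {
  if (length(candidates) == 0) {
    abort("sfs_select needs at least one candidate probe")
  }
  n <- length(labels$labels)
  remaining <- candidates
  selected <- character(0)
  trace <- list()
  round <- 1L

  # round 1: each candidate alone; the argmin is always accepted
  cce <- vapply(remaining, function(p) {
    cv_error(spec, p, M, labels, plan)
  }, numeric(1), USE.NAMES = FALSE)
  j <- which.min(cce) # ties -> lowest candidate index
  trace[[round]] <- tibble(round = round, candidate = remaining,
                           cce = unname(cce),
                           accepted = seq_along(remaining) == j)
  selected <- remaining[j]
  oce <- cce[[j]]
  remaining <- remaining[-j]

  # growth rounds: accept only strict improvement
  while (length(remaining) > 0) {
    round <- round + 1L
    cce <- vapply(remaining, function(p) {
      cv_error(spec, c(selected, p), M, labels, plan)
    }, numeric(1), USE.NAMES = FALSE)
    j <- which.min(cce)
    improved <- cce[[j]] < oce
    trace[[round]] <- tibble(round = round, candidate = remaining,
                             cce = unname(cce),
                             accepted = improved &
                               seq_along(remaining) == j)
    if (!improved) {
      break
    }
    selected <- c(selected, remaining[j])
    oce <- cce[[j]]
    remaining <- remaining[-j]
  }

  new_probe_selection(
    gene_id = gene_id,
    method = paste0("sfs_", classifier_label(spec)),
    selected = selected,
    final_cv_error = oce * plan$n_folds / n,
    trace = dplyr::bind_rows(trace))
}

new_probe_selection <- function(gene_id, method, selected, final_cv_error,
                                trace = NULL) {
  structure(list(gene_id = as.character(gene_id), method = method,
                 selected = as.character(selected),
                 final_cv_error = as.numeric(final_cv_error),
                 trace = trace),
            class = "probe_selection")
}

#' @export
print.probe_selection <- function(x, ...) {
  cat(sprintf("<probe_selection %s [%s]: %d probe(s), cv error %.3f>\n",
              x$gene_id, x$method, length(x$selected), x$final_cv_error))
  if (length(x$selected) > 0) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
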