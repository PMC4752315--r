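# broom-style tidiers for the package's result objects.

#' Tidy a probe selection
#'
#' Returns the selection trace: one row per candidate evaluation with the
#' round number, the candidate probe, the CV error (mean per-fold
#' misclassification count) and whether the candidate was accepted.
#'
#' @param x A `probe_selection`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.probe_selection <- function(x, ...) {
  if (is.null(x$trace)) {
    return(tibble(round = integer(0), candidate = character(0),
                  cce = numeric(0), accepted = logical(0)))
  }
  as_tibble(x$trace)
}

#' @rdname tidy.probe_selection
#' @return `glance()` returns a one-row tibble with `gene_id`, `method`,
#'   `n_selected`, `probes` (comma-joined) and `final_cv_error`.
#' @export
glance.probe_selection <- function(x, ...) {
  tibble(gene_id = x$gene_id, method = x$method,
         n_selected = length(x$selected),
         probes = paste(x$selected, collapse = ","),
         final_cv_error = x$final_cv_error)
}

#' Tidy ReliefF weights
#'
#' @param x A `relieff_state`.
#' @param ... Unused.
#' @return Tibble with `probe_id`, `weight` and `rank` (1 = highest
#'   weight).
#' @export
tidy.relieff_state <- function(x, ...) {
  ranking <- relieff_rank(x)
  tibble(probe_id = names(x$weights),
         weight = unname(x$weights),
         rank = match(names(x$weights), ranking))
}

#' Tidy confusion counts
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return One-row tibble of counts and derived metrics, as
#'   [metrics_from_confusion()].
#' @export
tidy.confusion_counts <- function(x, ...) {
  metrics_from_confusion(x)
}

#' Glance at a pipeline run
#'
#' @param x A `methylsel_run`.
#' @param ... Unused.
#' @return One-row tibble: method, genes evaluated/skipped, mean MCC and
#'   mean selected-probe count.
#' @export
glance.methylsel_run <- function(x, ...) {
  tibble(method = x$method,
         n_genes = nrow(x$evaluation),
         n_skipped = nrow(x$skips),
         mean_mcc = if (nrow(x$evaluation)) {
           mean(x$evaluation$mcc, na.rm = TRUE)
         } else {
           NA_real_
         },
         mean_n_probes = if (nrow(x$selection)) {
           mean(x$selection$n_selected)
         } else {
           NA_real_
         })
}
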