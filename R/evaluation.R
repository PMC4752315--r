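# Leave-one-out assessment of a probe selection and confusion-based
# metrics. Convention throughout: down-expressed samples are the positive
# class, up-expressed the negative class.

#' Leave-one-out confusion counts for a probe selection
#'
#' Each sample in turn is predicted by a classifier fitted on all other
#' samples, using the selected probes as features. When the training
#' remainder collapses to a single class (SVMs cannot fit then) the
#' majority training label is predicted instead.
#'
#' @param spec A [classifier_spec()].
#' @param probes Non-empty character vector of selected probe ids.
#' @param M A [methyl_matrix()].
#' @param labels A [label_vector()] with at least 2 samples.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`
#'   (`tp` = predicted down & truly down).
#' @export
loo_confusion <- function(spec, probes, M, labels) {
  if (length(probes) == 0) {
    abort("probes must be non-empty")
  }
  n <- length(labels$labels)
  if (n < 2) {
    abort("leave-one-out needs at least 2 samples")
  }
  x <- t(unclass(M)[probes, labels$sample_ids, drop = FALSE])
  y <- labels$labels
  pred <- vapply(seq_len(n), function(i) {
    model <- tryCatch(
      fit_classifier(spec, x[-i, , drop = FALSE], y[-i]),
      error = function(e) NULL)
    if (is.null(model)) {
      majority_label(y[-i])
    } else {
      as.character(predict_classifier(model, x[i, , drop = FALSE]))
    }
  }, character(1))
  confusion_counts(
    tp = sum(pred == "down" & y == "down"),
    tn = sum(pred == "up" & y == "up"),
    fp = sum(pred == "down" & y == "up"),
    fn = sum(pred == "up" & y == "down"))
}

#' Confusion counts (down = positive)
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Metrics from a confusion table
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any zero factor
#' in the MCC denominator yields MCC 0 (standard convention, keeps means
#' defined); an undefined rate (0/0) is reported as `NA` and excluded from
#' summary means.
#'
#' @param counts A [confusion_counts()].
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `specificity`, `mcc`.
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort("confusion table is empty")
  }
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = (tp + tn) / total,
         precision = rate(tp, tp + fp),
         recall = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         mcc = mcc)
}

#' Evaluate one gene's probe selection by LOO-CV
#'
#' @inheritParams loo_confusion
#' @param gene_id,method Identifiers stored in the output row.
#' @return One-row tibble: identifiers, classifier label, `n_probes`,
#'   confusion counts and metrics.
#' @export
evaluate_selection <- function(spec, probes, M, labels,
                               gene_id = labels$gene_id,
                               method = "manual") {
  counts <- loo_confusion(spec, probes, M, labels)
  dplyr::bind_cols(
    tibble(gene_id = gene_id, method = method,
           classifier = classifier_label(spec),
           n_probes = length(probes)),
    metrics_from_confusion(counts))
}

#' Stratify genes by MCC
#'
#' Splits evaluation records into a high-confidence list (`mcc > high`,
#' the putatively DNA methylation-sensitive genes) and a low list
#' (`mcc < low`). Inequalities are strict; genes at the thresholds fall in
#' neither list. Lists are sorted for deterministic export.
#'
#' @param records Evaluation tibble (rows from [evaluate_selection()]).
#' @param high,low MCC cutoffs (defaults 0.6 and 0.2).
#' @return List with character vectors `high` and `low`.
#' @export
stratify_by_mcc <- function(records, high = 0.6, low = 0.2) {
  list(high = sort(records$gene_id[!is.na(records$mcc) &
                                     records$mcc > high]),
       low = sort(records$gene_id[!is.na(records$mcc) &
                                    records$mcc < low]))
}

#' Exact hypergeometric overlap test for two gene lists
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene lists drawn from a common universe, by explicit summation of
#' the hypergeometric mass function.
#'
#' @param list_a,list_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return `P[overlap >= observed]`.
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("universe must be non-empty")
  }
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    abort("both gene lists must be subsets of the universe")
  }
  obs <- length(intersect(list_a, list_b))
  m <- length(list_a)
  k <- length(list_b)
  upper <- min(m, k)
  sum(stats::dhyper(obs:upper, m, length(universe) - m, k))
}

#' Summarize evaluation records per method
#'
#' Means and medians of each metric per (method, classifier), with
#' undefined (`NA`) metrics excluded from the aggregation.
#'
#' @param records Evaluation tibble.
#' @return Tibble with one row per method/classifier pair.
#' @export
summarize_evaluations <- function(records) {
  metrics <- c("accuracy", "precision", "recall", "specificity", "mcc")
  records |>
    dplyr::group_by(.data$method, .data$classifier) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         median = ~stats::median(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' Histogram of selected-probe counts per gene
#'
#' @param selection Selection tibble (columns `gene_id`, `probes`
#'   list-column or `n_selected`).
#' @return Tibble with `n_selected` and `n_genes`.
#' @export
probe_count_histogram <- function(selection) {
  n_sel <- if ("n_selected" %in% names(selection)) {
    selection$n_selected
  } else {
    vapply(selection$probes, length, integer(1))
  }
  tibble(n_selected = n_sel) |>
    dplyr::count(.data$n_selected, name = "n_genes")
}
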