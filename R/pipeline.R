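# Genome-wide orchestration: discretize every gene, select probes with the
# requested method, assess the selection by LOO-CV and summarize. Genes
# that fail the usability rules or raise an error are skipped with a
# recorded reason; per-gene seeds are derived from the global seed and the
# gene id, so results do not depend on gene order.

#' Run the per-gene selection and evaluation pipeline over all genes
#'
#' @param methylation A [methyl_matrix()].
#' @param expression An [expr_matrix()] (samples are aligned to the
#'   methylation matrix with [align_samples()]).
#' @param annotation Annotation tibble from [read_manifest()] or
#'   [simulate_dataset()].
#' @param method Selection method: `"sfs"`, `"svm_rfe"`, `"relieff"`,
#'   `"ga_knn"`, `"random"`, `"top_two"`, `"all"`,
#'   `"upstream_cpg_island"`, `"tss_window"` or `"top_sd"`.
#' @param classifier A [classifier_spec()]. Drives the SFS objective and,
#'   for SFS and the expression-agnostic selectors, the LOO-CV assessment.
#'   Rank/GA selectors use their conventional evaluation model regardless
#'   (KNN for ReliefF/GA-KNN/controls, Gaussian-kernel SVM for SVM-RFE).
#' @param config Optional [discretization_config()]; defaults follow the
#'   expression matrix's mode (1.1-fold for paired ratios, 1.2-fold for
#'   median-referenced data).
#' @param n_folds CV folds for the SFS objective (default 10).
#' @param min_samples,min_per_class Gene usability rules, see
#'   [usable_gene()].
#' @param seed Global seed; per-gene seeds are `gene_seed(seed, gene_id)`.
#' @param tss_window TSS window half-width for the `"tss_window"`
#'   selector.
#' @param reference_selection Optional selection tibble from a previous
#'   run (typically SFS): `"random"`, `"svm_rfe"` and `"relieff"` take
#'   their per-gene probe count k from it, matching the paired-comparison
#'   design. Without it k defaults to 1.
#' @param ga Optional [ga_config()] template for `method = "ga_knn"` (its
#'   seed is re-derived per gene).
#' @return A `methylsel_run` list: `selection` tibble (`gene_id`,
#'   `method`, `probes` list-column, `n_selected`, `final_cv_error`),
#'   `evaluation` tibble (one row per gene, see [evaluate_selection()]),
#'   `summary` ([summarize_evaluations()]), and `skips` tibble
#'   (`gene_id`, `reason`).
#' @export
run_genome <- function(methylation, expression, annotation,
                       method = c("sfs", "svm_rfe", "relieff", "ga_knn",
                                  "random", "top_two", "all",
                                  "upstream_cpg_island", "tss_window",
                                  "top_sd"),
                       classifier = classifier_spec("knn", k_neighbors = 1),
                       config = NULL, n_folds = 10, min_samples = 10,
                       min_per_class = 2, seed = 450, tss_window = 2500,
                       reference_selection = NULL, ga = NULL) {
  method <- match.arg(method)
  aligned <- align_samples(methylation, expression)
  M <- aligned$methylation
  E <- aligned$expression
  if (is.null(config)) {
    config <- discretization_config(mode = attr(E, "mode"))
  }
  gene_map <- build_gene_probe_map(annotation)
  genes <- names(gene_map)

  ref_k <- NULL
  if (!is.null(reference_selection)) {
    n_sel <- if ("n_selected" %in% names(reference_selection)) {
      reference_selection$n_selected
    } else {
      vapply(reference_selection$probes, length, integer(1))
    }
    ref_k <- setNames(n_sel, reference_selection$gene_id)
  }

  sel_rows <- list()
  eval_rows <- list()
  skip_rows <- list()
  for (gene in genes) {
    res <- tryCatch(
      run_one_gene(gene, gene_map[[gene]], M, E, annotation, method,
                   classifier, config, n_folds, min_samples, min_per_class,
                   seed, tss_window, ref_k, ga),
      error = function(e) list(skip = conditionMessage(e)))
    if (!is.null(res$skip)) {
      skip_rows[[gene]] <- tibble(gene_id = gene, reason = res$skip)
    } else {
      sel_rows[[gene]] <- res$selection
      eval_rows[[gene]] <- res$evaluation
    }
  }

  selection <- dplyr::bind_rows(sel_rows)
  evaluation <- dplyr::bind_rows(eval_rows)
  skips <- if (length(skip_rows) > 0) {
    dplyr::bind_rows(skip_rows)
  } else {
    tibble(gene_id = character(0), reason = character(0))
  }
  if (length(genes) > 0 && nrow(skips) > length(genes) / 2) {
    warn(sprintf("more than half of the genes were skipped (%d of %d)",
                 nrow(skips), length(genes)))
  }
  structure(list(
    selection = selection,
    evaluation = evaluation,
    summary = if (nrow(evaluation) > 0) summarize_evaluations(evaluation)
              else tibble(),
    skips = skips,
    method = method, seed = seed),
    class = "methylsel_run")
}

run_one_gene <- function(gene, candidates, M, E, annotation, method,
                         classifier, config, n_folds, min_samples,
                         min_per_class, seed, tss_window, ref_k, ga) {
  if (length(candidates) == 0) {
    return(list(skip = "no annotated probes"))
  }
  labels <- discretize_gene(unclass(E)[gene, ], config, gene_id = gene)
  if (!usable_gene(labels, min_samples, min_per_class)) {
    return(list(skip = "unusable after discretization"))
  }
  gseed <- gene_seed(seed, gene)
  k_ref <- if (!is.null(ref_k) && gene %in% names(ref_k)) {
    max(1L, min(ref_k[[gene]], length(candidates)))
  } else {
    1L
  }

  knn_spec <- if (classifier$family == "knn") classifier else
    classifier_spec("knn", k_neighbors = 1)

  sel <- switch(method,
    sfs = {
      plan <- make_cv_plan(labels, n_folds, seed = gseed)
      sfs_select(classifier, gene, candidates, M, labels, plan)
    },
    svm_rfe = {
      probes <- if (length(candidates) >= 2) {
        select_top_k(svm_rfe_rank(candidates, M, labels), k_ref)
      } else {
        candidates
      }
      new_probe_selection(gene, "svm_rfe", probes, NA_real_)
    },
    relieff = {
      state <- relieff_weights(candidates, M, labels,
                               k_neighbors = knn_spec$k_neighbors,
                               seed = gseed)
      new_probe_selection(
        gene, paste0("relieff_k", knn_spec$k_neighbors),
        select_top_k(relieff_rank(state), min(k_ref, length(candidates))),
        NA_real_)
    },
    ga_knn = {
      cfg <- ga %||% ga_config(k_neighbors = knn_spec$k_neighbors)
      cfg$seed <- gseed
      ga_knn_select(candidates, M, labels, cfg)
    },
    random = new_probe_selection(
      gene, "random", control_random(candidates, k_ref, seed = gseed),
      NA_real_),
    top_two = new_probe_selection(
      gene, "top_two",
      control_top_two_correlated(
        candidates, M, unclass(E)[gene, labels$sample_ids]),
      NA_real_),
    # annotation-driven selectors
    {
      probes <- suppressWarnings(select_annotation_based(
        method, gene, candidates, annotation, M, window_bp = tss_window))
      if (length(probes) == 0) {
        return(list(skip = sprintf("no probe passes selector '%s'", method)))
      }
      new_probe_selection(gene, method, probes, NA_real_)
    })

  if (length(sel$selected) == 0) {
    return(list(skip = "selector returned no probes"))
  }

  eval_spec <- switch(method,
    sfs = classifier,
    svm_rfe = classifier_spec(
      "svm_gaussian",
      class_weights = {
        w <- balance_weights(labels)
        c(down = w$w0, up = w$w1)
      }),
    relieff = ,
    ga_knn = ,
    random = ,
    top_two = knn_spec,
    classifier)

  list(
    selection = tibble(gene_id = gene, method = sel$method,
                       probes = list(sel$selected),
                       n_selected = length(sel$selected),
                       final_cv_error = sel$final_cv_error),
    evaluation = evaluate_selection(eval_spec, sel$selected, M, labels,
                                    gene_id = gene, method = sel$method))
}

#' @export
print.methylsel_run <- function(x, ...) {
  cat(sprintf("<methylsel_run [%s]: %d gene(s) evaluated, %d skipped>\n",
              x$method, nrow(x$evaluation), nrow(x$skips)))
  if (nrow(x$summary) > 0) {
    print(x$summary)
  }
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Emits `selection.tsv`, `evaluation.tsv`, `summary.tsv` and `skips.tsv`
#' under `dir`. Output is deterministic: rows sorted by gene id, numbers
#' formatted with 10 significant digits.
#'
#' @param run A `methylsel_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "methylsel_run"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_selection_results(run$selection, file.path(dir, "selection.tsv"))
  write_numeric_tsv <- function(df, path) {
    df <- dplyr::arrange(df, dplyr::across(dplyr::any_of("gene_id")))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_numeric_tsv(run$evaluation, file.path(dir, "evaluation.tsv"))
  write_numeric_tsv(run$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(dplyr::arrange(run$skips, .data$gene_id),
                   file.path(dir, "skips.tsv"), progress = FALSE)
  invisible(dir)
}
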