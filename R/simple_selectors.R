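# Control selectors (random, top-two-correlated) and expression-agnostic
# selectors driven by manifest annotation (all probes, upstream CpG
# islands, TSS windows, top standard deviation).

#' Take the top k probes of a ranking
#'
#' @param ranking Character vector of probe ids, best first.
#' @param k Number to keep (>= 1). If `k` exceeds the ranking length, all
#'   probes are returned with a warning.
#' @return Character vector of length `min(k, length(ranking))`.
#' @export
select_top_k <- function(ranking, k) {
  assert_scalar_count(k, "k")
  if (k > length(ranking)) {
    warn(sprintf("k = %d exceeds ranking length %d; returning all probes",
                 k, length(ranking)))
    return(ranking)
  }
  ranking[seq_len(k)]
}

#' Random probe selection (control)
#'
#' Draws `k` probes uniformly without replacement. `k` is normally matched
#' per gene to the number of probes the SFS wrapper selected, so the
#' control differs only in *which* probes it picks.
#'
#' @param candidates Ordered character vector of probe ids.
#' @param k Number of probes to draw.
#' @param seed RNG seed.
#' @return Character vector of `k` probe ids.
#' @export
control_random <- function(candidates, k, seed = 450) {
  assert_scalar_count(k, "k")
  if (k > length(candidates)) {
    abort("k exceeds the number of candidate probes")
  }
  with_seed(seed, sample(candidates, k))
}

#' Top-two-correlated probe selection (control)
#'
#' Ranks candidates by the absolute Pearson correlation between their beta
#' values and the gene's continuous expression over the labeled
#' (non-baseline) samples, and keeps the top two. Constant probes get
#' correlation 0; with fewer than two candidates all are returned.
#'
#' @param candidates Ordered character vector of probe ids.
#' @param M A [methyl_matrix()].
#' @param expression_values Numeric vector of continuous expression named
#'   by sample id; only samples present in `M` are used.
#' @return Character vector of (up to) two probe ids.
#' @export
control_top_two_correlated <- function(candidates, M, expression_values) {
  if (length(candidates) < 2) {
    return(candidates)
  }
  samples <- intersect(names(expression_values), colnames(M))
  if (length(samples) < 3) {
    abort("need at least 3 shared samples to compute correlations")
  }
  e <- expression_values[samples]
  r <- vapply(candidates, function(p) {
    b <- unclass(M)[p, samples]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) {
      return(0)
    }
    stats::cor(b, e)
  }, numeric(1))
  candidates[order(-abs(r), seq_along(candidates))][1:2]
}

#' Expression-agnostic probe selection from manifest annotation
#'
#' @param method One of:
#'   * `"all"`: every candidate probe;
#'   * `"upstream_cpg_island"`: probes in a CpG island whose region group
#'     for this gene is upstream (TSS200, TSS1500, 5'UTR or 1stExon);
#'   * `"tss_window"`: probes with `|tss_distance| <= window_bp`
#'     (inclusive boundary);
#'   * `"top_sd"`: the single probe with the highest beta standard
#'     deviation across samples (ties to the lower candidate index).
#' @param gene Gene id (used to look up per-gene region groups).
#' @param candidates Ordered character vector of probe ids for this gene.
#' @param annotation Annotation tibble from [read_manifest()].
#' @param M A [methyl_matrix()] (required for `"top_sd"`).
#' @param window_bp TSS window half-width in bp (default 2500).
#' @return Character vector of selected probes; empty (with a warning)
#'   when no candidate satisfies the rule.
#' @export
select_annotation_based <- function(method = c("all", "upstream_cpg_island",
                                               "tss_window", "top_sd"),
                                    gene, candidates, annotation = NULL,
                                    M = NULL, window_bp = 2500) {
  method <- match.arg(method)
  out <- switch(method,
    all = candidates,
    upstream_cpg_island = {
      ann <- annotation_for(annotation, gene, candidates)
      keep <- ann$island_relation == "Island" &
        ann$region_group %in% UPSTREAM_GROUPS
      intersect(candidates, ann$probe_id[keep])
    },
    tss_window = {
      ann <- annotation_for(annotation, gene, candidates)
      keep <- !is.na(ann$tss_distance) & abs(ann$tss_distance) <= window_bp
      intersect(candidates, ann$probe_id[keep])
    },
    top_sd = {
      stopifnot(!is.null(M))
      sds <- apply(unclass(M)[candidates, , drop = FALSE], 1, stats::sd)
      candidates[which.max(sds)] # ties -> lower candidate index
    })
  if (length(out) == 0) {
    warn(sprintf("gene %s: no probe satisfies selector '%s'", gene, method))
  }
  out
}

annotation_for <- function(annotation, gene, candidates) {
  if (is.null(annotation)) {
    abort("this selector needs the annotation table")
  }
  ann <- annotation[!is.na(annotation$gene) & annotation$gene == gene &
                      annotation$probe_id %in% candidates, , drop = FALSE]
  ann
}
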