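# Seeded synthetic-data generator: 450K-like beta matrices, manifest-style
# annotation and expression with planted probe-expression relationships,
# so selection and evaluation are benchmarkable without any download.
#
# Informative probes follow a truncated normal on [0, 1] with
# class-conditional means (so mean and sd are controlled directly); noise
# probes are class-independent Beta(2, 2). Expression is generated
# deterministically from the planted labels at ratios that discretize back
# to those labels exactly: up samples sit at 1.5x the fold threshold,
# down samples at its reciprocal.

#' Describe a simulation scenario
#'
#' The defaults are the package's benchmark conditions: 200 genes with 10
#' probes each (1 informative + 9 noise), 25 samples, class-conditional
#' informative-probe means 0.2/0.8 with sd 0.05, balanced classes, no
#' label noise. Real 450K arrays average about 18 probes per gene; pass
#' `probes_per_gene = c(5, 30)` for a uniform draw emulating that spread.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Single integer (fixed count) or length-2 integer
#'   range for a per-gene uniform draw.
#' @param n_samples Number of samples.
#' @param n_informative Informative probes per gene (0, 1 or 2).
#' @param mu_down,mu_up Class-conditional beta means of informative probes
#'   (down- and up-labeled samples respectively), in (0, 1).
#' @param effect_sd Within-class sd of informative probes.
#' @param noise_shape Length-2 Beta shape parameters for noise probes.
#' @param class_balance Probability a sample is labeled down.
#' @param label_noise Probability of flipping a sample's expression label
#'   relative to its methylation class (injects disagreement and mid-range
#'   MCC genes).
#' @param fold_threshold Discretization threshold the expression is built
#'   around.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   scenario including this seed.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_genes = 200, probes_per_gene = 10,
                                n_samples = 25, n_informative = 1,
                                mu_down = 0.2, mu_up = 0.8,
                                effect_sd = 0.05, noise_shape = c(2, 2),
                                class_balance = 0.5, label_noise = 0,
                                fold_threshold = 1.1, seed = 450) {
  stopifnot(mu_down > 0, mu_down < 1, mu_up > 0, mu_up < 1,
            effect_sd > 0, class_balance > 0, class_balance < 1,
            label_noise >= 0, label_noise <= 1,
            n_informative >= 0,
            length(probes_per_gene) %in% c(1L, 2L))
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 mu_down = mu_down, mu_up = mu_up, effect_sd = effect_sd,
                 noise_shape = noise_shape,
                 class_balance = class_balance, label_noise = label_noise,
                 fold_threshold = fold_threshold,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

rtruncnorm01 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0 | out > 1
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0 | out > 1
  }
  out
}

#' Simulate a planted-probe methylation/expression dataset
#'
#' @param scenario A [simulation_scenario()].
#' @return List with:
#'   * `methylation`: [methyl_matrix()] (probes x samples);
#'   * `expression`: [expr_matrix()] of linear paired ratios
#'     (genes x samples);
#'   * `annotation`: manifest-style tibble (one row per probe-gene pair);
#'   * `truth`: tibble `gene_id`, `probe_id` of planted informative probes;
#'   * `labels`: named list of planted per-gene [label_vector()]s (the
#'     methylation classes, before any label noise);
#'   * `scenario`: the input scenario.
#' @export
simulate_dataset <- function(scenario = simulation_scenario()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    sample_ids <- sprintf("S%03d", seq_len(sc$n_samples))
    gene_ids <- sprintf("GENE%04d", seq_len(sc$n_genes))
    n_probes_per_gene <- if (length(sc$probes_per_gene) == 1L) {
      rep(sc$probes_per_gene, sc$n_genes)
    } else {
      sample(sc$probes_per_gene[1]:sc$probes_per_gene[2], sc$n_genes,
             replace = TRUE)
    }
    total_probes <- sum(n_probes_per_gene)
    probe_ids <- sprintf("cg%06d", seq_len(total_probes))

    meth <- matrix(NA_real_, total_probes, sc$n_samples,
                   dimnames = list(probe_ids, sample_ids))
    expr <- matrix(NA_real_, sc$n_genes, sc$n_samples,
                   dimnames = list(gene_ids, sample_ids))
    truth <- vector("list", sc$n_genes)
    labels <- vector("list", sc$n_genes)
    ann <- vector("list", sc$n_genes)

    t_up <- sc$fold_threshold * 1.5
    t_down <- (1 / sc$fold_threshold) / 1.5
    offset <- 0L
    for (g in seq_len(sc$n_genes)) {
      np <- n_probes_per_gene[g]
      rows <- offset + seq_len(np)
      offset <- offset + np

      meth_class <- ifelse(stats::rbinom(sc$n_samples, 1,
                                         sc$class_balance) == 1,
                           "down", "up")
      flip <- stats::rbinom(sc$n_samples, 1, sc$label_noise) == 1
      expr_class <- ifelse(flip,
                           ifelse(meth_class == "down", "up", "down"),
                           meth_class)
      expr[g, ] <- ifelse(expr_class == "up", t_up, t_down)
      labels[[g]] <- label_vector(gene_ids[g], sample_ids, expr_class)

      n_inf <- min(sc$n_informative, np)
      inf_slots <- if (n_inf > 0) sample(np, n_inf) else integer(0)
      for (p in seq_len(np)) {
        if (p %in% inf_slots) {
          mu <- ifelse(meth_class == "down", sc$mu_down, sc$mu_up)
          meth[rows[p], ] <- rtruncnorm01(sc$n_samples, mu, sc$effect_sd)
        } else {
          meth[rows[p], ] <- stats::rbeta(sc$n_samples, sc$noise_shape[1],
                                          sc$noise_shape[2])
        }
      }
      truth[[g]] <- tibble(gene_id = gene_ids[g],
                           probe_id = probe_ids[rows[inf_slots]])

      region <- sample(c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                         "3'UTR"), np, replace = TRUE,
                       prob = c(0.10, 0.15, 0.10, 0.05, 0.45, 0.15))
      island <- sample(c("Island", "Shore", "Shelf", "OpenSea"), np,
                       replace = TRUE, prob = c(0.30, 0.25, 0.10, 0.35))
      upstream <- region %in% UPSTREAM_GROUPS
      tss <- integer(np)
      tss[upstream] <- -sample.int(1500, sum(upstream), replace = TRUE)
      tss[!upstream] <- sample.int(50000, sum(!upstream), replace = TRUE)
      ann[[g]] <- tibble(
        probe_id = probe_ids[rows],
        gene = gene_ids[g],
        region_group = region,
        island_relation = island,
        chromosome = paste0("chr", 1 + (g - 1) %% 22),
        position = as.integer(g * 1e6 + seq_len(np) * 100),
        tss_distance = as.integer(tss))
    }

    list(methylation = methyl_matrix(meth),
         expression = expr_matrix(expr, mode = "paired_ratio"),
         annotation = dplyr::bind_rows(ann),
         truth = dplyr::bind_rows(truth),
         labels = setNames(labels, gene_ids),
         scenario = sc)
  })
}

#' Fraction of genes whose selection recovers a planted probe
#'
#' @param truth Truth tibble from [simulate_dataset()] (`gene_id`,
#'   `probe_id`).
#' @param selection Selection tibble (columns `gene_id` and list-column
#'   `probes`).
#' @return Fraction of evaluated genes whose selected set intersects the
#'   planted informative set.
#' @export
recovery_rate <- function(truth, selection) {
  if (nrow(selection) == 0) {
    return(NA_real_)
  }
  hits <- vapply(seq_len(nrow(selection)), function(i) {
    planted <- truth$probe_id[truth$gene_id == selection$gene_id[i]]
    length(intersect(selection$probes[[i]], planted)) > 0
  }, logical(1))
  mean(hits)
}
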