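# Fixtures built in code, plus independent brute-force oracles used to
# cross-check the greedy wrapper, KNN and the CV error score.

toy_methyl <- function(values, n_probes, n_samples,
                       probe_ids = sprintf("cg%03d", seq_len(n_probes)),
                       sample_ids = sprintf("S%02d", seq_len(n_samples)),
                       permissive = FALSE) {
  m <- matrix(values, n_probes, n_samples,
              dimnames = list(probe_ids, sample_ids))
  methyl_matrix(m, permissive = permissive)
}

# A gene with one perfectly separating probe (class-disjoint beta ranges)
# among `n_noise` noise probes.
planted_fixture <- function(n_samples = 20, n_noise = 5, seed = 7) {
  set.seed(seed)
  labels <- rep(c("down", "up"), length.out = n_samples)
  betas <- ifelse(labels == "down",
                  runif(n_samples, 0.05, 0.25),
                  runif(n_samples, 0.75, 0.95))
  noise <- matrix(runif(n_noise * n_samples, 0.3, 0.7), n_noise, n_samples)
  m <- rbind(betas, noise)
  probe_ids <- c("cg_planted", sprintf("cg_noise%02d", seq_len(n_noise)))
  dimnames(m) <- list(probe_ids, sprintf("S%02d", seq_len(n_samples)))
  list(M = methyl_matrix(m),
       labels = label_vector("GENE1", colnames(m), labels),
       planted = "cg_planted",
       candidates = probe_ids)
}

# A random instance for oracle-equivalence checks: up to `n_probes`
# candidates, `n_samples` samples, labels guaranteed to contain both
# classes.
random_instance <- function(seed, n_probes = 5, n_samples = 20) {
  set.seed(seed)
  np <- sample(2:n_probes, 1)
  m <- matrix(runif(np * n_samples), np, n_samples,
              dimnames = list(sprintf("cg%03d", seq_len(np)),
                              sprintf("S%02d", seq_len(n_samples))))
  repeat {
    labels <- sample(c("down", "up"), n_samples, replace = TRUE)
    if (length(unique(labels)) == 2) break
  }
  list(M = methyl_matrix(m),
       labels = label_vector("G", colnames(m), labels),
       candidates = rownames(m))
}

# ---- independent oracles (plain loops, no package internals) ----------

# 1NN with the documented tie rules: stable order on (distance, sample
# id); the vote of the single nearest neighbour decides.
oracle_1nn <- function(train_x, train_y, train_ids, test_x) {
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sqrt(sum((test_x[i, ] - train_x[j, ])^2))
    }
    ord <- order(d, train_ids)
    out[i] <- as.character(train_y[ord[1]])
  }
  out
}

# Mean per-fold misclassification count of 1NN under a given fold
# assignment (named integer vector).
oracle_cv_error_1nn <- function(probes, M, labels, fold) {
  x <- t(unclass(M)[probes, labels$sample_ids, drop = FALSE])
  y <- as.character(labels$labels)
  ids <- labels$sample_ids
  o <- numeric(max(fold))
  for (f in seq_len(max(fold))) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(test) == 0) next
    pred <- oracle_1nn(x[train, , drop = FALSE], y[train], ids[train],
                       x[test, , drop = FALSE])
    o[f] <- sum(pred != y[test])
  }
  mean(o)
}

# Naive nested-loop greedy forward selection minimizing the 1NN CV error,
# ties to the lowest candidate index; first pick unconditional, growth
# only on strict improvement. Returns the selected set (in order) and the
# full evaluation trace.
oracle_greedy_1nn <- function(candidates, M, labels, fold) {
  remaining <- candidates
  selected <- character(0)
  trace <- list()
  oce <- NULL
  round <- 0
  repeat {
    round <- round + 1
    cce <- numeric(length(remaining))
    for (i in seq_along(remaining)) {
      cce[i] <- oracle_cv_error_1nn(c(selected, remaining[i]), M, labels,
                                    fold)
    }
    best <- which(cce == min(cce))[1]
    accept <- if (round == 1) TRUE else cce[best] < oce
    trace[[round]] <- data.frame(round = round, candidate = remaining,
                                 cce = cce,
                                 accepted = accept &
                                   seq_along(remaining) == best)
    if (!accept) break
    selected <- c(selected, remaining[best])
    oce <- cce[best]
    remaining <- remaining[-best]
    if (length(remaining) == 0) break
  }
  list(selected = selected, final = oce,
       trace = do.call(rbind, trace))
}
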