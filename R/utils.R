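# Internal helpers shared across modules.

# Region vocabulary used by the 450K manifest (gene region groups) and the
# CpG-island relation column. Values outside these sets are coerced to
# "Unknown" at load time.
REGION_GROUPS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
                   "Unknown")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea", "Unknown")
UPSTREAM_GROUPS <- c("TSS200", "TSS1500", "5'UTR", "1stExon")

LABEL_LEVELS <- c("down", "up")

#' Derive a reproducible per-gene seed
#'
#' Combines a global seed with a stable string hash of the gene identifier,
#' so per-gene randomness (fold assignment, random control draws) does not
#' depend on the order genes are processed in.
#'
#' @param seed Integer global seed.
#' @param gene_id Gene identifier string.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
gene_seed <- function(seed, gene_id) {
  stopifnot(length(seed) == 1L, length(gene_id) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double-integer range
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(gene_id))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. When seed is NULL, run as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Factor coercion for up/down labels with the fixed level order
# c("down", "up"); "down" is the positive class throughout.
as_label_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), LABEL_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("labels must be 'up' or 'down'; found: ",
                 paste(bad, collapse = ", ")))
  }
  factor(x, levels = LABEL_LEVELS)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}
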