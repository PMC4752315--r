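# Readers and writers for the TSV formats the toolkit consumes and emits:
# a manifest-style probe annotation table, beta/expression matrices and
# selection-result tables. All files are tab-delimited UTF-8 with a header.

MANIFEST_REQUIRED <- c("probe_id", "gene", "region_group", "island_relation",
                       "chromosome", "position")

#' Column map for a raw Illumina 450K manifest
#'
#' Maps the package's canonical manifest column names to the header names
#' used by Illumina's HumanMethylation450 manifest CSV/TSV export.
#'
#' @return Named character vector usable as `column_map` in
#'   [read_manifest()].
#' @export
illumina_column_map <- function() {
  c(probe_id = "IlmnID",
    gene = "UCSC_RefGene_Name",
    region_group = "UCSC_RefGene_Group",
    island_relation = "Relation_to_UCSC_CpG_Island",
    chromosome = "CHR",
    position = "MAPINFO")
}

#' Read a probe annotation table (450K manifest style)
#'
#' Parses a TSV mapping each probe to its gene(s), gene region group(s),
#' CpG-island relation, chromosome and 1-based position. Multi-gene cells
#' use the Illumina dialect: gene and region fields are `;`-separated and
#' paired positionally (gene *i* with region *i*). When the same gene is
#' listed more than once for a probe with conflicting regions, the
#' first-listed region is kept and a warning emitted.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`probe_id`, `gene`, `region_group`, `island_relation`, `chromosome`,
#'   `position`, optionally `tss_distance`) to the file's header names.
#'   See [illumina_column_map()].
#' @return A tibble with one row per (probe, gene) pair — probes with an
#'   empty gene field get a single row with `gene = NA` — and columns
#'   `probe_id`, `gene`, `region_group`, `island_relation`, `chromosome`,
#'   `position`, `tss_distance` (NA when absent from the file).
#' @export
read_manifest <- function(path, column_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cmap <- c(probe_id = "probe_id", gene = "gene",
            region_group = "region_group",
            island_relation = "island_relation",
            chromosome = "chromosome", position = "position",
            tss_distance = "tss_distance")
  if (!is.null(column_map)) {
    cmap[names(column_map)] <- column_map
  }
  for (col in MANIFEST_REQUIRED) {
    if (!cmap[[col]] %in% names(raw)) {
      abort(sprintf("manifest is missing required column '%s' (mapped from '%s')",
                    cmap[[col]], col))
    }
  }
  probe_id <- raw[[cmap[["probe_id"]]]]
  if (anyDuplicated(probe_id)) {
    abort(paste0("duplicate probe_id in manifest: ",
                 paste(unique(probe_id[duplicated(probe_id)]), collapse = ", ")))
  }
  position <- suppressWarnings(as.integer(raw[[cmap[["position"]]]]))
  if (anyNA(position) || any(position < 1L)) {
    abort("manifest positions must be integers >= 1 (1-based coordinates)")
  }
  tss <- if (cmap[["tss_distance"]] %in% names(raw)) {
    suppressWarnings(as.integer(raw[[cmap[["tss_distance"]]]]))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  island <- coerce_vocab(raw[[cmap[["island_relation"]]]], ISLAND_RELATIONS,
                         "island relation")
  genes_raw <- raw[[cmap[["gene"]]]]
  regions_raw <- raw[[cmap[["region_group"]]]]

  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    gene_cell <- genes_raw[[i]]
    genes <- if (is.na(gene_cell) || !nzchar(gene_cell)) character(0) else
      strsplit(gene_cell, ";", fixed = TRUE)[[1]]
    if (length(genes) == 0) {
      rows[[i]] <- tibble(probe_id = probe_id[[i]], gene = NA_character_,
                          region_group = NA_character_)
      next
    }
    region_cell <- regions_raw[[i]]
    regions <- if (is.na(region_cell) || !nzchar(region_cell)) character(0) else
      strsplit(region_cell, ";", fixed = TRUE)[[1]]
    if (length(regions) < length(genes)) {
      regions <- c(regions, rep("Unknown", length(genes) - length(regions)))
    }
    regions <- regions[seq_along(genes)]
    dup <- duplicated(genes)
    if (any(dup)) {
      conflicting <- vapply(unique(genes[dup]), function(g) {
        length(unique(regions[genes == g])) > 1L
      }, logical(1))
      if (any(conflicting)) {
        warn(sprintf(
          "probe %s lists gene(s) %s with conflicting regions; keeping first",
          probe_id[[i]],
          paste(unique(genes[dup])[conflicting], collapse = ", ")))
      }
      regions <- regions[!dup]
      genes <- genes[!dup]
    }
    rows[[i]] <- tibble(probe_id = probe_id[[i]], gene = genes,
                        region_group = coerce_vocab(regions, REGION_GROUPS,
                                                    "region group"))
  }
  ann <- dplyr::bind_rows(rows)
  probe_level <- tibble(probe_id = probe_id,
                        island_relation = island,
                        chromosome = raw[[cmap[["chromosome"]]]],
                        position = position,
                        tss_distance = tss)
  dplyr::left_join(ann, probe_level, by = "probe_id")
}

coerce_vocab <- function(x, vocab, what) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "Unknown"
  bad <- !x %in% vocab
  if (any(bad)) {
    warn(sprintf("%d %s value(s) outside the known vocabulary set to 'Unknown'",
                 sum(bad), what))
    x[bad] <- "Unknown"
  }
  x
}

#' Build the gene-to-probes map from an annotation table
#'
#' @param annotation Tibble from [read_manifest()] (or the synthetic
#'   generator), one row per (probe, gene) pair.
#' @return Named list: gene id -> character vector of probe ids in manifest
#'   (row) order. Genes with no probes are absent; probes with no gene are
#'   excluded.
#' @export
build_gene_probe_map <- function(annotation) {
  ann <- annotation[!is.na(annotation$gene), , drop = FALSE]
  if (nrow(ann) == 0) {
    return(setNames(list(), character(0)))
  }
  split(ann$probe_id, factor(ann$gene, levels = unique(ann$gene)))
}

#' Read a beta-value or expression matrix from TSV
#'
#' First column holds the row ids (probe or gene ids), the header row the
#' sample ids. Every data cell must parse as a number; a non-numeric cell is
#' reported with its row/column coordinates.
#'
#' @param path Path to a TSV file.
#' @param permissive Beta matrices only: accept values outside `[0, 1]`.
#' @param missing How to treat missing cells: `"error"` (default) or
#'   `"drop_row"` to discard rows containing any NA.
#' @return A [methyl_matrix()] or [expr_matrix()].
#' @name read_matrix
NULL

#' @rdname read_matrix
#' @export
read_beta_matrix <- function(path, permissive = FALSE,
                             missing = c("error", "drop_row")) {
  m <- read_numeric_tsv(path, match.arg(missing))
  methyl_matrix(m, permissive = permissive)
}

#' @rdname read_matrix
#' @param mode Expression mode, see [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   mode = c("paired_ratio",
                                            "median_reference"),
                                   missing = c("error", "drop_row")) {
  m <- read_numeric_tsv(path, match.arg(missing))
  expr_matrix(m, mode = match.arg(mode))
}

read_numeric_tsv <- function(path, missing) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("matrix TSV needs a row-id column plus at least one sample column")
  }
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- is.na(num) & !is.na(vals) & nzchar(trimws(vals)) &
    toupper(trimws(vals)) != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell '%s' at row %d ('%s'), column '%s'",
                  vals[idx[1], idx[2]], idx[1], ids[idx[1]],
                  colnames(vals)[idx[2]]))
  }
  rownames(num) <- ids
  if (anyNA(num)) {
    if (missing == "drop_row") {
      keep <- !apply(is.na(num), 1, any)
      inform(sprintf("dropping %d row(s) with missing values", sum(!keep)))
      num <- num[keep, , drop = FALSE]
    } else {
      abort("matrix contains missing values; use missing = 'drop_row' to discard those rows")
    }
  }
  num
}

#' Write a numeric matrix as TSV
#'
#' Values are written with 10 significant digits, which round-trips through
#' [read_beta_matrix()]/[read_expression_matrix()] bit-exactly for values
#' carrying at most that precision.
#'
#' @param x Matrix with dimnames (e.g. a [methyl_matrix()]).
#' @param path Output path.
#' @param id_column Name for the first (row id) column.
#' @export
write_matrix_tsv <- function(x, path, id_column = "id") {
  df <- as.data.frame(apply(unclass(x), 2, function(col) {
    sprintf("%.10g", col)
  }, simplify = FALSE), check.names = FALSE, optional = TRUE)
  df <- cbind(setNames(data.frame(rownames(x)), id_column), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write and read selection-result tables
#'
#' One row per gene: `gene_id`, `method`, `n_selected`, the selected probe
#' ids comma-joined in selection order, and the final cross-validation
#' error. Rows are sorted by `gene_id` for deterministic output.
#'
#' @param results Tibble with columns `gene_id`, `method`, `probes`
#'   (list-column of character vectors) and `final_cv_error`, as produced by
#'   [run_genome()].
#' @param path Output path.
#' @export
write_selection_results <- function(results, path) {
  out <- tibble(
    gene_id = results$gene_id,
    method = results$method,
    n_selected = vapply(results$probes, length, integer(1)),
    probes = vapply(results$probes, paste, character(1), collapse = ","),
    final_cv_error = sprintf("%.10g", results$final_cv_error)
  )
  out <- dplyr::arrange(out, .data$gene_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_selection_results
#' @return `read_selection_results()` returns the tibble with `probes`
#'   restored as a list-column of ordered probe ids.
#' @export
read_selection_results <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", method = "c", n_selected = "i", probes = "c",
    final_cv_error = "d"), progress = FALSE)
  raw$probes <- lapply(raw$probes, function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else
      strsplit(p, ",", fixed = TRUE)[[1]]
  })
  raw
}

#' Write a gene list as plain text
#'
#' One gene symbol per line, suitable for GO-enrichment web tools.
#'
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
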