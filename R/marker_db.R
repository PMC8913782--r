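#' Construct a marker database
#'
#' A marker database is a tibble with one row per (tissue, cell type) and
#' list-columns of positive and negative marker gene symbols. Positive markers
#' are genes expected to be expressed in the cell type; negative markers are
#' genes expected to be absent. The same gene may be a positive marker for one
#' cell type and a negative marker for another.
#'
#' @param tissue Character vector of tissue names.
#' @param cell_type Character vector of cell-type names (same length).
#' @param positive List of character vectors of positive marker symbols.
#' @param negative Optional list of character vectors of negative markers;
#'   `NULL` means no negative markers anywhere.
#' @return A `marker_db` tibble with columns `tissue`, `cell_type`,
#'   `positive` (list), `negative` (list).
#' @examples
#' db <- marker_db(
#'   tissue = c("Immune system", "Immune system"),
#'   cell_type = c("B cell", "Plasma cell"),
#'   positive = list(c("CD19", "MS4A1"), "SDC1"),
#'   negative = list(character(), c("CD19", "MS4A1"))
#' )
#' @export
marker_db <- function(tissue, cell_type, positive, negative = NULL) {
  if (is.null(negative)) {
    negative <- rep(list(character()), length(tissue))
  }
  stopifnot(
    length(tissue) == length(cell_type),
    length(positive) == length(tissue),
    length(negative) == length(tissue)
  )
  clean <- function(x) {
    x <- trimws(as.character(x))
    x <- x[nzchar(x)]
    x[!duplicated(x)]
  }
  positive <- purrr::map(positive, clean)
  negative <- purrr::map(negative, clean)
  db <- tibble::tibble(
    tissue = as.character(tissue),
    cell_type = as.character(cell_type),
    positive = positive,
    negative = negative
  )
  validate_marker_db(db)
}

#' @keywords internal
validate_marker_db <- function(db) {
  npos <- lengths(db$positive)
  if (any(npos == 0)) {
    bad <- db[npos == 0, ]
    stop(
      "empty positive marker list for ",
      paste(sprintf("%s / %s", bad$tissue, bad$cell_type), collapse = "; "),
      call. = FALSE
    )
  }
  overlap <- purrr::map2(db$positive, db$negative, intersect)
  if (any(lengths(overlap) > 0)) {
    i <- which(lengths(overlap) > 0)[1]
    stop(
      sprintf(
        "genes %s are both positive and negative markers of %s / %s",
        paste(overlap[[i]], collapse = ", "), db$tissue[i], db$cell_type[i]
      ),
      call. = FALSE
    )
  }
  if (anyDuplicated(paste(db$tissue, db$cell_type, sep = "\r"))) {
    stop("duplicate (tissue, cell type) rows in marker database", call. = FALSE)
  }
  class(db) <- c("marker_db", class(tibble::tibble()))
  db
}

#' Read a marker database from a TSV file
#'
#' The file dialect mirrors the ScType database schema: UTF-8, tab-separated,
#' header columns `tissueType`, `cellName`, `geneSymbolmore1` (positive
#' markers) and `geneSymbolmore2` (negative markers). Gene lists are
#' comma-separated; whitespace around symbols and trailing commas are
#' tolerated, `geneSymbolmore2` may be empty. Duplicate genes within one list
#' are dropped keeping the first occurrence.
#'
#' @param path Path to the TSV file.
#' @param tissue Optional tissue name; keep only matching rows. An unknown
#'   tissue is an error listing the available tissues.
#' @param case_insensitive If `TRUE`, gene symbols are upper-cased so that
#'   matching against expression data ignores case (human vs mouse casing).
#'   Default `FALSE`: matching is exact and case-sensitive.
#' @return A [marker_db()] tibble.
#' @export
read_marker_db <- function(path, tissue = NULL, case_insensitive = FALSE) {
  if (!file.exists(path)) stop("marker database file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("tissueType", "cellName", "geneSymbolmore1", "geneSymbolmore2")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(
      "marker database is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  split_genes <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character())
    g <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    g <- g[nzchar(g)]
    if (case_insensitive) g <- toupper(g)
    g[!duplicated(g)]
  }
  db <- marker_db(
    tissue = trimws(raw$tissueType),
    cell_type = trimws(raw$cellName),
    positive = purrr::map(raw$geneSymbolmore1, split_genes),
    negative = purrr::map(raw$geneSymbolmore2, split_genes)
  )
  if (!is.null(tissue)) {
    if (!tissue %in% db$tissue) {
      stop(
        sprintf(
          "tissue '%s' not in database; available tissues: %s",
          tissue, paste(unique(db$tissue), collapse = ", ")
        ),
        call. = FALSE
      )
    }
    db <- db[db$tissue == tissue, ]
    class(db) <- c("marker_db", class(tibble::tibble()))
  }
  db
}

#' Cell-type specificity scores of a tissue's markers
#'
#' Pools all positive and negative markers of all cell types within a tissue
#' and scores each pooled gene by how selectively it is used: with
#' \eqn{|M_i|_t} the number of cell types of tissue \eqn{t} enlisting gene
#' \eqn{i} (as positive or negative marker; at most once per cell type),
#' \deqn{S_i^t = 1 - \frac{|M_i|_t - \min(|M|_t)}{\max(|M|_t) - \min(|M|_t)}.}
#' A gene enlisted by the fewest cell types scores 1 (maximally specific), one
#' enlisted by the most scores 0. If every pooled gene is enlisted by the same
#' number of cell types the normalisation is degenerate and all scores are 1
#' (no gene is less specific than any other).
#'
#' @param db A [marker_db()].
#' @param tissue Tissue name present in `db`.
#' @return A tibble with columns `gene`, `n_types` (\eqn{|M_i|_t}) and
#'   `specificity` in \[0, 1\].
#' @export
specificity_scores <- function(db, tissue) {
  sets <- db[db$tissue == tissue, ]
  if (nrow(sets) == 0) {
    stop(
      sprintf(
        "tissue '%s' not in database; available tissues: %s",
        tissue, paste(unique(db$tissue), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  # one enlistment per cell type even when a gene is in both lists
  per_type <- purrr::map2(sets$positive, sets$negative, ~ unique(c(.x, .y)))
  counts <- table(unlist(per_type))
  n_types <- as.integer(counts)
  gene <- names(counts)
  rng <- range(n_types)
  if (rng[1] == rng[2]) {
    s <- rep(1, length(gene))
  } else {
    s <- 1 - (n_types - rng[1]) / (rng[2] - rng[1])
  }
  tibble::tibble(gene = gene, n_types = n_types, specificity = s)
}

#' Build an in-memory marker database from extracted marker lists
#'
#' Convenience for benchmarking: turns a per-cell-type marker table (as
#' returned by [extract_markers()]) into a positive-only [marker_db()].
#'
#' @param markers Tibble with columns `cell_type` and `gene`, or a named list
#'   of character vectors.
#' @param tissue Tissue name to assign, default `"simulated"`.
#' @return A [marker_db()].
#' @export
markers_to_db <- function(markers, tissue = "simulated") {
  if (is.data.frame(markers)) {
    markers <- split(markers$gene, markers$cell_type)
  }
  marker_db(
    tissue = rep(tissue, length(markers)),
    cell_type = names(markers),
    positive = unname(markers)
  )
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf(
    "<marker_db> %d cell types, %d tissue(s), %d pooled genes\n",
    nrow(x), length(unique(x$tissue)),
    length(unique(unlist(c(x$positive, x$negative))))
  ))
  NextMethod()
}
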