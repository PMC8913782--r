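#' Read an expression matrix
#'
#' Accepts either a 10x-style MatrixMarket triplet directory
#' (`matrix.mtx[.gz]` plus `features.tsv`/`genes.tsv[.gz]` and
#' `barcodes.tsv[.gz]`; genes as rows) or a dense TSV/CSV with gene symbols
#' in the first column and one column per cell. Gene symbols duplicated after
#' load keep the highest-total row (see [expr_matrix()]).
#'
#' @param path Directory (MTX triplet) or file (dense table).
#' @param layer Layer tag for the loaded values (default `"raw"`).
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, layer = "raw") {
  if (dir.exists(path)) {
    find_one <- function(names) {
      for (n in names) {
        for (f in file.path(path, c(n, paste0(n, ".gz")))) {
          if (file.exists(f)) return(f)
        }
      }
      stop("missing ", names[1], " in ", path, call. = FALSE)
    }
    mtx <- find_one("matrix.mtx")
    feat <- find_one(c("features.tsv", "genes.tsv"))
    bc <- find_one("barcodes.tsv")
    m <- Matrix::readMM(mtx)
    features <- readr::read_tsv(
      feat,
      col_names = FALSE, col_types = readr::cols(.default = "c"), progress = FALSE
    )
    barcodes <- readr::read_tsv(
      bc,
      col_names = FALSE, col_types = readr::cols(.default = "c"), progress = FALSE
    )
    # 10x features.tsv: id, symbol, [type] — use the symbol column when present
    genes <- if (ncol(features) >= 2) features[[2]] else features[[1]]
    if (nrow(m) != length(genes) || ncol(m) != nrow(barcodes)) {
      stop(sprintf(
        "dimension mismatch: matrix %d x %d vs %d features, %d barcodes",
        nrow(m), ncol(m), length(genes), nrow(barcodes)
      ), call. = FALSE)
    }
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes[[1]])
    message(sprintf("loaded %d genes x %d cells (sparse)", nrow(m), ncol(m)))
    return(expr_matrix(m, layer = layer))
  }
  if (!file.exists(path)) stop("expression input not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
  genes <- as.character(tab[[1]])
  v <- as.matrix(tab[, -1, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- genes
  message(sprintf("loaded %d genes x %d cells (dense)", nrow(v), ncol(v)))
  expr_matrix(v, layer = layer)
}

#' Read per-cell cluster labels
#'
#' Two-column TSV `cell_id`, `cluster` (header required).
#'
#' @param path TSV path.
#' @return Tibble `cell_id`, `cluster` (character).
#' @export
read_cluster_labels <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(tab))) {
    stop("cluster file needs header columns 'cell_id' and 'cluster'", call. = FALSE)
  }
  tibble::tibble(cell_id = tab$cell_id, cluster = tab$cluster)
}

#' Write an annotation result to TSV
#'
#' One row per cluster, deterministic column order (`cluster`, `n_cells`,
#' `assigned_type`, `sctype_score`, `second_best`, `second_score`); scores
#' serialised with 6 decimals. Round-trips through [read_annotation()].
#'
#' @param result An `sctype_annotation`.
#' @param path Output path.
#' @param scores_path Optional path for the long per-cluster score table.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(result, path, scores_path = NULL) {
  a <- result$assignments |>
    dplyr::arrange(.data$cluster) |>
    dplyr::mutate(
      sctype_score = sprintf("%.6f", .data$sctype_score),
      second_score = ifelse(is.na(.data$second_score), "", sprintf("%.6f", .data$second_score))
    )
  readr::write_tsv(a, path)
  if (!is.null(scores_path)) {
    s <- result$scores |>
      dplyr::arrange(.data$cluster, .data$rank) |>
      dplyr::mutate(score = sprintf("%.6f", .data$score))
    readr::write_tsv(s, scores_path)
  }
  invisible(path)
}

#' Read an annotation table written by [write_annotation()]
#'
#' @param path TSV path.
#' @return Tibble matching `result$assignments`.
#' @export
read_annotation <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      cluster = "c", n_cells = "i", assigned_type = "c",
      sctype_score = "d", second_best = "c", second_score = "d"
    ),
    progress = FALSE
  )
}

#' Run the annotation pipeline end to end
#'
#' Reads the expression matrix, cluster labels and marker database, annotates,
#' and writes the per-cluster annotation table (plus optional score table and
#' JSON summary). Stage progress and marker-coverage diagnostics go to
#' `message()` (stderr); results go to files only. Errors are rethrown with
#' the failing stage named.
#'
#' @param config Named list: `matrix`, `clusters`, `db`, `tissue`, `out`
#'   (required); optional `scores_out`, `summary_out`, `min_score_frac`
#'   (default 0.25), `zscore` (default TRUE), `case_insensitive` (default
#'   FALSE), `scale_total` (default 1e4).
#' @return The `sctype_annotation`, invisibly.
#' @export
run_pipeline <- function(config) {
  required <- c("matrix", "clusters", "db", "tissue", "out")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("missing config field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  opt <- function(name, default) if (is.null(config[[name]])) default else config[[name]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  x <- stage("read_matrix", read_expression(config$matrix))
  clusters <- stage("read_clusters", read_cluster_labels(config$clusters))
  db <- stage("read_db", read_marker_db(
    config$db,
    tissue = config$tissue,
    case_insensitive = opt("case_insensitive", FALSE)
  ))
  pooled <- unique(unlist(c(db$positive, db$negative)))
  covered <- sum(pooled %in% rownames(x$values))
  message(sprintf("marker coverage: %d / %d tissue markers present in data", covered, length(pooled)))
  ann <- stage("annotate", annotate(
    x, clusters, db, config$tissue,
    scale_total = opt("scale_total", 1e4),
    zscore = opt("zscore", TRUE),
    min_score_frac = opt("min_score_frac", 0.25),
    case_insensitive = opt("case_insensitive", FALSE)
  ))
  stage("write", write_annotation(ann, config$out, scores_path = config$scores_out))
  if (!is.null(config$summary_out)) {
    jsonlite::write_json(
      list(
        n_clusters = nrow(ann$assignments),
        n_cells = sum(ann$assignments$n_cells),
        n_unknown = sum(ann$assignments$assigned_type == "Unknown"),
        tissue = config$tissue,
        assignments = ann$assignments
      ),
      config$summary_out,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(ann)
}
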