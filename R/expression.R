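#' Expression matrix container
#'
#' A light wrapper around a genes-by-cells numeric matrix (dense or
#' `Matrix` sparse) that records which processing layer the values are on:
#' `"raw"` counts, `"normalized"` (library-size scaled, log1p) or `"zscored"`
#' (per-gene z-scores). Duplicate gene symbols are resolved at construction by
#' keeping the row with the highest total signal (a common 10x artifact); the
#' collision is reported via `message()`.
#'
#' @param values Numeric genes-by-cells matrix with rownames (gene symbols)
#'   and colnames (cell barcodes).
#' @param layer One of `"raw"`, `"normalized"`, `"zscored"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, layer = c("raw", "normalized", "zscored")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("Gene%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("Cell%05d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    tot <- if (methods::is(values, "sparseMatrix")) {
      Matrix::rowSums(values)
    } else {
      rowSums(values)
    }
    ord <- order(-tot)  # keep highest-total row of each duplicated symbol
    keep <- ord[!duplicated(rownames(values)[ord])]
    n_drop <- nrow(values) - length(keep)
    message(sprintf("dropped %d duplicated gene symbol row(s), keeping highest total", n_drop))
    values <- values[sort(keep), , drop = FALSE]
  }
  vals_finite <- if (methods::is(values, "sparseMatrix")) values@x else values
  if (length(vals_finite) && any(!is.finite(vals_finite))) {
    stop("expression values must be finite", call. = FALSE)
  }
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) as.matrix(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d cells, layer = %s\n",
    nrow(x$values), ncol(x$values), x$layer
  ))
  invisible(x)
}

as_expr_matrix <- function(x, layer = "raw") {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(x, layer = layer)
}

#' Library-size normalisation of raw counts
#'
#' Scales every cell to `scale_total` total counts, then applies `log1p`.
#' All-zero cells cannot be scaled and are left all-zero with a warning.
#'
#' @param x An [expr_matrix()] on the `"raw"` layer (or a bare count matrix).
#' @param scale_total Target total count per cell (default 10,000).
#' @return An [expr_matrix()] on the `"normalized"` layer.
#' @export
normalize_counts <- function(x, scale_total = 1e4) {
  x <- as_expr_matrix(x, layer = "raw")
  if (x$layer != "raw") stop("normalize_counts() expects the raw layer", call. = FALSE)
  v <- x$values
  neg <- if (methods::is(v, "sparseMatrix")) any(v@x < 0) else any(v < 0)
  if (neg) stop("raw counts must be non-negative", call. = FALSE)
  totals <- if (methods::is(v, "sparseMatrix")) Matrix::colSums(v) else colSums(v)
  if (any(totals == 0)) {
    warning(sprintf("%d cell(s) with zero total counts left all-zero", sum(totals == 0)))
  }
  fac <- ifelse(totals > 0, scale_total / totals, 0)
  if (methods::is(v, "sparseMatrix")) {
    v <- v %*% Matrix::Diagonal(x = fac)
    dimnames(v) <- dimnames(x$values)
    v@x <- log1p(v@x)
  } else {
    v <- sweep(v, 2, fac, "*")
    v <- log1p(v)
  }
  expr_matrix(v, layer = "normalized")
}

#' Per-gene z-score transform
#'
#' Standardises each gene's expression profile to mean 0 and unit standard
#' deviation across all cells. Zero-variance genes become all-zero rows rather
#' than being dropped, so marker counts downstream stay stable while the gene
#' contributes nothing.
#'
#' @param x An [expr_matrix()] (normally on the `"normalized"` layer; raw
#'   input is allowed and z-scored as-is).
#' @param sd_type `"sample"` (denominator n-1, the default, matching the R
#'   single-cell ecosystem's `scale()` convention) or `"population"`
#'   (denominator n).
#' @return A dense [expr_matrix()] on the `"zscored"` layer.
#' @export
zscore_genes <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as_expr_matrix(x, layer = "normalized")
  v <- as.matrix(x$values)
  n <- ncol(v)
  mu <- rowMeans(v)
  centred <- v - mu
  denom <- if (sd_type == "sample") max(n - 1L, 1L) else n
  sdv <- sqrt(rowSums(centred^2) / denom)
  z <- centred / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  expr_matrix(z, layer = "zscored")
}
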