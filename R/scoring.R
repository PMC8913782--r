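#' Coerce cluster labels to a named character vector
#'
#' Accepts a two-column data frame (`cell_id`, `cluster`; extra columns
#' ignored) or a named vector mapping cell id to cluster id.
#'
#' @keywords internal
as_cluster_assignment <- function(clusters) {
  if (is.data.frame(clusters)) {
    if (!all(c("cell_id", "cluster") %in% names(clusters))) {
      stop("cluster table needs columns 'cell_id' and 'cluster'", call. = FALSE)
    }
    out <- stats::setNames(as.character(clusters$cluster), clusters$cell_id)
  } else {
    if (is.null(names(clusters))) {
      stop("cluster vector must be named by cell id", call. = FALSE)
    }
    out <- stats::setNames(as.character(clusters), names(clusters))
  }
  if (anyDuplicated(names(out))) {
    stop("each cell must have exactly one cluster label", call. = FALSE)
  }
  out
}

#' Restrict to tissue markers and weight by specificity
#'
#' Keeps the genes present both in the data and in the tissue's pooled marker
#' set, and multiplies each retained z-score row by the gene's cell-type
#' specificity score. Markers absent from the data are dropped (count
#' reported via `message()`).
#'
#' @param x An [expr_matrix()] on the `"zscored"` layer.
#' @param db A [marker_db()].
#' @param tissue Tissue name.
#' @return An [expr_matrix()] (layer `"zscored"`) with marker rows only.
#' @export
weight_by_specificity <- function(x, db, tissue) {
  if (x$layer != "zscored") stop("weight_by_specificity() expects z-scored input", call. = FALSE)
  spec <- specificity_scores(db, tissue)
  keep <- intersect(rownames(x$values), spec$gene)
  if (length(keep) == 0) stop("no marker genes found in data", call. = FALSE)
  n_missing <- sum(!spec$gene %in% rownames(x$values))
  if (n_missing > 0) {
    message(sprintf("%d tissue marker gene(s) absent from the data", n_missing))
  }
  w <- spec$specificity[match(keep, spec$gene)]
  v <- as.matrix(x$values)[keep, , drop = FALSE] * w
  out <- expr_matrix(v, layer = "zscored")
  attr(out, "weighted") <- TRUE
  out
}

#' Per-cell marker enrichment scores
#'
#' For every cell and cell type \eqn{c}, sums the specificity-weighted
#' z-scores of the type's positive markers present in the data, normalised by
#' \eqn{\sqrt{j}} (j = number of such markers), and subtracts the analogous
#' \eqn{\sqrt{l}}-normalised sum over its negative markers:
#' \deqn{x'_c = \sum_{i=1}^{j} x'_i/\sqrt{j} - \sum_{k=1}^{l} x'_k/\sqrt{l}.}
#' j and l count markers present in the supplied matrix, so the normaliser
#' always matches the terms actually summed. A cell type with no positive
#' marker in the data scores 0 for all cells (with a warning).
#'
#' @param xw Output of [weight_by_specificity()].
#' @param db A [marker_db()].
#' @param tissue Tissue name.
#' @return A cells-by-cell-types numeric matrix.
#' @export
cell_enrichment <- function(xw, db, tissue) {
  if (is.null(attr(xw, "weighted"))) {
    stop("cell_enrichment() expects the output of weight_by_specificity()", call. = FALSE)
  }
  sets <- db[db$tissue == tissue, ]
  if (nrow(sets) == 0) stop("tissue '", tissue, "' not in database", call. = FALSE)
  v <- as.matrix(xw$values)
  genes <- rownames(v)
  score_one <- function(pos, neg, type) {
    pos <- intersect(pos, genes)
    neg <- intersect(neg, genes)
    j <- length(pos)
    l <- length(neg)
    if (j == 0) {
      warning(sprintf("no positive markers of '%s' in data; scores set to 0", type))
      return(rep(0, ncol(v)))
    }
    s <- colSums(v[pos, , drop = FALSE]) / sqrt(j)
    if (l > 0) s <- s - colSums(v[neg, , drop = FALSE]) / sqrt(l)
    s
  }
  e <- purrr::pmap(
    list(sets$positive, sets$negative, sets$cell_type),
    score_one
  )
  e <- do.call(cbind, e)
  dimnames(e) <- list(colnames(v), sets$cell_type)
  e
}

#' Per-cluster annotation scores
#'
#' Sums the per-cell enrichment scores of every cell type over the cells of
#' each cluster.
#'
#' @param enrichment Cells-by-cell-types matrix from [cell_enrichment()].
#' @param clusters Cluster labels (data frame `cell_id`/`cluster` or named
#'   vector).
#' @return Long tibble with columns `cluster`, `cell_type`, `score`.
#' @export
cluster_scores <- function(enrichment, clusters) {
  cl <- as_cluster_assignment(clusters)
  missing <- setdiff(names(cl), rownames(enrichment))
  if (length(missing) > 0) {
    stop(
      "clustered cell(s) absent from enrichment matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  e <- enrichment[names(cl), , drop = FALSE]
  sums <- rowsum(e, group = cl)
  tibble::tibble(
    cluster = rep(rownames(sums), times = ncol(sums)),
    cell_type = rep(colnames(sums), each = nrow(sums)),
    score = as.vector(sums)
  )
}

#' Assign a cell type (or "Unknown") to every cluster
#'
#' Each cluster is labeled with the cell type of highest score. A cluster
#' whose best score is negative, or smaller than `min_score_frac` times the
#' number of cells in the cluster (default one quarter), is a low-confidence
#' annotation and is labeled `"Unknown"`. Both comparisons are strict. Exact
#' ties on the top score are broken by the lexicographically smallest
#' cell-type name, with a warning.
#'
#' @param scores Long tibble from [cluster_scores()].
#' @param clusters Cluster labels (used for cluster sizes).
#' @param min_score_frac Fraction of the cluster size below which the best
#'   score is deemed low-confidence (default 0.25).
#' @param enrichment Optional cells-by-types matrix to carry along.
#' @return An object of class `sctype_annotation`; see [tidy.sctype_annotation()].
#' @export
assign_cell_types <- function(scores, clusters, min_score_frac = 0.25, enrichment = NULL) {
  stopifnot(min_score_frac >= 0, min_score_frac <= 1)
  cl <- as_cluster_assignment(clusters)
  sizes <- table(cl)
  ranked <- scores |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$score), .data$cell_type) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  top2 <- ranked |>
    dplyr::filter(.data$rank <= 2) |>
    tidyr::pivot_wider(
      names_from = "rank",
      values_from = c("cell_type", "score")
    )
  tied <- top2$cluster[!is.na(top2$score_2) & top2$score_1 == top2$score_2]
  if (length(tied) > 0) {
    warning(
      "tied top scores in cluster(s) ", paste(tied, collapse = ", "),
      "; lexicographically smallest cell type chosen"
    )
  }
  n_cells <- as.integer(sizes[top2$cluster])
  unknown <- top2$score_1 < n_cells * min_score_frac | top2$score_1 < 0
  assignments <- tibble::tibble(
    cluster = top2$cluster,
    n_cells = n_cells,
    assigned_type = ifelse(unknown, "Unknown", top2$cell_type_1),
    sctype_score = top2$score_1,
    second_best = top2$cell_type_2,
    second_score = top2$score_2
  )
  structure(
    list(
      assignments = assignments,
      scores = ranked,
      clusters = tibble::tibble(cell_id = names(cl), cluster = unname(cl)),
      enrichment = enrichment,
      min_score_frac = min_score_frac
    ),
    class = "sctype_annotation"
  )
}

#' Annotate clustered single-cell expression data
#'
#' Runs the full scoring pipeline: library-size normalisation (skipped when
#' the input layer is already `"normalized"`), per-gene z-scoring, restriction
#' to the tissue's marker genes weighted by cell-type specificity, per-cell
#' enrichment scores, per-cluster score sums, and final label assignment with
#' the Unknown rule.
#'
#' @param x Raw counts: an [expr_matrix()] or bare genes-by-cells matrix.
#' @param clusters Cluster labels (data frame `cell_id`/`cluster` or named
#'   vector) covering the cells of `x`.
#' @param db A [marker_db()].
#' @param tissue Tissue name in `db`.
#' @param scale_total Normalisation target per cell, see [normalize_counts()].
#' @param zscore If `FALSE`, skip the z-score transform (ablation switch;
#'   normalised expression is weighted directly). Accuracy is expected to
#'   drop without it.
#' @param sd_type Standard-deviation convention for [zscore_genes()].
#' @param min_score_frac Unknown-rule fraction, see [assign_cell_types()].
#' @param case_insensitive Upper-case gene symbols on both sides before
#'   matching data to markers.
#' @param contributions If `TRUE`, also return the per-gene contribution
#'   breakdown of every cluster/cell-type score.
#' @return An `sctype_annotation` object. `$assignments` holds one row per
#'   cluster (`cluster`, `n_cells`, `assigned_type`, `sctype_score`,
#'   `second_best`, `second_score`).
#' @examples
#' counts <- matrix(rpois(60, 5), nrow = 6,
#'                  dimnames = list(paste0("G", 1:6), paste0("c", 1:10)))
#' db <- marker_db("toy", c("A", "B"), list(c("G1", "G2"), c("G5", "G6")))
#' cl <- tibble::tibble(cell_id = paste0("c", 1:10), cluster = rep(c("1", "2"), each = 5))
#' ann <- annotate(counts, cl, db, "toy")
#' ann$assignments
#' @export
annotate <- function(x, clusters, db, tissue,
                     scale_total = 1e4, zscore = TRUE,
                     sd_type = "sample", min_score_frac = 0.25,
                     case_insensitive = FALSE, contributions = FALSE) {
  x <- as_expr_matrix(x)
  if (case_insensitive) {
    rownames(x$values) <- toupper(rownames(x$values))
    db$positive <- purrr::map(db$positive, toupper)
    db$negative <- purrr::map(db$negative, toupper)
  }
  if (x$layer == "raw") x <- normalize_counts(x, scale_total = scale_total)
  z <- if (zscore) zscore_genes(x, sd_type = sd_type) else {
    y <- expr_matrix(as.matrix(x$values), layer = "zscored")
    y
  }
  xw <- weight_by_specificity(z, db, tissue)
  e <- cell_enrichment(xw, db, tissue)
  sc <- cluster_scores(e, clusters)
  res <- assign_cell_types(sc, clusters, min_score_frac = min_score_frac, enrichment = e)
  res$tissue <- tissue
  if (contributions) {
    res$contributions <- gene_contributions(xw, db, tissue, clusters)
  }
  res
}

#' @keywords internal
gene_contributions <- function(xw, db, tissue, clusters) {
  cl <- as_cluster_assignment(clusters)
  v <- as.matrix(xw$values)
  genes <- rownames(v)
  sums <- rowsum(t(v[, names(cl), drop = FALSE]), group = cl)  # clusters x genes
  sets <- db[db$tissue == tissue, ]
  purrr::pmap_dfr(
    list(sets$positive, sets$negative, sets$cell_type),
    function(pos, neg, type) {
      pos <- intersect(pos, genes)
      neg <- intersect(neg, genes)
      j <- length(pos)
      l <- length(neg)
      out <- list()
      if (j > 0) {
        out$pos <- tibble::tibble(
          cluster = rep(rownames(sums), each = j),
          cell_type = type,
          gene = rep(pos, times = nrow(sums)),
          role = "positive",
          contribution = as.vector(t(sums[, pos, drop = FALSE])) / sqrt(j)
        )
      }
      if (l > 0) {
        out$neg <- tibble::tibble(
          cluster = rep(rownames(sums), each = l),
          cell_type = type,
          gene = rep(neg, times = nrow(sums)),
          role = "negative",
          contribution = -as.vector(t(sums[, neg, drop = FALSE])) / sqrt(l)
        )
      }
      dplyr::bind_rows(out)
    }
  )
}

#' @export
print.sctype_annotation <- function(x, ...) {
  n_unknown <- sum(x$assignments$assigned_type == "Unknown")
  cat(sprintf(
    "<sctype_annotation> %d clusters, %d cells, %d Unknown\n",
    nrow(x$assignments), sum(x$assignments$n_cells), n_unknown
  ))
  print(x$assignments)
  invisible(x)
}

#' Tidy the per-cluster score table of an annotation
#'
#' @param x An `sctype_annotation`.
#' @param ... Unused.
#' @return Long tibble `cluster`, `cell_type`, `score`, `rank`, `assigned`.
#' @export
tidy.sctype_annotation <- function(x, ...) {
  x$scores |>
    dplyr::left_join(
      dplyr::select(x$assignments, "cluster", "assigned_type"),
      by = "cluster"
    ) |>
    dplyr::mutate(assigned = .data$cell_type == .data$assigned_type & .data$rank == 1) |>
    dplyr::select("cluster", "cell_type", "score", "rank", "assigned")
}

#' One-row summary of an annotation
#'
#' @param x An `sctype_annotation`.
#' @param ... Unused.
#' @export
glance.sctype_annotation <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$assignments),
    n_cells = sum(x$assignments$n_cells),
    n_unknown = sum(x$assignments$assigned_type == "Unknown"),
    n_cell_types = length(unique(x$scores$cell_type)),
    min_score_frac = x$min_score_frac
  )
}

#' Heatmap of per-cluster annotation scores
#'
#' @param object An `sctype_annotation`.
#' @param ... Unused.
#' @return A ggplot object: clusters by cell types, tile fill = score, the
#'   assigned type of each cluster outlined.
#' @export
autoplot.sctype_annotation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type, y = .data$cluster, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(d, .data$assigned),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    ggplot2::labs(x = "cell type", y = "cluster", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
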