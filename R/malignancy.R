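#' Per-cell SNV burden in cancer genes
#'
#' Counts, for every cell, the number of distinct variants falling in cancer
#' census genes. A variant is present in a cell when its matrix entry is >= 1.
#' Duplicate variant columns (same variant id) are counted once.
#'
#' @param snv Cells-by-variants numeric matrix (dense or sparse) with cell ids
#'   as rownames and variant ids as colnames.
#' @param variant_genes Tibble `variant_id`, `gene` (or named vector mapping
#'   variant id to gene symbol). Every variant column must map to a gene.
#' @param cancer_genes Character vector of cancer gene symbols (e.g. a COSMIC
#'   census export).
#' @return Tibble `cell_id`, `burden`.
#' @export
snv_burden <- function(snv, variant_genes, cancer_genes) {
  if (length(cancer_genes) == 0) stop("cancer gene set is empty", call. = FALSE)
  if (is.data.frame(variant_genes)) {
    variant_genes <- stats::setNames(as.character(variant_genes$gene), variant_genes$variant_id)
  }
  if (anyDuplicated(colnames(snv))) {
    snv <- snv[, !duplicated(colnames(snv)), drop = FALSE]
  }
  unmapped <- setdiff(colnames(snv), names(variant_genes))
  if (length(unmapped) > 0) {
    stop(
      "variant(s) without gene annotation: ",
      paste(utils::head(unmapped, 5), collapse = ", "),
      call. = FALSE
    )
  }
  in_cancer <- variant_genes[colnames(snv)] %in% cancer_genes
  if (!any(in_cancer)) {
    warning("no variant maps to a cancer gene; all burdens are 0")
    return(tibble::tibble(cell_id = rownames(snv), burden = 0L))
  }
  sub <- snv[, in_cancer, drop = FALSE]
  present <- sub >= 1
  burden <- if (methods::is(present, "sparseMatrix") || methods::is(present, "lMatrix")) {
    as.integer(Matrix::rowSums(present))
  } else {
    as.integer(rowSums(present))
  }
  tibble::tibble(cell_id = rownames(snv), burden = burden)
}

#' SNV score per cell type
#'
#' For each cell type, the percentage of its cells whose cancer-gene SNV
#' burden is strictly above the median burden across all cells of the sample.
#'
#' @param burden Tibble `cell_id`, `burden` from [snv_burden()].
#' @param clusters Cell-type assignment per cell (data frame
#'   `cell_id`/`cluster` or named vector; clusters here are annotated cell
#'   types).
#' @return Tibble `cell_type`, `n_cells`, `snv_score` (percentage in
#'   \[0, 100\]).
#' @export
sctype_snv_score <- function(burden, clusters) {
  cl <- as_cluster_assignment(clusters)
  missing <- setdiff(names(cl), burden$cell_id)
  if (length(missing) > 0) {
    stop(
      "burden missing for cell(s): ", paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  b <- stats::setNames(burden$burden, burden$cell_id)[names(cl)]
  med <- stats::median(burden$burden)
  tibble::tibble(cell_id = names(cl), cell_type = unname(cl), above = b > med) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      snv_score = 100 * mean(.data$above),
      .groups = "drop"
    )
}

#' Classify cell types as malignant or non-malignant
#'
#' A cell type is non-malignant when its SNV score is below 20 **and** more
#' than half of its ploidy-called cells are diploid; otherwise malignant.
#' Both comparisons are strict. Cells with unknown ploidy are excluded from
#' the diploid fraction's denominator; a cell type whose ploidy is entirely
#' unknown is conservatively labeled malignant with `ploidy_missing = TRUE`
#' and a warning.
#'
#' @param scores Tibble from [sctype_snv_score()].
#' @param ploidy Tibble `cell_id`, `ploidy` with values `"diploid"`,
#'   `"aneuploid"` or `"unknown"` (or a named vector).
#' @param clusters Cell-type assignment per cell.
#' @param score_threshold SNV-score threshold (default 20).
#' @param diploid_threshold Diploid-majority threshold (default 0.5).
#' @return Tibble `cell_type`, `snv_score`, `diploid_fraction`,
#'   `n_ploidy_known`, `malignant` (logical), `ploidy_missing` (logical).
#' @export
classify_malignancy <- function(scores, ploidy, clusters,
                                score_threshold = 20, diploid_threshold = 0.5) {
  cl <- as_cluster_assignment(clusters)
  if (is.data.frame(ploidy)) {
    ploidy <- stats::setNames(as.character(ploidy$ploidy), ploidy$cell_id)
  }
  pl <- ploidy[names(cl)]
  pl[is.na(pl)] <- "unknown"
  frac <- tibble::tibble(cell_type = unname(cl), ploidy = unname(pl)) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_ploidy_known = sum(.data$ploidy != "unknown"),
      diploid_fraction = ifelse(
        .data$n_ploidy_known > 0,
        sum(.data$ploidy == "diploid") / .data$n_ploidy_known,
        NA_real_
      ),
      .groups = "drop"
    )
  out <- dplyr::left_join(scores, frac, by = "cell_type") |>
    dplyr::mutate(
      ploidy_missing = .data$n_ploidy_known == 0,
      malignant = !(
        .data$snv_score < score_threshold &
          !is.na(.data$diploid_fraction) &
          .data$diploid_fraction > diploid_threshold
      )
    ) |>
    dplyr::select(
      "cell_type", "snv_score", "diploid_fraction", "n_ploidy_known",
      "malignant", "ploidy_missing"
    )
  if (any(out$ploidy_missing)) {
    warning(
      "cell type(s) with no ploidy calls labeled malignant by default: ",
      paste(out$cell_type[out$ploidy_missing], collapse = ", ")
    )
  }
  out
}

#' SNV-sharing similarity between cell types
#'
#' Each cell type is represented by the set of cancer-gene variants present
#' in at least `theta` of its cells; similarity between two types is the
#' Jaccard index of those sets. A type with an empty variant set has
#' similarity 0 to everything, including itself (warning).
#'
#' @param snv Cells-by-variants matrix (see [snv_burden()]).
#' @param variant_genes Variant-to-gene map.
#' @param cancer_genes Cancer gene symbols.
#' @param clusters Cell-type assignment per cell.
#' @param theta Prevalence threshold (default 0.1).
#' @return Symmetric types-by-types numeric matrix.
#' @export
snv_similarity <- function(snv, variant_genes, cancer_genes, clusters, theta = 0.1) {
  cl <- as_cluster_assignment(clusters)
  types <- sort(unique(cl))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (is.data.frame(variant_genes)) {
    variant_genes <- stats::setNames(as.character(variant_genes$gene), variant_genes$variant_id)
  }
  if (anyDuplicated(colnames(snv))) {
    snv <- snv[, !duplicated(colnames(snv)), drop = FALSE]
  }
  in_cancer <- variant_genes[colnames(snv)] %in% cancer_genes
  sub <- as.matrix(snv[names(cl), in_cancer, drop = FALSE]) >= 1
  sets <- purrr::map(types, function(tp) {
    cells <- names(cl)[cl == tp]
    prev <- colMeans(sub[cells, , drop = FALSE])
    colnames(sub)[prev >= theta]
  })
  names(sets) <- types
  if (any(lengths(sets) == 0)) {
    warning(
      "cell type(s) with empty variant set: ",
      paste(types[lengths(sets) == 0], collapse = ", ")
    )
  }
  sim <- matrix(0, length(types), length(types), dimnames = list(types, types))
  for (a in seq_along(types)) {
    for (b in seq_len(a)) {
      u <- length(union(sets[[a]], sets[[b]]))
      sim[a, b] <- sim[b, a] <- if (u == 0) 0 else {
        length(intersect(sets[[a]], sets[[b]])) / u
      }
    }
  }
  sim
}
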