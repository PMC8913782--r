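#' Per-cell annotation accuracy
#'
#' Fraction of cells whose cluster's assigned label matches the cell's true
#' type. `"Unknown"` counts as incorrect — unless the cell's true type is the
#' held-out type of a leave-one-cell-type-out run, in which case `"Unknown"`
#' is the correct call.
#'
#' @param result An `sctype_annotation`.
#' @param truth Tibble `cell_id`, `cell_type` (or named vector) covering all
#'   clustered cells.
#' @param held_out Optional name of a held-out cell type.
#' @return A fraction in \[0, 1\].
#' @export
annotation_accuracy <- function(result, truth, held_out = NULL) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$cell_type), truth$cell_id)
  }
  cl <- stats::setNames(result$clusters$cluster, result$clusters$cell_id)
  if (!all(names(cl) %in% names(truth))) {
    stop("truth does not cover all clustered cells", call. = FALSE)
  }
  assigned <- stats::setNames(result$assignments$assigned_type, result$assignments$cluster)
  labels <- assigned[cl[names(cl)]]
  true_types <- truth[names(cl)]
  foreign <- setdiff(setdiff(unique(labels), "Unknown"), unique(true_types))
  if (length(foreign) > 0) {
    stop(
      "assigned label(s) absent from truth: ", paste(foreign, collapse = ", "),
      call. = FALSE
    )
  }
  correct <- labels == true_types
  if (!is.null(held_out)) {
    ho <- true_types == held_out
    correct[ho] <- labels[ho] == "Unknown"
  }
  mean(correct)
}

benchmark_config <- function(seed, dropout_mid, n_genes, n_cells, de_fac_scales) {
  # de.facScale drawn per dataset from the configured set, as in the
  # moderate-similarity benchmark world
  set.seed(seed)
  sim_config(
    seed = seed,
    n_genes = n_genes, n_cells = n_cells,
    de_fac_scale = sample(de_fac_scales, 1),
    dropout_mid = dropout_mid
  )
}

#' Dropout-robustness benchmark
#'
#' For each dropout level and replicate: simulate a dataset, extract the top
#' `k` specific (or unspecific) markers per cell type, build an in-memory
#' marker database, annotate using the true groups as clusters, and record
#' the per-cell accuracy. Using truth as the clustering isolates annotation
#' quality from clustering noise.
#'
#' @param n_per_level Replicates per dropout level (the full-scale benchmark
#'   uses 15).
#' @param levels Dropout midpoints (default -2.5, 0, 2.5 for ~50/65/80%
#'   zeros at shape -0.5).
#' @param seed Integer master seed; per-dataset seeds derive from it.
#' @param n_genes,n_cells Dataset dimensions.
#' @param k Markers per type.
#' @param marker_type `"specific"` (one-vs-rest top-k) or `"unspecific"`
#'   (pooled-pair top-k union, sampled).
#' @param de_fac_scales Set from which each dataset's DE factor scale is
#'   drawn (default 0.5, 0.6, 0.7).
#' @param zscore Passed to [annotate()] (ablation switch).
#' @return Tibble with one row per dataset: `dropout_mid`, `seed`,
#'   `de_fac_scale`, `realized_dropout`, `accuracy`, `runtime_s`.
#' @export
dropout_benchmark <- function(n_per_level = 15, levels = c(-2.5, 0, 2.5),
                              seed = 1, n_genes = 2000, n_cells = 2000,
                              k = 10, marker_type = c("specific", "unspecific"),
                              de_fac_scales = c(0.5, 0.6, 0.7), zscore = TRUE) {
  marker_type <- match.arg(marker_type)
  if (n_per_level == 0) {
    return(tibble::tibble(
      dropout_mid = numeric(), seed = integer(), de_fac_scale = numeric(),
      realized_dropout = numeric(), accuracy = numeric(), runtime_s = numeric()
    ))
  }
  grid <- tidyr::expand_grid(dropout_mid = levels, rep = seq_len(n_per_level))
  purrr::pmap_dfr(grid, function(dropout_mid, rep) {
    ds_seed <- (seed * 1000L + which(levels == dropout_mid) * 100L + rep) %% .Machine$integer.max
    cfg <- benchmark_config(ds_seed, dropout_mid, n_genes, n_cells, de_fac_scales)
    t0 <- proc.time()[["elapsed"]]
    sim <- simulate_counts(cfg)
    markers <- if (marker_type == "specific") {
      extract_markers(sim, k = k)
    } else {
      extract_unspecific_markers(sim, k = k, seed = ds_seed)
    }
    db <- markers_to_db(markers)
    ann <- annotate(sim$counts, clusters_from_truth(sim$truth), db, "simulated", zscore = zscore)
    acc <- annotation_accuracy(ann, sim$truth)
    tibble::tibble(
      dropout_mid = dropout_mid, seed = ds_seed,
      de_fac_scale = cfg$de_fac_scale,
      realized_dropout = sim$realized_dropout,
      accuracy = acc,
      runtime_s = proc.time()[["elapsed"]] - t0
    )
  })
}

#' @keywords internal
clusters_from_truth <- function(truth) {
  tibble::tibble(cell_id = truth$cell_id, cluster = truth$cell_type)
}

#' Leave-one-cell-type-out unknown-detection benchmark
#'
#' Per dataset, one seeded-random cell type's marker signature is removed
#' from the marker set before annotation; the dataset counts as a detection
#' when the held-out type's cluster is labeled `"Unknown"` by the
#' low/negative-score rule. Datasets are spread evenly over the dropout
#' levels.
#'
#' @param n_datasets Total datasets (full scale: 45, i.e. 15 per level).
#' @param levels Dropout midpoints.
#' @param seed Master seed.
#' @param n_genes,n_cells,k,de_fac_scales As in [dropout_benchmark()].
#' @return Tibble with one row per dataset: `dropout_mid`, `seed`,
#'   `held_out_type`, `detected` (logical), `others_correct` (fraction of
#'   non-held-out clusters still labeled correctly).
#' @export
unknown_benchmark <- function(n_datasets = 45, levels = c(-2.5, 0, 2.5),
                              seed = 1, n_genes = 2000, n_cells = 2000,
                              k = 10, de_fac_scales = c(0.5, 0.6, 0.7)) {
  if (n_datasets == 0) {
    return(tibble::tibble(
      dropout_mid = numeric(), seed = integer(), held_out_type = character(),
      detected = logical(), others_correct = numeric()
    ))
  }
  mids <- rep(levels, length.out = n_datasets)
  purrr::map_dfr(seq_len(n_datasets), function(i) {
    ds_seed <- (seed * 1000L + 7L * i) %% .Machine$integer.max
    cfg <- benchmark_config(ds_seed, mids[i], n_genes, n_cells, de_fac_scales)
    sim <- simulate_counts(cfg)
    markers <- extract_markers(sim, k = k)
    types <- sort(unique(sim$truth$cell_type))
    set.seed(ds_seed + 1L)
    held_out <- sample(types, 1)
    db <- markers_to_db(dplyr::filter(markers, .data$cell_type != held_out))
    ann <- annotate(sim$counts, clusters_from_truth(sim$truth), db, "simulated")
    assigned <- stats::setNames(ann$assignments$assigned_type, ann$assignments$cluster)
    others <- setdiff(types, held_out)
    tibble::tibble(
      dropout_mid = mids[i], seed = ds_seed, held_out_type = held_out,
      detected = unname(assigned[held_out] == "Unknown"),
      others_correct = mean(assigned[others] == others)
    )
  })
}
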