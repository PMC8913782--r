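#' Simulation configuration
#'
#' Parameters of the gamma-Poisson single-cell count simulator with logistic
#' dropout (a Splatter-style generative model). Defaults describe the
#' benchmark world used throughout: 10 cell types at lognormal-scaled
#' proportions, 2,000 genes by 2,000 cells, moderate between-type similarity
#' (`de_fac_scale` 0.5-0.7), dropout shape -0.5 with midpoint -2.5/0/2.5
#' giving roughly 50/65/80% zeros.
#'
#' @param seed Integer seed; every stochastic draw derives from it.
#' @param n_cell_types Number of cell types (default 10).
#' @param n_genes,n_cells Matrix dimensions (default 2,000 each).
#' @param proportions Optional explicit cell-type proportions (normalised to
#'   sum 1); default lognormal-scaled random deviates, see
#'   [default_proportions()].
#' @param de_fac_scale sdlog of the lognormal differential-expression factors
#'   (one of 0.5, 0.6, 0.7 in the benchmark world).
#' @param dropout_shape,dropout_mid Logistic dropout parameters; probability
#'   of zeroing an entry is `plogis(dropout_shape * (log(mean) - dropout_mid))`
#'   with `mean` the pre-Poisson expected count.
#' @param dropout Set `FALSE` to disable the dropout step entirely.
#' @param mean_shape,mean_rate Gamma parameters of the base gene means.
#' @param lib_loc,lib_sdlog Lognormal library-size parameters; `lib_loc = NULL`
#'   defaults to `log(3 * n_genes)` (about 3 counts per gene on average),
#'   calibrated so the three dropout midpoints land on ~50/65/80% zeros.
#' @param de_prob Probability that a gene is differentially expressed in a
#'   given cell type.
#' @param de_loc meanlog of the DE factors.
#' @param de_down_prob Probability a DE factor is inverted (down-regulation).
#' @param bcv Common biological coefficient of variation of the gamma noise
#'   on expected counts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_cell_types = 10, n_genes = 2000, n_cells = 2000,
                       proportions = NULL, de_fac_scale = 0.5,
                       dropout_shape = -0.5, dropout_mid = -2.5,
                       dropout = TRUE,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = NULL, lib_sdlog = 0.2,
                       de_prob = 0.1, de_loc = 0.1, de_down_prob = 0.5,
                       bcv = 0.1) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  if (n_cell_types < 2) stop("need at least 2 cell types", call. = FALSE)
  if (n_cells < n_cell_types) {
    stop("infeasible config: n_cells < n_cell_types", call. = FALSE)
  }
  if (de_fac_scale <= 0) stop("de_fac_scale must be positive", call. = FALSE)
  if (!is.null(proportions)) {
    if (length(proportions) != n_cell_types || any(proportions <= 0)) {
      stop("proportions must be ", n_cell_types, " positive values", call. = FALSE)
    }
    proportions <- proportions / sum(proportions)
  }
  if (is.null(lib_loc)) lib_loc <- log(3 * n_genes)
  structure(
    list(
      seed = as.integer(seed), n_cell_types = n_cell_types,
      n_genes = n_genes, n_cells = n_cells, proportions = proportions,
      de_fac_scale = de_fac_scale, dropout_shape = dropout_shape,
      dropout_mid = dropout_mid, dropout = dropout,
      mean_shape = mean_shape, mean_rate = mean_rate,
      lib_loc = lib_loc, lib_sdlog = lib_sdlog,
      de_prob = de_prob, de_loc = de_loc, de_down_prob = de_down_prob,
      bcv = bcv
    ),
    class = "sim_config"
  )
}

#' Lognormal-scaled random cell-type proportions
#'
#' Draws `n` lognormal deviates, sorts them in decreasing order and normalises
#' to sum 1, giving the heavy-tailed composition typical of real tissues
#' (a handful of dominant types and several rare ones).
#'
#' @param n Number of cell types (>= 2).
#' @param seed Integer seed.
#' @param sdlog Spread of the deviates (default 1).
#' @return Numeric vector of length `n`, decreasing, summing to 1.
#' @export
default_proportions <- function(n, seed, sdlog = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  p <- sort(stats::rlnorm(n, meanlog = 0, sdlog = sdlog), decreasing = TRUE)
  p / sum(p)
}

#' Simulate a single-cell count dataset
#'
#' Generative model: base gene means are gamma-distributed; each cell type
#' multiplies a random subset of genes (probability `de_prob`) by lognormal
#' DE factors (sdlog `de_fac_scale`, down-regulated with probability
#' `de_down_prob`); each cell's expected profile is its type's mean vector
#' rescaled to a lognormal library size; gamma noise with coefficient of
#' variation `bcv` is applied entry-wise and counts drawn Poisson; finally
#' each entry is zeroed with probability
#' `plogis(dropout_shape * (log(mu) - dropout_mid))` where `mu` is the
#' pre-Poisson expected count. Fully reproducible from `config$seed`.
#'
#' Every configured cell type is guaranteed at least 3 cells (cells are
#' reassigned from the largest types when the multinomial draw leaves a type
#' below that floor), so that downstream one-vs-rest testing is always
#' feasible.
#'
#' @param config A [sim_config()].
#' @return A `sctype_sim` list: `counts` (genes-by-cells integer matrix),
#'   `truth` (tibble `cell_id`, `cell_type`), `de_genes` (tibble `cell_type`,
#'   `gene`, `factor` for factors != 1), `realized_dropout` (overall zero
#'   fraction of `counts`), `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nc <- config$n_cells
  nt <- config$n_cell_types
  types <- sprintf("Type%02d", seq_len(nt))

  prop <- config$proportions
  if (is.null(prop)) {
    p <- sort(stats::rlnorm(nt, 0, 1), decreasing = TRUE)
    prop <- p / sum(p)
  }

  base_mean <- stats::rgamma(ng, shape = config$mean_shape, rate = config$mean_rate)
  genes <- sprintf("Gene%05d", seq_len(ng))

  fac <- matrix(1, ng, nt)
  for (t in seq_len(nt)) {
    de <- stats::runif(ng) < config$de_prob
    f <- stats::rlnorm(sum(de), meanlog = config$de_loc, sdlog = config$de_fac_scale)
    dn <- stats::runif(sum(de)) < config$de_down_prob
    f[dn] <- 1 / f[dn]
    fac[de, t] <- f
  }
  type_mean <- base_mean * fac

  cell_type <- sample(seq_len(nt), nc, replace = TRUE, prob = prop)
  # floor of 3 cells per type: steal from the largest types, deterministically
  tab <- tabulate(cell_type, nbins = nt)
  for (t in which(tab < 3)) {
    need <- 3 - tab[t]
    donors <- which(cell_type == which.max(tabulate(cell_type, nbins = nt)))
    cell_type[donors[seq_len(need)]] <- t
    tab <- tabulate(cell_type, nbins = nt)
  }

  lib <- stats::rlnorm(nc, meanlog = config$lib_loc, sdlog = config$lib_sdlog)
  mu <- type_mean[, cell_type, drop = FALSE]
  mu <- sweep(mu, 2, colSums(type_mean)[cell_type], "/")
  mu <- sweep(mu, 2, lib, "*")

  if (config$bcv > 0) {
    # Splatter-style mean-dependent biological CV: common term + 1/sqrt(mean)
    bcv <- config$bcv + 1 / sqrt(pmax(mu, .Machine$double.eps))
    shape <- 1 / bcv^2
    mu <- matrix(stats::rgamma(length(mu), shape = shape, scale = mu / shape), ng)
  }
  counts <- matrix(stats::rpois(length(mu), mu), ng)

  if (config$dropout) {
    pdrop <- stats::plogis(config$dropout_shape * (log(mu) - config$dropout_mid))
    keep <- matrix(stats::rbinom(length(pdrop), 1, 1 - pdrop), ng)
    counts <- counts * keep
  }
  dimnames(counts) <- list(genes, sprintf("Cell%05d", seq_len(nc)))

  de_idx <- which(fac != 1, arr.ind = TRUE)
  de_genes <- tibble::tibble(
    cell_type = types[de_idx[, 2]],
    gene = genes[de_idx[, 1]],
    factor = fac[de_idx]
  )

  structure(
    list(
      counts = counts,
      truth = tibble::tibble(
        cell_id = colnames(counts),
        cell_type = types[cell_type]
      ),
      de_genes = de_genes,
      realized_dropout = mean(counts == 0),
      config = config
    ),
    class = "sctype_sim"
  )
}

#' @export
print.sctype_sim <- function(x, ...) {
  cat(sprintf(
    "<sctype_sim> %d genes x %d cells, %d cell types, %.1f%% zeros (seed %d)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$truth$cell_type)),
    100 * x$realized_dropout, x$config$seed
  ))
  invisible(x)
}

# Vectorised one-vs-rest Wilcoxon rank-sum machinery: ranks (with average
# ties) are computed once per gene across all cells and reused for every
# grouping, with the normal approximation and per-gene tie correction.
rank_stats <- function(xnorm) {
  ranks <- t(apply(xnorm, 1, rank))
  tie_term <- apply(xnorm, 1, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  list(ranks = ranks, tie_term = tie_term, lognorm = xnorm)
}

wilcox_group <- function(rs, in_group) {
  n <- ncol(rs$ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  w <- rowSums(rs$ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - rs$tie_term / (n * (n - 1)))
  z <- (w - n1 * n2 / 2) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-abs(z))
  lfc <- rowMeans(rs$lognorm[, in_group, drop = FALSE]) -
    rowMeans(rs$lognorm[, !in_group, drop = FALSE])
  tibble::tibble(
    gene = rownames(rs$ranks),
    statistic = z,
    p_value = p,
    lfc = lfc,
    up = w > n1 * n2 / 2
  )
}

top_up_genes <- function(de, k) {
  # p is monotone in |z| but underflows to 0 at these sample sizes, which
  # would reduce "rank by p" to the fold-change tiebreak; order by z instead
  de |>
    dplyr::filter(.data$up) |>
    dplyr::arrange(dplyr::desc(.data$statistic), dplyr::desc(.data$lfc)) |>
    dplyr::slice_head(n = k)
}

#' Extract highly-specific marker genes from a simulated dataset
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene on the normalised
#' expression (normal approximation with tie correction), ranked by p-value
#' with log fold-change breaking ties; the top `k` up-regulated genes per
#' cell type are returned.
#'
#' @param sim A `sctype_sim` (or any list with `counts` and `truth`).
#' @param k Markers per cell type (default 10). `k` beyond the number of
#'   up-regulated genes is truncated (`strict = FALSE`, a warning) or an
#'   error (`strict = TRUE`).
#' @param strict Error instead of truncating short lists.
#' @return Tibble `cell_type`, `gene`, `rank`, `p_value`, `lfc`.
#' @export
extract_markers <- function(sim, k = 10, strict = FALSE) {
  truth <- sim$truth
  types <- sort(unique(truth$cell_type))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  small <- names(which(table(truth$cell_type) < 3))
  if (length(small) > 0) {
    stop("cell type(s) with fewer than 3 cells: ", paste(small, collapse = ", "), call. = FALSE)
  }
  if (k > nrow(sim$counts)) {
    if (strict) stop("k exceeds the number of genes", call. = FALSE)
    warning("k exceeds the number of genes; truncating")
    k <- nrow(sim$counts)
  }
  xnorm <- as.matrix(normalize_counts(expr_matrix(sim$counts))$values)
  rs <- rank_stats(xnorm)
  n_cells_all <- ncol(sim$counts)
  out <- purrr::map_dfr(types, function(tp) {
    de <- wilcox_group(rs, truth$cell_type == tp)
    top <- top_up_genes(de, k)
    if (nrow(top) < k) warning(sprintf("only %d up-regulated genes for %s", nrow(top), tp))
    # Bonferroni-adjusted null-signal check: uniform p-values trip it, real DE
    # does not; suppressed when the group is too small for the rank-sum test
    # to reach significance at all (p floor above the adjusted threshold)
    n1 <- sum(truth$cell_type == tp)
    z_max <- sqrt(3 * n1 * (n_cells_all - n1) / (n_cells_all + 1))
    achievable <- 2 * stats::pnorm(-z_max) * nrow(sim$counts) <= 0.05
    if (achievable && nrow(top) > 0 && min(top$p_value) * nrow(sim$counts) > 0.05) {
      warning(sprintf("no significant markers for %s (min p = %.3g)", tp, min(top$p_value)))
    }
    dplyr::mutate(top, cell_type = tp, rank = dplyr::row_number())
  })
  dplyr::select(out, "cell_type", "gene", "rank", "p_value", "lfc")
}

#' Extract low-specificity ("unspecific") marker genes
#'
#' For a target cell type n, every pair (n, other type) is pooled and tested
#' against all remaining cells; the top `k` up-regulated genes of each pair
#' test are combined and `k` genes are sampled uniformly from the union.
#' These genes discriminate mixtures containing the target type rather than
#' the target type itself, mimicking promiscuous markers.
#'
#' @param sim A `sctype_sim`.
#' @param k Markers per cell type (default 10).
#' @param seed Integer seed for the sampling step.
#' @return Tibble `cell_type`, `gene`.
#' @export
extract_unspecific_markers <- function(sim, k = 10, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  truth <- sim$truth
  types <- sort(unique(truth$cell_type))
  if (length(types) < 3) stop("need at least 3 cell types", call. = FALSE)
  xnorm <- as.matrix(normalize_counts(expr_matrix(sim$counts))$values)
  rs <- rank_stats(xnorm)
  set.seed(seed)
  purrr::map_dfr(types, function(tp) {
    pool <- unlist(purrr::map(setdiff(types, tp), function(o) {
      de <- wilcox_group(rs, truth$cell_type %in% c(tp, o))
      top_up_genes(de, k)$gene
    }))
    pool <- unique(pool)
    if (length(pool) < k) {
      warning(sprintf("unspecific pool for %s smaller than k; returning all %d", tp, length(pool)))
      sel <- pool
    } else {
      sel <- sample(pool, k)
    }
    tibble::tibble(cell_type = tp, gene = sel)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the 10x-style MatrixMarket triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) plus `truth.tsv` (`cell_id`, `cell_type`).
#'
#' @param sim A `sctype_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(sim$counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(id = rownames(sim$counts), symbol = rownames(sim$counts)),
    file.path(dir, "features.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(barcode = colnames(sim$counts)),
    file.path(dir, "barcodes.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
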