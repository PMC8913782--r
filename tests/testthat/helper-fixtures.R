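# Shared fixtures and the literal (loop-based) scoring oracle.

toy_db_path <- function() system.file("extdata", "toy_markers.tsv", package = "sctyper")
toy_counts_path <- function() system.file("extdata", "toy_counts.tsv", package = "sctyper")
toy_clusters_path <- function() system.file("extdata", "toy_clusters.tsv", package = "sctyper")

toy_fixture <- function() {
  x <- suppressMessages(read_expression(toy_counts_path()))
  list(
    x = x,
    clusters = read_cluster_labels(toy_clusters_path()),
    db = read_marker_db(toy_db_path(), tissue = "Immune system"),
    expected = c(`1` = "B cell", `2` = "Plasma cell", `3` = "T cell")
  )
}

random_marker_db <- function(genes, n_types = 5, seed = 1) {
  set.seed(seed)
  pos <- list()
  neg <- list()
  for (i in seq_len(n_types)) {
    pos[[i]] <- sample(genes, sample(2:5, 1))
    rest <- setdiff(genes, pos[[i]])
    neg[[i]] <- if (stats::runif(1) < 0.5) sample(rest, sample(1:3, 1)) else character()
  }
  marker_db(rep("rand", n_types), paste0("T", seq_len(n_types)), pos, neg)
}

# Independent oracle: per-cell, per-gene double loops implementing the
# formulas literally. Deliberately avoids the package's vectorised path.
naive_sctype <- function(counts, clusters, db, tissue, scale_total = 1e4) {
  counts <- as.matrix(counts)
  m <- nrow(counts); n <- ncol(counts)
  norm <- counts
  for (cc in seq_len(n)) {
    tot <- sum(counts[, cc])
    for (g in seq_len(m)) {
      norm[g, cc] <- log1p(if (tot > 0) counts[g, cc] / tot * scale_total else 0)
    }
  }
  z <- norm
  for (g in seq_len(m)) {
    mu <- mean(norm[g, ])
    sdv <- sqrt(sum((norm[g, ] - mu)^2) / (n - 1))
    for (cc in seq_len(n)) z[g, cc] <- if (sdv > 0) (norm[g, cc] - mu) / sdv else 0
  }
  sets <- db[db$tissue == tissue, ]
  pooled <- unique(unlist(c(sets$positive, sets$negative)))
  n_enlist <- sapply(pooled, function(g) {
    sum(sapply(seq_len(nrow(sets)), function(i) {
      g %in% sets$positive[[i]] || g %in% sets$negative[[i]]
    }))
  })
  lo <- min(n_enlist); hi <- max(n_enlist)
  spec <- sapply(n_enlist, function(k) if (hi == lo) 1 else 1 - (k - lo) / (hi - lo))
  names(spec) <- pooled
  xp <- matrix(0, n, nrow(sets), dimnames = list(colnames(counts), sets$cell_type))
  for (cc in seq_len(n)) {
    for (i in seq_len(nrow(sets))) {
      pos <- intersect(sets$positive[[i]], rownames(counts))
      neg <- intersect(sets$negative[[i]], rownames(counts))
      j <- length(pos); l <- length(neg)
      s <- 0
      if (j > 0) {
        for (g in pos) s <- s + z[g, cc] * spec[[g]] / sqrt(j)
        if (l > 0) for (g in neg) s <- s - z[g, cc] * spec[[g]] / sqrt(l)
      }
      xp[cc, i] <- s
    }
  }
  cl <- stats::setNames(as.character(clusters$cluster), clusters$cell_id)
  clusters_u <- unique(unname(cl))
  sc <- matrix(0, length(clusters_u), nrow(sets),
               dimnames = list(clusters_u, sets$cell_type))
  for (p in clusters_u) {
    for (i in seq_len(nrow(sets))) {
      sc[p, i] <- sum(xp[names(cl)[cl == p], i])
    }
  }
  labels <- character(length(clusters_u))
  names(labels) <- clusters_u
  for (p in clusters_u) {
    ord <- order(-sc[p, ], colnames(sc))
    best <- sc[p, ord[1]]
    size <- sum(cl == p)
    labels[p] <- if (best < size / 4 || best < 0) "Unknown" else colnames(sc)[ord[1]]
  }
  list(enrichment = xp, scores = sc, labels = labels)
}
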