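test_that("normalize_counts scales cells to a common total then log1p", {
  x <- matrix(c(1, 1, 2, 2, 2, 4, 0, 0, 0), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  expect_warning(out <- normalize_counts(expr_matrix(x), scale_total = 4), "zero total")
  expect_equal(out$layer, "normalized")
  expect_equal(unname(as.matrix(out)[, 1]), log1p(c(1, 1, 2)))  # total already 4
  # proportional cells normalise identically
  expect_equal(as.matrix(out)[, 1], as.matrix(out)[, 2], ignore_attr = TRUE)
  expect_equal(unname(as.matrix(out)[, 3]), c(0, 0, 0))
  expect_error(normalize_counts(matrix(-1)), "non-negative")
})

test_that("zscore_genes standardises rows with sample SD and zeroes flat genes", {
  x <- expr_matrix(
    matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), paste0("c", 1:3))),
    layer = "normalized"
  )
  z <- as.matrix(zscore_genes(x))
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_lt(abs(mean(z["g1", ])), 1e-10)
  # population SD option
  zp <- as.matrix(zscore_genes(x, sd_type = "population"))
  expect_equal(unname(zp["g1", ]), c(-1, 0, 1) * sqrt(3 / 2))
})

test_that("weight_by_specificity restricts to markers and scales by S", {
  z <- expr_matrix(
    matrix(rep(c(-1, 0, 1), 4), nrow = 4, byrow = TRUE,
           dimnames = list(paste0("g", 1:4), paste0("c", 1:3))),
    layer = "zscored"
  )
  # g1 in 1 type (S=1), g2 in 2 (S=0.5), g3 in 3 (S=0); g5 not in data
  db <- marker_db(
    rep("t", 3), c("A", "B", "C"),
    list(c("g1", "g2", "g3"), c("g2", "g3", "g5"), "g3")
  )
  expect_message(w <- weight_by_specificity(z, db, "t"), "absent from the data")
  expect_equal(sort(rownames(w$values)), c("g1", "g2", "g3"))
  expect_equal(unname(as.matrix(w)["g1", ]), c(-1, 0, 1))
  expect_equal(unname(as.matrix(w)["g2", ]), c(-0.5, 0, 0.5))
  expect_equal(unname(as.matrix(w)["g3", ]), c(0, 0, 0))
  db2 <- marker_db("t", "A", list("not_there"))
  expect_error(weight_by_specificity(z, db2, "t"), "no marker genes found in data")
})

test_that("cell enrichment applies the sqrt(j), sqrt(l) normalisers", {
  v <- matrix(
    c(1, 0,
      1, 0,
      1, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("p1", "p2", "n1"), c("c1", "c2"))
  )
  xw <- expr_matrix(v, layer = "zscored")
  attr(xw, "weighted") <- TRUE
  db_pos <- marker_db("t", "A", list(c("p1", "p2")))
  e <- cell_enrichment(xw, db_pos, "t")
  expect_equal(unname(e["c1", "A"]), 2 / sqrt(2))
  expect_equal(unname(e["c2", "A"]), 0)  # no markers expressed
  db_neg <- marker_db("t", "A", list(c("p1", "p2")), list("n1"))
  e2 <- cell_enrichment(xw, db_neg, "t")
  expect_equal(unname(e2["c1", "A"]), 2 / sqrt(2) - 1)
  # cell type with no positive marker in data scores 0 with a warning
  db_miss <- marker_db(c("t", "t"), c("A", "B"), list("p1", "zzz"))
  expect_warning(e3 <- cell_enrichment(xw, db_miss, "t"), "no positive markers")
  expect_equal(unname(e3[, "B"]), c(0, 0))
})

test_that("cluster scores are exact per-cluster sums partitioning the total", {
  e <- matrix(c(1, 2, 3, -1, 0, 1), ncol = 2,
              dimnames = list(paste0("c", 1:3), c("A", "B")))
  cl <- tibble::tibble(cell_id = paste0("c", 1:3), cluster = c("p1", "p1", "p2"))
  sc <- cluster_scores(e, cl)
  expect_equal(sc$score[sc$cluster == "p1" & sc$cell_type == "A"], 3)
  expect_equal(sc$score[sc$cluster == "p2" & sc$cell_type == "A"], 3)
  tot <- sc |> dplyr::group_by(cell_type) |> dplyr::summarise(s = sum(score))
  expect_equal(tot$s, unname(colSums(e)))
  bad <- tibble::tibble(cell_id = c("c1", "c9"), cluster = c("p", "p"))
  expect_error(cluster_scores(e, bad), "c9")
})

test_that("unknown rule: strict quarter-of-cluster and negative-score thresholds", {
  mk_scores <- function(best, cluster = "p") {
    tibble::tibble(cluster = cluster, cell_type = c("A", "B"), score = c(best, best - 5))
  }
  cl100 <- tibble::tibble(cell_id = paste0("c", 1:100), cluster = "p")
  expect_equal(
    assign_cell_types(mk_scores(30), cl100)$assignments$assigned_type, "A"
  )
  expect_equal(
    assign_cell_types(mk_scores(20), cl100)$assignments$assigned_type, "Unknown"
  )
  # boundary: exactly n/4 is not "less than" -> keep the label
  expect_equal(
    assign_cell_types(mk_scores(25), cl100)$assignments$assigned_type, "A"
  )
  cl8 <- tibble::tibble(cell_id = paste0("c", 1:8), cluster = "p")
  expect_equal(
    assign_cell_types(mk_scores(-1), cl8)$assignments$assigned_type, "Unknown"
  )
  # ties broken lexicographically with a warning
  tie <- tibble::tibble(cluster = "p", cell_type = c("B", "A"), score = c(50, 50))
  expect_warning(res <- assign_cell_types(tie, cl100), "tied")
  expect_equal(res$assignments$assigned_type, "A")
})

test_that("annotate labels the packaged fixture and is order-invariant", {
  fx <- toy_fixture()
  ann <- annotate(fx$x, fx$clusters, fx$db, "Immune system")
  got <- setNames(ann$assignments$assigned_type, ann$assignments$cluster)
  expect_equal(got[names(fx$expected)], fx$expected)
  # per-cluster enrichment column sums equal the cluster scores
  cl <- setNames(fx$clusters$cluster, fx$clusters$cell_id)
  for (p in unique(cl)) {
    sums <- colSums(ann$enrichment[names(cl)[cl == p], , drop = FALSE])
    sc <- ann$scores[ann$scores$cluster == p, ]
    expect_equal(sums[sc$cell_type], setNames(sc$score, sc$cell_type))
  }
  # shuffled cells and genes give the identical result
  set.seed(42)
  v <- as.matrix(fx$x)[sample(nrow(fx$x)), sample(ncol(fx$x))]
  ann2 <- annotate(v, fx$clusters[sample(nrow(fx$clusters)), ], fx$db, "Immune system")
  expect_equal(
    dplyr::arrange(ann2$assignments, cluster),
    dplyr::arrange(ann$assignments, cluster)
  )
})

test_that("an expressed negative marker strictly lowers the wrong type's score", {
  fx <- toy_fixture()
  # positive-only database with filler types pinning max enlistment at 3, so
  # the negative marker keeps non-zero specificity when added back
  db_pos <- marker_db(
    rep("Immune system", 5),
    c("B cell", "Plasma cell", "T cell", "Pan1", "Pan2"),
    list(c("CD79A", "CD79B", "CD19", "MS4A1"), c("SDC1", "PRDM1"),
         c("CD3D", "CD3E"), c("CD19", "CD3D", "SDC1"), c("CD19", "ACTB"))
  )
  db_neg <- db_pos
  db_neg$negative[[2]] <- "MS4A1"
  ann_pos <- annotate(fx$x, fx$clusters, db_pos, "Immune system")
  ann_neg <- suppressWarnings(annotate(fx$x, fx$clusters, db_neg, "Immune system"))
  plasma_in_b <- function(a) {
    s <- a$scores
    s$score[s$cluster == "1" & s$cell_type == "Plasma cell"]
  }
  expect_lt(plasma_in_b(ann_neg), plasma_in_b(ann_pos))
})

test_that("duplicated cells leave per-cell enrichment unchanged and scores additive", {
  fx <- toy_fixture()
  v <- as.matrix(fx$x)
  v2 <- cbind(v, v[, "c1", drop = FALSE])
  colnames(v2)[10] <- "c1b"
  cl2 <- dplyr::bind_rows(fx$clusters, tibble::tibble(cell_id = "c1b", cluster = "1"))
  ann2 <- annotate(v2, cl2, fx$db, "Immune system")
  # identical cells get identical enrichment, and the cluster score is the
  # plain sum over its cells (so a duplicate adds exactly its own x')
  expect_equal(ann2$enrichment["c1", ], ann2$enrichment["c1b", ])
  s2 <- ann2$scores[ann2$scores$cluster == "1" & ann2$scores$cell_type == "B cell", "score"][[1]]
  expect_equal(
    s2,
    sum(ann2$enrichment[c("c1", "c2", "c3", "c1b"), "B cell"])
  )
})

test_that("gene contributions decompose every cluster score", {
  fx <- toy_fixture()
  ann <- annotate(fx$x, fx$clusters, fx$db, "Immune system", contributions = TRUE)
  recomposed <- ann$contributions |>
    dplyr::group_by(cluster, cell_type) |>
    dplyr::summarise(score = sum(contribution), .groups = "drop") |>
    dplyr::arrange(cluster, cell_type)
  direct <- ann$scores |>
    dplyr::select(cluster, cell_type, score) |>
    dplyr::arrange(cluster, cell_type)
  expect_equal(recomposed$score, direct$score)
})

test_that("tidy, glance and autoplot work on an annotation", {
  fx <- toy_fixture()
  ann <- annotate(fx$x, fx$clusters, fx$db, "Immune system")
  td <- tidy(ann)
  expect_true(all(c("cluster", "cell_type", "score", "rank", "assigned") %in% names(td)))
  expect_equal(sum(td$assigned), 3)
  gl <- glance(ann)
  expect_equal(gl$n_clusters, 3)
  expect_equal(gl$n_cells, 9)
  p <- autoplot(ann)
  expect_s3_class(p, "ggplot")
})

test_that("duplicate gene symbols keep the highest-total row", {
  v <- matrix(c(1, 1, 10, 10, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gA", "gB"), c("c1", "c2")))
  expect_message(x <- expr_matrix(v), "duplicated gene symbol")
  expect_equal(nrow(x$values), 2)
  expect_equal(unname(as.matrix(x)["gA", ]), c(10, 10))
})
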