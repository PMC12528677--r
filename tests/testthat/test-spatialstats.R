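make_cell_table <- function(tx, cy5, cy7) {
  data.frame(label = seq_along(tx), mean_TxRed = tx, mean_Cy5 = cy5,
             mean_Cy7 = cy7)
}

test_that("marker classification picks the most specific class", {
  thr <- c(TxRed = 0.5, Cy5 = 0.5, Cy7 = 0.5)
  rule <- classification_rule(thr)
  tab <- make_cell_table(tx = c(0.1, 0.9, 0.9, 0.1),
                         cy5 = c(0.9, 0.9, 0.9, 0.1),
                         cy7 = c(0.1, 0.1, 0.9, 0.1))
  cl <- classify_cells(tab, rule)
  expect_equal(as.character(cl),
               c("CD45+", "Ly6G+", "DcTRAIL-R1+", "other"))
})

test_that("classification is monotone in thresholds", {
  set.seed(15)
  tab <- make_cell_table(runif(200), runif(200), runif(200))
  lo <- classify_cells(tab, classification_rule(
    c(TxRed = 0.3, Cy5 = 0.3, Cy7 = 0.3)))
  hi <- classify_cells(tab, classification_rule(
    c(TxRed = 0.6, Cy5 = 0.6, Cy7 = 0.6)))
  # the set of cells qualifying for a class (its label or any more
  # specific one) never grows when thresholds rise
  qual <- function(cl, cls) switch(cls,
    "DcTRAIL-R1+" = which(cl == "DcTRAIL-R1+"),
    "Ly6G+" = which(cl %in% c("Ly6G+", "DcTRAIL-R1+")),
    "CD45+" = which(cl != "other"))
  for (cls in c("DcTRAIL-R1+", "Ly6G+", "CD45+")) {
    expect_true(all(qual(hi, cls) %in% qual(lo, cls)))
  }
})

test_that("otsu-based thresholds separate phantom marker populations", {
  ph <- std_phantom()
  mo <- morphometrics(ph$truth$label_mask, ph$fm_channels)
  cl <- classify_cells(mo)
  truth_type <- ph$truth$cells$type[match(mo$label, ph$truth$cells$label)]
  map <- c(tumor = "other", immune = "CD45+", neutrophil = "Ly6G+",
           t3_neutrophil = "DcTRAIL-R1+")
  expect_equal(as.character(cl), unname(map[truth_type]))
})

test_that("standardization centres, scales and drops constants", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(0, 0, 10, 10))
  expect_warning(z <- standardize_features(x), "zero-variance")
  expect_identical(colnames(z), c("a", "c"))
  expect_equal(colMeans(z), c(a = 0, c = 0))
  expect_equal(sqrt(colMeans(z^2)), c(a = 1, c = 1))  # population sd
})

test_that("k-means recovers well-separated blobs", {
  set.seed(16)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30),
             matrix(rnorm(60, -8), 30))
  truth <- rep(1:3, each = 30)
  cl <- cluster_tme(X, k = 3, seed = 4)
  expect_equal(adjusted_rand_index(cl, truth), 1)
  expect_identical(cluster_tme(X, k = 1, seed = 4), rep(1L, 90),
                   ignore_attr = TRUE)
  # duplicated rows land in the same cluster
  cl2 <- cluster_tme(rbind(X, X), k = 3, seed = 4)
  expect_identical(cl2[1:90], cl2[91:180])
  # determinism
  expect_identical(as.integer(cluster_tme(X, k = 3, seed = 4)),
                   as.integer(cluster_tme(X, k = 3, seed = 4)))
})

test_that("silhouette scan reports the k range without deciding", {
  set.seed(17)
  X <- rbind(matrix(rnorm(80, 0, 0.4), 20), matrix(rnorm(80, 5, 0.4), 20))
  sc <- silhouette_scan(X, k_range = 2:4, seed = 1)
  expect_identical(sc$k, 2:4)
  expect_true(which.max(sc$mean_silhouette) == 1)   # k = 2 fits blobs
})

test_that("dbscan matches its definition on constructed cases", {
  # two dense blobs and one outlier
  pts <- rbind(cbind(rep(0:2 / 10, 3), rep(0:2 / 10, each = 3)),
               cbind(5 + rep(0:2 / 10, 3), rep(0:2 / 10, each = 3)),
               c(10, 10))
  lab <- dbscan_cluster(pts, eps = 0.3, min_pts = 5)
  expect_identical(lab[19], 0L)                     # isolated point: noise
  expect_identical(length(unique(lab[1:9])), 1L)
  expect_identical(length(unique(lab[10:18])), 1L)
  expect_true(lab[1] != lab[10])
  # fewer points than min_pts: all noise
  expect_identical(dbscan_cluster(matrix(rnorm(8), 4), 0.5, 7), rep(0L, 4))
})

test_that("umap + dbscan subtyping separates planted profiles", {
  set.seed(18)
  n <- 40; p <- 8
  mu <- matrix(rnorm(4 * p, sd = 4), 4)
  feat <- do.call(rbind, lapply(1:4, function(i)
    matrix(rnorm(n * p, mu[i, ], 0.3), n, byrow = TRUE)))
  st <- subtype_cells(feat, seed = 3)
  expect_equal(adjusted_rand_index(st$labels, rep(1:4, each = n)), 1)
  expect_identical(dim(st$embedding), c(160L, 2L))
  st2 <- subtype_cells(feat, seed = 3)
  expect_identical(st$labels, st2$labels)
  # fewer than min_pts cells: all noise
  tiny <- subtype_cells(feat[1:5, ], seed = 3)
  expect_identical(tiny$labels, rep(0L, 5))
})

test_that("neighborhood counts use edge-to-edge distances", {
  # two 10x10 um square cells with a 10 um edge gap, one far away
  m <- matrix(0L, 60, 120)
  m[20:29, 11:20] <- 1L
  m[20:29, 31:40] <- 2L       # edge gap 10 um at 1 um/px
  m[20:29, 101:110] <- 3L     # >> 15 um from both
  mask <- label_mask(m, 1)
  nb <- neighborhood_counts(mask, radius_um = 15)
  expect_equal(nb$n_neighbors, c(1L, 1L, 0L))
  # centroids are 20 um apart but edges only 10 um: the edge rule counts
  nb5 <- neighborhood_counts(mask, radius_um = 5)
  expect_equal(nb5$n_neighbors, c(0L, 0L, 0L))
})

test_that("neighborhood counts match a brute-force pairwise oracle", {
  ph <- std_phantom()
  mask <- ph$truth$label_mask
  nb <- neighborhood_counts(mask, radius_um = 15)
  b <- mask_boundaries(mask)
  bl <- split(seq_len(nrow(b)), b$label)
  labs <- sort(unique(b$label))
  oracle <- vapply(labs, function(i) {
    bi <- cbind(b$x_um[bl[[as.character(i)]]], b$y_um[bl[[as.character(i)]]])
    sum(vapply(setdiff(labs, i), function(j) {
      bj <- cbind(b$x_um[bl[[as.character(j)]]], b$y_um[bl[[as.character(j)]]])
      dmin <- min(sqrt(outer(rowSums(bi^2), rowSums(bj^2), "+") -
                         2 * bi %*% t(bj)))
      dmin <= 15
    }, logical(1)))
  }, integer(1))
  expect_equal(nb$n_neighbors, oracle)
  # symmetry: total pairwise count is even
  expect_identical(sum(nb$n_neighbors) %% 2L, 0L)
})

test_that("lattice neighbor counts follow the closed form", {
  # 5x5 lattice of 6x6 um squares at 20 um pitch: edge gap 14 um, so
  # every 4-neighbour pair counts at radius 15, diagonals do not
  m <- matrix(0L, 120, 120)
  lab <- 0L
  for (i in 0:4) for (j in 0:4) {
    lab <- lab + 1L
    m[i * 20 + 8:13, j * 20 + 8:13] <- lab
  }
  nb <- neighborhood_counts(label_mask(m, 1), radius_um = 15)
  inner_of <- function(i, j) (i >= 1 && i <= 3) && (j >= 1 && j <= 3)
  expected <- integer(0)
  for (i in 0:4) for (j in 0:4) {
    expected <- c(expected, sum(c(i > 0, i < 4, j > 0, j < 4)))
  }
  expect_equal(nb$n_neighbors, expected)
})

test_that("TME assignment takes the modal label with nearest tie-break", {
  # subject cell 1 surrounded by reference cells 2..4
  m <- matrix(0L, 50, 50)
  m[23:27, 23:27] <- 1L
  m[23:27, 3:7] <- 2L      # left, edge distance 15
  m[23:27, 43:47] <- 3L    # right, edge distance 15
  m[3:7, 23:27] <- 4L      # above, edge distance 15
  mask <- label_mask(m, 1)
  # all neighbors share a label
  expect_identical(assign_tme(mask, 1L, c(`2` = 3L, `3` = 3L, `4` = 3L), 40),
                   c(`1` = 3L))
  # majority vote
  expect_identical(assign_tme(mask, 1L, c(`2` = 1L, `3` = 1L, `4` = 2L), 40),
                   c(`1` = 1L))
  # tie between I and II: nearest neighbor decides
  m2 <- m; m2[23:27, 8:12] <- 5L           # another left cell, closer (gap 10)
  mask2 <- label_mask(m2, 1)
  out <- assign_tme(mask2, 1L, c(`2` = 1L, `3` = 2L, `5` = 2L, `4` = 9L), 40)
  # labels {1, 2, 2, 9}: 2 wins outright; restrict to a true tie
  out2 <- assign_tme(mask2, 1L, c(`3` = 1L, `5` = 2L), 40)
  expect_identical(out2, c(`1` = 2L))      # 5 is nearer than 3
  # no neighbors in radius: unassigned
  expect_true(is.na(assign_tme(mask, 1L, c(`2` = 1L), 5)[["1"]]))
})

test_that("summary matrix conserves counts and keeps empty rows", {
  subtypes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 3L)
  tme <- c(`1` = 1L, `2` = 2L, `3` = 1L, `4` = NA)
  classes <- factor(c(`1` = "Ly6G+", `2` = "DcTRAIL-R1+", `3` = "Ly6G+",
                      `4` = "Ly6G+", `5` = "CD45+", `6` = "other"))
  ref_tme <- c(`5` = 1L, `6` = 2L)
  sm <- summary_matrix(subtypes, tme, classes, ref_tme)
  expect_equal(sum(sm$counts), sum(!is.na(tme)))
  expect_true("subtype_3" %in% rownames(sm$counts))
  expect_equal(sum(sm$counts["subtype_3", ]), 0)   # unassigned: zero row
  expect_equal(unname(sm$pct_dctrail_by_subtype["subtype_1"]), 50)
  expect_equal(unname(sm$class_totals_by_tme["TME_1", "CD45+"]), 1)
})

test_that("planted subtype-TME association concentrates the matrix", {
  set.seed(19)
  # subtypes 1 and 2 planted in TMEs 10 and 20 respectively
  subtypes <- stats::setNames(rep(c(1L, 2L), each = 20), 1:40)
  tme <- stats::setNames(rep(c(10L, 20L), each = 20), 1:40)
  classes <- factor(stats::setNames(rep("Ly6G+", 40), 1:40))
  sm <- summary_matrix(subtypes, tme, classes, integer(0))
  expect_equal(sm$counts["subtype_1", "TME_10"], 20)
  expect_equal(sm$counts["subtype_2", "TME_20"], 20)
  expect_equal(sm$counts["subtype_1", "TME_20"], 0)
})

test_that("profile similarity is 1 on identical profiles", {
  p <- matrix(runif(12), 3)
  s <- profile_similarity(p, p)
  expect_equal(diag(s), rep(1, 3))
  expect_true(all(s <= 1 + 1e-12))
})
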