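#' Spatial single-cell statistics
#'
#' Marker-based immune classification, k-means clustering of tissue
#' microenvironments (TMEs) on Ly6G-negative cells, UMAP + DBSCAN
#' subtyping of Ly6G-positive neutrophils, edge-distance neighborhood
#' counts, modal TME assignment, and the subtype-by-TME summary
#' matrix.
#'
#' @name spatialstats
NULL

#' Marker classification rule
#'
#' The marker logic of the stained tumor section: CD45+ cells are high
#' in Cy5; Ly6G+ neutrophils are high in TxRed and Cy5; DcTRAIL-R1+
#' (T3) neutrophils are high in TxRed, Cy5 and Cy7. Classes are
#' nested, and each cell receives the most specific matching class.
#'
#' @param thresholds named numeric vector of per-channel "high"
#'   thresholds, or `NULL` to derive each by Otsu over all cells.
#' @export
classification_rule <- function(thresholds = NULL) {
  structure(list(
    classes = list(
      "DcTRAIL-R1+" = c("TxRed", "Cy5", "Cy7"),
      "Ly6G+"       = c("TxRed", "Cy5"),
      "CD45+"       = c("Cy5")),
    thresholds = thresholds), class = "classification_rule")
}

#' Classify cells by thresholding channel mean intensities
#'
#' @param cell_table data.frame with per-cell channel means in columns
#'   `mean_<channel>`.
#' @param rule a [classification_rule()]. Missing thresholds default
#'   to an Otsu split of the per-cell means of that channel.
#' @return factor of class labels (`"other"` for cells matching no
#'   class), ordered most specific first in the levels.
#' @export
classify_cells <- function(cell_table, rule = classification_rule()) {
  chans <- unique(unlist(rule$classes))
  cols <- paste0("mean_", chans)
  miss <- cols[!cols %in% names(cell_table)]
  if (length(miss)) stop("cell table lacks channel means: ",
                         paste(miss, collapse = ", "))
  thr <- rule$thresholds
  if (is.null(thr)) thr <- stats::setNames(numeric(0), character(0))
  high <- sapply(chans, function(ch) {
    v <- cell_table[[paste0("mean_", ch)]]
    t <- if (ch %in% names(thr)) thr[[ch]] else otsu_threshold(v)
    v > t
  })
  high <- matrix(high, nrow = nrow(cell_table),
                 dimnames = list(NULL, chans))
  lab <- rep("other", nrow(cell_table))
  for (cl in rev(names(rule$classes))) {   # least specific first,
    req <- rule$classes[[cl]]              # most specific overwrites
    lab[rowSums(high[, req, drop = FALSE]) == length(req)] <- cl
  }
  factor(lab, levels = c(names(rule$classes), "other"))
}

#' Z-score standardization of a feature matrix
#'
#' Per-feature centring and scaling by the population (n) standard
#' deviation; zero-variance features are dropped with a warning.
#'
#' @param x numeric matrix (cells x features).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_n <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sd_n > 0
  if (!all(keep))
    warning("dropping zero-variance features: ",
            paste(colnames(x)[!keep], collapse = ", "))
  sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_n[keep], "/")
}

#' Cluster tissue microenvironments by k-means
#'
#' k-means on the standardized per-cell species intensities of the
#' Ly6G-negative cells. k defaults to 8; [silhouette_scan()] reports
#' the silhouette profile over the 6-10 scan range without making the
#' choice.
#'
#' @param features cells x species matrix (raw; standardized
#'   internally unless `standardize = FALSE`).
#' @param k number of clusters.
#' @param seed RNG seed (k-means starts are stochastic).
#' @param nstart independent k-means starts.
#' @param standardize apply [standardize_features()] first.
#' @return integer cluster labels (1..k) with the fitted
#'   `stats::kmeans` object in attribute `"fit"`.
#' @export
cluster_tme <- function(features, k = 8, seed = 1L, nstart = 10,
                        standardize = TRUE) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  x <- if (standardize) standardize_features(features) else as.matrix(features)
  if (k == 1)
    return(structure(rep(1L, nrow(x)), fit = NULL))
  fit <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  structure(as.integer(fit$cluster), fit = fit)
}

#' Mean silhouette width over a range of k
#' @param features cells x species matrix.
#' @param k_range candidate cluster numbers (default 6:10).
#' @inheritParams cluster_tme
#' @return data.frame `k`, `mean_silhouette`.
#' @export
silhouette_scan <- function(features, k_range = 6:10, seed = 1L,
                            standardize = TRUE) {
  x <- if (standardize) standardize_features(features) else as.matrix(features)
  d <- stats::dist(x)
  data.frame(k = k_range, mean_silhouette = vapply(k_range, function(k) {
    cl <- cluster_tme(x, k = k, seed = seed, standardize = FALSE)
    mean(cluster::silhouette(as.integer(cl), d)[, 3])
  }, numeric(1)))
}

#' DBSCAN clustering
#'
#' Density-based clustering: core points have at least `min_pts`
#' points (including themselves) within `eps`; clusters are the
#' connected components of core points plus their border points;
#' everything else is noise (label 0).
#'
#' @param x n x d numeric matrix.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size of a core point.
#' @return integer labels, 0 = noise.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Subtype cells by DBSCAN on a UMAP embedding
#'
#' The standardized per-cell species profiles are embedded in 2-D by
#' UMAP (default parameters, seeded) and clustered by DBSCAN with
#' eps = 0.7 and a minimum of seven neighbors. Cells in no dense
#' region are labelled noise (0). Fewer than `min_pts` cells are all
#' noise by construction.
#'
#' @param features cells x species matrix.
#' @param eps DBSCAN radius in embedding units (default 0.7).
#' @param min_pts DBSCAN minimum neighborhood size (default 7).
#' @param seed RNG seed fixing the embedding.
#' @param standardize apply [standardize_features()] first.
#' @return list(`labels` = integer subtype labels (0 = noise),
#'   `embedding` = n x 2 UMAP coordinates).
#' @export
subtype_cells <- function(features, eps = 0.7, min_pts = 7, seed = 1L,
                          standardize = TRUE) {
  x <- if (standardize) standardize_features(features) else as.matrix(features)
  n <- nrow(x)
  if (n < min_pts)
    return(list(labels = integer(n), embedding = matrix(NA_real_, n, 2)))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  emb <- uwot::umap(x, n_neighbors = min(15, n - 1), n_threads = 1,
                    batch = TRUE)
  list(labels = dbscan_cluster(emb, eps = eps, min_pts = min_pts),
       embedding = emb)
}

#' Edge-to-edge neighborhood counts
#'
#' For every cell, the number of other cells whose mask lies within
#' `radius_um` of the cell's boundary (minimum boundary-to-boundary
#' distance at most the radius), in total and per class.
#'
#' @param mask a [label_mask()] in a metric frame.
#' @param classes factor/character of class per label (named by label,
#'   or in label order).
#' @param radius_um neighborhood radius (default 15).
#' @return data.frame `label`, `n_neighbors`, and `n_<class>` columns.
#' @export
neighborhood_counts <- function(mask, classes = NULL, radius_um = 15) {
  b <- mask_boundaries(mask)
  labs <- sort(unique(b$label))
  nl <- length(labs)
  if (!is.null(classes) && is.null(names(classes)))
    names(classes) <- labs
  adj <- neighbor_pairs(b, labs, radius_um)
  out <- data.frame(label = labs,
                    n_neighbors = vapply(seq_len(nl), function(i)
                      length(adj[[i]]), integer(1)))
  if (!is.null(classes)) {
    cls <- as.character(classes[as.character(labs)])
    for (cl in sort(unique(cls))) {
      out[[paste0("n_", cl)]] <- vapply(seq_len(nl), function(i)
        sum(cls[adj[[i]]] == cl), integer(1))
    }
  }
  out
}

# minimum boundary-to-boundary distances, with centroid/radius pruning
neighbor_pairs <- function(boundaries, labs, radius_um) {
  nl <- length(labs)
  bl <- split(seq_len(nrow(boundaries)), match(boundaries$label, labs))
  cx <- vapply(bl, function(i) mean(boundaries$x_um[i]), numeric(1))
  cy <- vapply(bl, function(i) mean(boundaries$y_um[i]), numeric(1))
  rmax <- vapply(seq_len(nl), function(i)
    max(sqrt((boundaries$x_um[bl[[i]]] - cx[i])^2 +
             (boundaries$y_um[bl[[i]]] - cy[i])^2)), numeric(1))
  adj <- rep(list(integer(0)), nl)
  for (i in seq_len(nl)) {
    for (j in seq_len(nl)) {
      if (j <= i) next
      dc <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      if (dc - rmax[i] - rmax[j] > radius_um) next
      bi <- bl[[i]]; bj <- bl[[j]]
      dmin <- min(cross_dist(cbind(boundaries$x_um[bi], boundaries$y_um[bi]),
                             cbind(boundaries$x_um[bj], boundaries$y_um[bj])))
      if (dmin <= radius_um) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  adj
}

#' Assign subject cells to tissue microenvironments
#'
#' Each subject cell receives the most frequent TME label among the
#' reference cells whose masks lie within `radius_um` (edge-to-edge)
#' of it; ties are broken by the label of the nearest neighbor; cells
#' with no neighbor in range stay unassigned (NA).
#'
#' @param mask a [label_mask()] holding both subject and reference
#'   cells.
#' @param subject_labels labels of the cells to assign (e.g. Ly6G+).
#' @param tme_labels named integer vector: TME cluster per reference
#'   cell label.
#' @param radius_um assignment radius (default 40).
#' @return named integer vector: TME per subject label (NA when
#'   unassigned).
#' @export
assign_tme <- function(mask, subject_labels, tme_labels, radius_um = 40) {
  b <- mask_boundaries(mask)
  ref_labels <- as.integer(names(tme_labels))
  out <- stats::setNames(rep(NA_integer_, length(subject_labels)),
                         subject_labels)
  bl <- split(seq_len(nrow(b)), b$label)
  for (s in subject_labels) {
    bs <- bl[[as.character(s)]]
    if (is.null(bs)) next
    ps <- cbind(b$x_um[bs], b$y_um[bs])
    dmin <- vapply(ref_labels, function(r) {
      br <- bl[[as.character(r)]]
      if (is.null(br) || r == s) return(Inf)
      min(cross_dist(ps, cbind(b$x_um[br], b$y_um[br])))
    }, numeric(1))
    inr <- dmin <= radius_um
    if (!any(inr)) next
    votes <- table(tme_labels[inr])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) out[as.character(s)] <- as.integer(top)
    else {
      cand <- which(inr & as.character(tme_labels) %in% top)
      out[as.character(s)] <- as.integer(
        tme_labels[cand[which.min(dmin[cand])]])
    }
  }
  out
}

#' Subtype-by-TME summary matrix
#'
#' Tabulates neutrophil subtypes across tissue regions: subtype x TME
#' counts (zero rows/columns retained), the percentage of DcTRAIL-R1+
#' cells per subtype, mean neighborhood counts per subtype, and
#' per-TME totals of each immune class.
#'
#' @param subtypes named integer vector: subtype per Ly6G+ cell label.
#' @param tme_of_subject named integer vector from [assign_tme()].
#' @param classes named factor/character: immune class per cell label
#'   (all cells).
#' @param tme_of_reference named integer vector: TME per Ly6G- cell
#'   label.
#' @param neighborhood optional data.frame from
#'   [neighborhood_counts()].
#' @return list(`counts` = subtype x TME matrix,
#'   `pct_dctrail_by_subtype`, `mean_neighbors_by_subtype`,
#'   `class_totals_by_tme`).
#' @export
summary_matrix <- function(subtypes, tme_of_subject, classes,
                           tme_of_reference, neighborhood = NULL) {
  st_levels <- sort(unique(subtypes))
  tme_levels <- sort(unique(c(tme_of_subject, tme_of_reference)))
  tme_levels <- tme_levels[!is.na(tme_levels)]
  counts <- matrix(0L, length(st_levels), length(tme_levels),
                   dimnames = list(paste0("subtype_", st_levels),
                                   paste0("TME_", tme_levels)))
  common <- intersect(names(subtypes), names(tme_of_subject))
  for (lb in common) {
    tm <- tme_of_subject[[lb]]
    if (is.na(tm)) next
    counts[match(subtypes[[lb]], st_levels), match(tm, tme_levels)] <-
      counts[match(subtypes[[lb]], st_levels), match(tm, tme_levels)] + 1L
  }
  pct_dctrail <- vapply(st_levels, function(s) {
    lbs <- names(subtypes)[subtypes == s]
    if (!length(lbs)) return(NA_real_)
    100 * mean(classes[lbs] == "DcTRAIL-R1+")
  }, numeric(1))
  names(pct_dctrail) <- paste0("subtype_", st_levels)
  mean_nb <- NULL
  if (!is.null(neighborhood)) {
    ncols <- setdiff(names(neighborhood), "label")
    mean_nb <- do.call(rbind, lapply(st_levels, function(s) {
      lbs <- as.integer(names(subtypes)[subtypes == s])
      colMeans(neighborhood[neighborhood$label %in% lbs, ncols,
                            drop = FALSE])
    }))
    rownames(mean_nb) <- paste0("subtype_", st_levels)
  }
  class_levels <- sort(unique(as.character(classes)))
  class_totals <- do.call(rbind, lapply(tme_levels, function(tm) {
    lbs <- c(names(tme_of_reference)[!is.na(tme_of_reference) &
                                       tme_of_reference == tm],
             names(tme_of_subject)[!is.na(tme_of_subject) &
                                     tme_of_subject == tm])
    tab <- table(factor(as.character(classes[lbs]), levels = class_levels))
    c(total = length(lbs), as.integer(tab))
  }))
  colnames(class_totals) <- c("total", class_levels)
  rownames(class_totals) <- paste0("TME_", tme_levels)
  list(counts = counts, pct_dctrail_by_subtype = pct_dctrail,
       mean_neighbors_by_subtype = mean_nb,
       class_totals_by_tme = class_totals)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement measure used to compare recovered
#' cluster labels with planted partitions.
#'
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}

#' Cosine similarity between profile matrices
#'
#' Generic profile-similarity report (e.g. subtype vs TME mean
#' profiles).
#'
#' @param a,b matrices with profiles in rows and the same columns.
#' @return matrix of cosine similarities, rows of `a` x rows of `b`.
#' @export
profile_similarity <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- sqrt(rowSums(a^2)); bn <- sqrt(rowSums(b^2))
  (a %*% t(b)) / outer(pmax(an, 1e-12), pmax(bn, 1e-12))
}
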