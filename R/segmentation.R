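#' Cell and subcellular masks
#'
#' The pipeline normally ingests label masks produced by an external
#' deep-learning segmenter. For phantoms and model-free use a classical
#' fallback segmenter is provided: nuclei are thresholded and labelled
#' as seeds, then labels are propagated into the membrane/cytoplasm
#' signal (seeded region growing bounded by a global threshold, with
#' watershed-like division lines between touching cells). A minimal
#' set of morphometric measurements feeds downstream analysis.
#'
#' @name segmentation
NULL

#' Otsu threshold of an intensity vector or image
#' @param x numeric values.
#' @param levels histogram resolution.
#' @export
otsu_threshold <- function(x, levels = 256) {
  x <- as.numeric(x)
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(r[1])
  brk <- seq(r[1], r[2], length.out = levels + 1)
  h <- as.numeric(tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                           nbins = levels))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  wt <- w[levels]; mt <- m[levels]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- 0
  # the criterion plateaus over empty histogram gaps; take the
  # plateau midpoint so the threshold sits between the modes
  mx <- max(between)
  mean(mids[between >= mx * (1 - 1e-12)])
}

#' Classical fallback cell segmentation
#'
#' @param nuclei_channel nuclear-stain image (e.g. DAPI).
#' @param membrane_channel cytoplasm/membrane image (e.g. FITC) on the
#'   same grid.
#' @param nuclei_threshold,membrane_threshold numeric thresholds or
#'   `"otsu"` (default) for a parameter-free global threshold.
#' @param min_seed_px discard nucleus seeds smaller than this.
#' @return a [label_mask()] in the frame of the input channels. A blank
#'   nuclei channel yields an empty (all-zero) mask.
#' @export
fallback_segment <- function(nuclei_channel, membrane_channel,
                             nuclei_threshold = "otsu",
                             membrane_threshold = "otsu",
                             min_seed_px = 9) {
  stopifnot(all(dim(nuclei_channel) == dim(membrane_channel)))
  nt <- if (identical(nuclei_threshold, "otsu"))
    otsu_threshold(nuclei_channel) else nuclei_threshold
  seeds_bin <- nuclei_channel > nt
  if (!any(seeds_bin))
    return(label_mask(matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                      pixel_size(nuclei_channel), attr(nuclei_channel, "frame")))
  # EBImage works on [x, y] arrays; transpose in and out
  seeds <- EBImage::bwlabel(t(seeds_bin))
  sizes <- tabulate(seeds[seeds > 0])
  kill <- which(sizes < min_seed_px)
  if (length(kill)) seeds[seeds %in% kill] <- 0L
  mt <- if (identical(membrane_threshold, "otsu"))
    otsu_threshold(membrane_channel) else membrane_threshold
  body <- t(membrane_channel > mt) | seeds > 0
  lab <- EBImage::propagate(t(membrane_channel), seeds, mask = body)
  out <- t(as.matrix(lab))
  # relabel compactly and deterministically
  u <- sort(unique(out[out > 0]))
  out <- matrix(match(out, u, nomatch = 0L), nrow(out), ncol(out))
  out[is.na(out)] <- 0L
  label_mask(out, pixel_size(nuclei_channel), attr(nuclei_channel, "frame"))
}

#' Subcellular feature mask by intensity thresholding
#'
#' Supra-threshold regions of a single channel (e.g. the pHrodo signal
#' of acidified phagolysosomes) are labelled as subcellular features.
#'
#' @param channel single-channel image.
#' @param threshold_rule numeric threshold or `"otsu"`.
#' @return a [label_mask()]; empty when nothing is above threshold.
#' @export
subcellular_mask <- function(channel, threshold_rule = "otsu") {
  thr <- if (identical(threshold_rule, "otsu"))
    otsu_threshold(channel) else threshold_rule
  bin <- channel > thr
  if (!any(bin))
    return(label_mask(matrix(0L, nrow(channel), ncol(channel)),
                      pixel_size(channel), attr(channel, "frame")))
  lab <- t(as.matrix(EBImage::bwlabel(t(bin))))
  label_mask(lab, pixel_size(channel), attr(channel, "frame"))
}

#' Complement of a subcellular mask within each parent cell
#'
#' The "remaining cell" region: pixels of each labelled cell not
#' covered by the feature mask.
#'
#' @param cell_mask parent-cell [label_mask()].
#' @param feature_mask subcellular [label_mask()] on the same grid.
#' @export
remaining_cell_mask <- function(cell_mask, feature_mask) {
  stopifnot(all(dim(cell_mask) == dim(feature_mask)))
  out <- unclass(cell_mask)
  out[feature_mask > 0] <- 0L
  label_mask(out, pixel_size(cell_mask), attr(cell_mask, "frame"))
}

#' Morphometric measurements per labelled cell
#'
#' Area, perimeter (length of the 4-adjacent boundary between the cell
#' and anything else, in micrometres), eccentricity of the
#' second-moment ellipse, centroid, and mean intensity in each supplied
#' channel.
#'
#' @param mask a [label_mask()].
#' @param channels named list of images on the same grid.
#' @return data.frame with one row per label, columns `label`,
#'   `area_um2`, `perimeter_um`, `eccentricity`, `centroid_x_um`,
#'   `centroid_y_um`, and `mean_<channel>` per channel.
#' @export
morphometrics <- function(mask, channels = list()) {
  px <- pixel_size(mask)
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    out <- data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), eccentricity = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric())
    for (nm in names(channels)) out[[paste0("mean_", nm)]] <- numeric()
    return(out)
  }
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m > 0)
  lab_of <- m[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  g <- match(lab_of, labs)
  n_px <- tabulate(g, length(labs))
  x <- (cc - 0.5) * px; y <- (rr - 0.5) * px
  cx <- rowsum(x, g)[, 1] / n_px
  cy <- rowsum(y, g)[, 1] / n_px
  # central second moments
  dx <- x - cx[g]; dy <- y - cy[g]
  mxx <- rowsum(dx * dx, g)[, 1] / n_px
  myy <- rowsum(dy * dy, g)[, 1] / n_px
  mxy <- rowsum(dx * dy, g)[, 1] / n_px
  tr <- mxx + myy; dt <- sqrt(pmax(0, (mxx - myy)^2 + 4 * mxy^2))
  l1 <- (tr + dt) / 2; l2 <- pmax((tr - dt) / 2, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  # perimeter: count exposed 4-neighbour faces
  pad <- matrix(0L, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- m
  pidx <- (cc) * (nr + 2) + rr + 1L      # position of (rr, cc) inside pad
  expo <- (pad[pidx - 1L] != lab_of) + (pad[pidx + 1L] != lab_of) +
          (pad[pidx - (nr + 2L)] != lab_of) + (pad[pidx + (nr + 2L)] != lab_of)
  perim <- rowsum(as.numeric(expo), g)[, 1] * px
  out <- data.frame(label = labs, area_um2 = n_px * px^2,
                    perimeter_um = perim, eccentricity = ecc,
                    centroid_x_um = cx, centroid_y_um = cy)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    stopifnot(all(dim(ch) == dim(m)))
    out[[paste0("mean_", nm)]] <- rowsum(as.numeric(ch)[idx], g)[, 1] / n_px
  }
  rownames(out) <- NULL
  out
}

#' Boundary pixels of every label (4-adjacency)
#'
#' A mask pixel is a boundary pixel when one of its 4-neighbours
#' carries a different label or background. Used for edge-to-edge
#' neighborhood distances.
#'
#' @param mask a [label_mask()].
#' @return data.frame `label`, `x_um`, `y_um` of boundary pixel
#'   centres.
#' @export
mask_boundaries <- function(mask) {
  px <- pixel_size(mask)
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- m
  idx <- which(m > 0)
  lab_of <- m[idx]
  rr <- ((idx - 1L) %% nr) + 1L; cc <- ((idx - 1L) %/% nr) + 1L
  pidx <- (cc) * (nr + 2) + rr + 1L
  is_b <- pad[pidx - 1L] != lab_of | pad[pidx + 1L] != lab_of |
          pad[pidx - (nr + 2L)] != lab_of | pad[pidx + (nr + 2L)] != lab_of
  data.frame(label = lab_of[is_b], x_um = (cc[is_b] - 0.5) * px,
             y_um = (rr[is_b] - 0.5) * px)
}
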