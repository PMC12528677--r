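#' Single-cell and subcellular spectrum compilation
#'
#' Cell masks (segmented on the fine fluorescence grid) are projected
#' through the global registration transform onto the MSI grid; each
#' MSI pixel is apportioned to cells by the geometric area fraction it
#' shares with each mask ("hit coverage"), per-cell spectra are
#' compiled as coverage-weighted intensity sums, normalized to the
#' per-cell total, and region masks are compared by log2 fold change.
#'
#' @name singlecell
NULL

#' Project cell masks onto the MSI grid
#'
#' Every MSI pixel is supersampled at the mask's (fluorescence)
#' resolution; each subsample centre is mapped through `transform`
#' into the mask frame and assigned the label found there. The area
#' fraction of the pixel covered by each label is returned. Fractions
#' per pixel sum to at most 1; the remainder is background and stays
#' unassigned.
#'
#' @param mask a [label_mask()] in the mask (moving) frame.
#' @param transform [affine2d()] mapping MSI-frame coordinates to
#'   mask-frame coordinates.
#' @param msi_grid list(`dims` = c(nrow, ncol), `pixel_size_um`) of the
#'   MSI raster.
#' @param supersample subsamples per axis; defaults to the
#'   MSI-to-mask pixel size ratio.
#' @return data.frame `px`, `py`, `label`, `fraction` (one row per
#'   pixel-label pair with fraction > 0). Emits a warning and returns
#'   an empty map when the grids do not overlap.
#' @export
project_masks <- function(mask, transform, msi_grid,
                          supersample = NULL) {
  mpx <- msi_grid$pixel_size_um
  fpx <- pixel_size(mask)
  if (fpx > mpx + 1e-9)
    stop("mask pixels must be at least as fine as MSI pixels")
  ss <- if (is.null(supersample)) max(1L, round(mpx / fpx)) else as.integer(supersample)
  d <- msi_grid$dims
  g <- expand.grid(py = seq_len(d[1]), px = seq_len(d[2]))
  off <- (seq_len(ss) - 0.5) / ss
  sub <- expand.grid(oy = off, ox = off)
  n_px <- nrow(g); n_sub <- nrow(sub)
  sx <- rep((g$px - 1) * mpx, each = n_sub) + rep(sub$ox, n_px) * mpx
  sy <- rep((g$py - 1) * mpx, each = n_sub) + rep(sub$oy, n_px) * mpx
  pts <- affine_apply(transform, cbind(sx, sy))
  cc <- floor(pts[, 1] / fpx) + 1L
  rr <- floor(pts[, 2] / fpx) + 1L
  ok <- cc >= 1 & cc <= ncol(mask) & rr >= 1 & rr <= nrow(mask)
  lab <- integer(length(cc))
  lab[ok] <- unclass(mask)[(cc[ok] - 1L) * nrow(mask) + rr[ok]]
  if (!any(ok)) {
    warning("project_masks: MSI grid and mask do not overlap")
    return(data.frame(px = integer(), py = integer(), label = integer(),
                      fraction = numeric()))
  }
  pix_of_sub <- rep(seq_len(n_px), each = n_sub)
  keep <- lab > 0
  if (!any(keep))
    return(data.frame(px = integer(), py = integer(), label = integer(),
                      fraction = numeric()))
  key <- paste(pix_of_sub[keep], lab[keep])
  cnt <- rowsum(rep(1, sum(keep)), key)
  parts <- strsplit(rownames(cnt), " ", fixed = TRUE)
  pixi <- as.integer(vapply(parts, `[[`, "", 1))
  out <- data.frame(px = g$px[pixi], py = g$py[pixi],
                    label = as.integer(vapply(parts, `[[`, "", 2)),
                    fraction = cnt[, 1] / n_sub)
  out <- out[order(out$px, out$py, out$label), ]
  rownames(out) <- NULL
  out
}

#' Per-pixel species intensities of an MSI dataset
#'
#' Peaks are matched to the target m/z of each species within the
#' accurate-mass window and summed per (pixel, species).
#'
#' @param msi an [msi_dataset()].
#' @param species data.frame with columns `species` and `mz` (target
#'   m/z values).
#' @param tolerance_ppm matching window.
#' @return data.frame `px`, `py`, `species`, `intensity`.
#' @export
pixel_species_intensity <- function(msi, species, tolerance_ppm = 3) {
  pk <- msi$peaks
  if (!nrow(pk))
    return(data.frame(px = integer(), py = integer(),
                      species = character(), intensity = numeric()))
  o <- order(species$mz)
  smz <- species$mz[o]; snm <- species$species[o]
  i <- findInterval(pk$mz, smz)
  cand_lo <- pmax(i, 1L); cand_hi <- pmin(i + 1L, length(smz))
  d_lo <- abs(pk$mz - smz[cand_lo]); d_hi <- abs(pk$mz - smz[cand_hi])
  best <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
  ppm <- abs(pk$mz - smz[best]) / smz[best] * 1e6
  keep <- ppm < tolerance_ppm
  if (!any(keep))
    return(data.frame(px = integer(), py = integer(),
                      species = character(), intensity = numeric()))
  pk <- pk[keep, ]; sp <- snm[best[keep]]
  agg <- rowsum(pk$intensity, paste(pk$px, pk$py, sp, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(px = as.integer(vapply(parts, `[[`, "", 1)),
             py = as.integer(vapply(parts, `[[`, "", 2)),
             species = vapply(parts, `[[`, "", 3),
             intensity = agg[, 1])
}

#' Compile per-cell spectra from a coverage map
#'
#' The intensity of species s in cell k is the coverage-weighted sum
#' over MSI pixels: `sum_p fraction(k, p) * I(p, s)`. Pixels shared
#' between cells contribute proportionally to each ("scaled according
#' to the hit coverage"), so total assigned intensity never exceeds
#' the pixel total and intensity is conserved exactly.
#'
#' @param msi an [msi_dataset()].
#' @param coverage data.frame from [project_masks()].
#' @param species data.frame (`species`, `mz`).
#' @param tolerance_ppm accurate-mass window for peak-to-species
#'   matching.
#' @return data.frame: `label`, `n_pixels` (sum of fractions), one
#'   intensity column per species, and `flag_empty` for cells with no
#'   covered signal.
#' @export
compile_spectra <- function(msi, coverage, species, tolerance_ppm = 3) {
  labs <- sort(unique(coverage$label))
  psi <- pixel_species_intensity(msi, species, tolerance_ppm)
  out <- data.frame(label = labs)
  out$n_pixels <- rowsum(coverage$fraction,
                         match(coverage$label, labs))[, 1]
  M <- matrix(0, length(labs), nrow(species),
              dimnames = list(NULL, species$species))
  if (nrow(psi) && nrow(coverage)) {
    key_cov <- paste(coverage$px, coverage$py)
    key_psi <- paste(psi$px, psi$py)
    # join coverage rows with all species rows of the same pixel
    psi_by_pix <- split(seq_len(nrow(psi)), key_psi)
    hit <- key_cov %in% names(psi_by_pix)
    for (ci in which(hit)) {
      rows <- psi_by_pix[[key_cov[ci]]]
      li <- match(coverage$label[ci], labs)
      M[li, psi$species[rows]] <- M[li, psi$species[rows]] +
        coverage$fraction[ci] * psi$intensity[rows]
    }
  }
  out <- cbind(out, as.data.frame(M))
  out$flag_empty <- rowSums(M) == 0
  out
}

#' Normalize per-cell spectra to the per-cell total
#'
#' Each species intensity is divided by the cell's summed intensity
#' over `species_list`; all-zero cells are flagged and left
#' unnormalized. Idempotent on already-normalized rows.
#'
#' @param table a [compile_spectra()] table.
#' @param species_list character vector of species columns to
#'   normalize over (default: all species columns present).
#' @export
normalize_cells <- function(table, species_list = NULL) {
  if (is.null(species_list))
    species_list <- setdiff(names(table),
                            c("label", "n_pixels", "flag_empty"))
  stopifnot(length(species_list) > 0, all(species_list %in% names(table)))
  tot <- rowSums(as.matrix(table[, species_list, drop = FALSE]))
  ok <- tot > 0
  table[ok, species_list] <- table[ok, species_list, drop = FALSE] / tot[ok]
  table$flag_empty <- !ok
  table
}

#' Region comparison by log2 fold change
#'
#' Mean per-pixel intensity of every species in region A and region B
#' (pixels without signal for a species count as zero), with
#' `log2((A + eps) / (B + eps))`; species above the marker threshold
#' are flagged.
#'
#' @param msi an [msi_dataset()].
#' @param mask_A,mask_B disjoint binary/label masks on the MSI grid
#'   (any value > 0 marks the region).
#' @param species data.frame (`species`, `mz`).
#' @param pseudocount epsilon; defaults to the smallest nonzero region
#'   mean across species.
#' @param fc_threshold marker threshold on the log2 fold change
#'   (default 2.8).
#' @param tolerance_ppm accurate-mass window.
#' @return data.frame `species`, `mean_A`, `mean_B`, `log2fc`,
#'   `flagged`.
#' @export
region_compare <- function(msi, mask_A, mask_B, species,
                           pseudocount = NULL, fc_threshold = 2.8,
                           tolerance_ppm = 3) {
  stopifnot(all(dim(mask_A) == msi$dims), all(dim(mask_B) == msi$dims))
  if (any(mask_A > 0 & mask_B > 0)) stop("region masks must be disjoint")
  psi <- pixel_species_intensity(msi, species, tolerance_ppm)
  region_mean <- function(mask) {
    n <- sum(mask > 0)
    means <- stats::setNames(numeric(nrow(species)), species$species)
    if (n == 0 || !nrow(psi)) return(means)
    inreg <- unclass(mask)[(psi$px - 1L) * msi$dims[1] + psi$py] > 0
    if (any(inreg)) {
      s <- rowsum(psi$intensity[inreg], psi$species[inreg])
      means[rownames(s)] <- s[, 1] / n
    }
    means
  }
  mA <- region_mean(mask_A); mB <- region_mean(mask_B)
  if (is.null(pseudocount)) {
    nzmeans <- c(mA[mA > 0], mB[mB > 0])
    pseudocount <- if (length(nzmeans)) min(nzmeans) else 1
  }
  l2 <- log2((mA + pseudocount) / (mB + pseudocount))
  data.frame(species = species$species, mean_A = as.numeric(mA),
             mean_B = as.numeric(mB), log2fc = as.numeric(l2),
             flagged = as.numeric(l2) > fc_threshold)
}
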