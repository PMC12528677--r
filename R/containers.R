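#' Image and MSI containers
#'
#' Images are numeric matrices indexed `[row, col]` with the row axis
#' pointing down (y) and the column axis pointing right (x). The pixel
#' with 1-based index (r, c) has its centre at
#' `x = (c - 0.5) * pixel_size_um`, `y = (r - 0.5) * pixel_size_um`
#' in the image's frame. All physical coordinates are micrometres.
#'
#' @param data numeric matrix of intensities.
#' @param pixel_size_um edge length of one pixel in micrometres.
#' @param frame coordinate-frame identifier.
#' @param channel channel tag (e.g. "DAPI", "FITC", "TxRed", "Cy3",
#'   "Cy5", "Cy7", "BF").
#' @export
channel_image <- function(data, pixel_size_um, frame = "external_fm",
                          channel = NA_character_) {
  stopifnot(is.matrix(data), pixel_size_um > 0)
  structure(data, pixel_size_um = pixel_size_um, frame = frame,
            channel = channel, class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %dx%d px, %.3g um/px, frame=%s, channel=%s>\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), attr(x, "frame"),
              attr(x, "channel")))
  invisible(x)
}

#' Pixel size of an image, mask or MSI dataset
#' @param x object carrying a `pixel_size_um` attribute or field.
#' @export
pixel_size <- function(x) {
  if (is.list(x) && !is.null(x$pixel_size_um)) return(x$pixel_size_um)
  attr(x, "pixel_size_um")
}

#' Integer label mask (0 = background, k > 0 = cell k)
#' @param data integer matrix.
#' @inheritParams channel_image
#' @export
label_mask <- function(data, pixel_size_um, frame = "external_fm") {
  stopifnot(is.matrix(data), pixel_size_um > 0)
  storage.mode(data) <- "integer"
  structure(data, pixel_size_um = pixel_size_um, frame = frame,
            class = c("label_mask", "matrix", "array"))
}

#' Micrometre coordinates of the centres of all pixels of an image
#' @param img image, mask or dimension pair.
#' @param pixel_size_um used when `img` is a dim pair.
#' @return n x 2 matrix (x, y), row-major over the image.
#' @export
pixel_centers_um <- function(img, pixel_size_um = pixel_size(img)) {
  d <- if (is.matrix(img)) dim(img) else img
  rc <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  cbind(x = (rc$c - 0.5) * pixel_size_um, y = (rc$r - 0.5) * pixel_size_um)
}

#' MSI dataset: a pixel grid of peak lists
#'
#' Per-pixel centroided spectra in long form: one row per (pixel, peak).
#' Pixel indices are 1-based (`px` = column/x, `py` = row/y); the
#' physical centre of pixel (px, py) is
#' `((px - 0.5) * pixel_size_um, (py - 0.5) * pixel_size_um)` in `frame`.
#'
#' @param peaks data.frame with columns `px`, `py`, `mz`, `intensity`.
#' @param dims c(nrow, ncol) of the pixel grid.
#' @param pixel_size_um MSI pixel edge in micrometres (1 or 1.5 in the
#'   intended acquisitions).
#' @param frame coordinate frame, normally `"msi"`.
#' @export
msi_dataset <- function(peaks, dims, pixel_size_um, frame = "msi") {
  peaks <- as.data.frame(peaks)
  need <- c("px", "py", "mz", "intensity")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns px, py, mz, intensity")
  stopifnot(length(dims) == 2, all(dims >= 0), pixel_size_um > 0)
  if (nrow(peaks) && (any(peaks$px < 1) || any(peaks$px > dims[2]) ||
                      any(peaks$py < 1) || any(peaks$py > dims[1])))
    stop("peak pixel indices outside grid")
  structure(list(peaks = peaks[need], dims = as.integer(dims),
                 pixel_size_um = pixel_size_um, frame = frame),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset %dx%d px @ %.3g um, %d peaks, frame=%s>\n",
              x$dims[1], x$dims[2], x$pixel_size_um, nrow(x$peaks), x$frame))
  invisible(x)
}

#' Total ion intensity per pixel as an image
#' @param msi an `msi_dataset`.
#' @param mz_range optional c(lo, hi) window restricting the summation
#'   (an "ion image").
#' @export
ion_image <- function(msi, mz_range = NULL) {
  img <- matrix(0, msi$dims[1], msi$dims[2])
  pk <- msi$peaks
  if (!is.null(mz_range)) pk <- pk[pk$mz >= mz_range[1] & pk$mz <= mz_range[2], ]
  if (nrow(pk)) {
    idx <- (pk$px - 1L) * msi$dims[1] + pk$py
    tot <- rowsum(pk$intensity, idx)
    img[as.integer(rownames(tot))] <- tot[, 1]
  }
  channel_image(img, msi$pixel_size_um, frame = msi$frame, channel = "TIC")
}

#' Mean spectrum over all pixels of an MSI dataset
#'
#' Peaks across pixels are merged by agglomerating m/z values closer
#' than `tol_ppm`, then averaging the summed intensity over the number
#' of grid pixels (pixels without a peak contribute zero, as in a
#' profile mean spectrum).
#'
#' @param msi an `msi_dataset`.
#' @param tol_ppm merge tolerance in parts per million.
#' @return data.frame with columns `mz` (intensity-weighted centroid)
#'   and `intensity` (mean over pixels), sorted by m/z.
#' @export
mean_spectrum <- function(msi, tol_ppm = 5) {
  pk <- msi$peaks
  n_px <- prod(msi$dims)
  if (!nrow(pk) || n_px == 0)
    return(data.frame(mz = numeric(), intensity = numeric()))
  o <- order(pk$mz)
  mz <- pk$mz[o]; int <- pk$intensity[o]
  newgrp <- c(TRUE, diff(mz) / mz[-length(mz)] > tol_ppm * 1e-6)
  g <- cumsum(newgrp)
  data.frame(
    mz = as.numeric(rowsum(mz * int, g) / rowsum(int, g)),
    intensity = as.numeric(rowsum(int, g)) / n_px)
}
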