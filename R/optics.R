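#' In-source microscopy math
#'
#' Autofocus by variance of the Laplacian, radial-basis interpolation of
#' the focal surface over the region of interest, mosaic stitching of
#' stage-positioned camera tiles, pixel-to-stage scale calibration from
#' a resolution test target, and teaching-point export linking canvas
#' pixels to stage coordinates.
#'
#' @name optics
NULL

#' Image sharpness: variance of the Laplacian
#'
#' The 3x3 four-neighbour Laplacian stencil is convolved with the image
#' and the variance of the response over the valid (interior) region is
#' returned. Invariant to additive intensity offsets; scales with the
#' square of image contrast.
#'
#' @param image numeric matrix, at least 3x3.
#' @return nonnegative scalar.
#' @export
sharpness <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop("sharpness needs an image of at least 3x3 pixels")
  nr <- nrow(image); nc <- ncol(image)
  ctr <- image[2:(nr - 1), 2:(nc - 1)]
  lap <- image[1:(nr - 2), 2:(nc - 1)] + image[3:nr, 2:(nc - 1)] +
         image[2:(nr - 1), 1:(nc - 2)] + image[2:(nr - 1), 3:nc] - 4 * ctr
  v <- stats::var(as.vector(lap))
  if (is.na(v)) 0 else v
}

#' Autofocus scan parameters
#'
#' A coarse scan at 1 um z-increments over the full range followed by a
#' fine scan at 0.1 um over +/- 1 um around the coarse optimum.
#'
#' @param z_range c(min, max) of stage z in micrometres.
#' @param coarse_step_um coarse increment (default 1).
#' @param fine_step_um fine increment (default 0.1).
#' @param fine_halfrange_um half-width of the fine scan (default 1).
#' @export
focus_scan <- function(z_range, coarse_step_um = 1, fine_step_um = 0.1,
                       fine_halfrange_um = 1) {
  stopifnot(length(z_range) == 2, z_range[2] >= z_range[1],
            fine_step_um < coarse_step_um, fine_halfrange_um >= fine_step_um)
  list(z_range = as.numeric(z_range), coarse_step_um = coarse_step_um,
       fine_step_um = fine_step_um, fine_halfrange_um = fine_halfrange_um)
}

#' Two-stage autofocus
#'
#' Evaluates [sharpness()] on the coarse z grid, moves to the maximum,
#' then rescans at the fine step within the fine half-range and returns
#' the z of maximal sharpness. Ties are broken towards the lowest z.
#'
#' @param stack_reader function(z) returning the image at stage
#'   position z.
#' @param scan a [focus_scan()] list.
#' @return focal z in micrometres, with the evaluated (z, sharpness)
#'   tables attached as attribute `"scan"`.
#' @export
autofocus <- function(stack_reader, scan) {
  zs <- seq(scan$z_range[1], scan$z_range[2], by = scan$coarse_step_um)
  if (!length(zs)) stop("empty autofocus z-range")
  s_coarse <- vapply(zs, function(z) sharpness(stack_reader(z)), numeric(1))
  if (length(zs) > 1 && diff(range(s_coarse)) == 0)
    stop("autofocus: sharpness constant over the scan (featureless field?)")
  z0 <- zs[which.max(s_coarse)]           # which.max -> lowest z on ties
  zf <- seq(z0 - scan$fine_halfrange_um, z0 + scan$fine_halfrange_um,
            by = scan$fine_step_um)
  zf <- zf[zf >= scan$z_range[1] & zf <= scan$z_range[2]]
  s_fine <- vapply(zf, function(z) sharpness(stack_reader(z)), numeric(1))
  z_best <- zf[which.max(s_fine)]
  structure(z_best, scan = list(coarse = data.frame(z = zs, sharpness = s_coarse),
                                fine = data.frame(z = zf, sharpness = s_fine)))
}

#' Fit a focal surface through autofocus sample points
#'
#' Exact radial-basis interpolation of focal z over (x, y): thin-plate
#' spline (r^2 log r plus affine polynomial) for three or more
#' non-collinear points; a linear radial basis for two points; a
#' constant for one. The surface reproduces z exactly at every sample
#' point.
#'
#' @param points data.frame with columns `x_um`, `y_um`, `z_um`.
#' @return object of class `focal_surface`.
#' @export
fit_focal_surface <- function(points) {
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(points)))
  n <- nrow(points)
  if (n == 0) stop("fit_focal_surface needs at least one point")
  xy <- cbind(points$x_um, points$y_um)
  z <- points$z_um
  if (n > 1 && all(stats::dist(xy) < 1e-9))
    stop("fit_focal_surface: points are colocated")
  collinear <- n >= 3 && {
    d <- cbind(xy[, 1] - xy[1, 1], xy[, 2] - xy[1, 2])
    svd(d)$d[2] < 1e-9 * max(svd(d)$d[1], 1)
  }
  if (n == 1) {
    fit <- list(kind = "constant", z0 = z)
  } else if (n == 2 || collinear) {
    K <- as.matrix(stats::dist(xy, diag = TRUE, upper = TRUE))
    w <- solve(K + diag(1e-12, n), z)
    fit <- list(kind = "linear_rbf", xy = xy, w = w)
  } else {
    K <- tps_kernel(as.matrix(stats::dist(xy, diag = TRUE, upper = TRUE)))
    P <- cbind(1, xy)
    M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    sol <- solve(M, c(z, 0, 0, 0))
    fit <- list(kind = "tps", xy = xy, w = sol[1:n], poly = sol[(n + 1):(n + 3)])
  }
  structure(c(fit, list(points = points, mesh_spacing_um = 10)),
            class = "focal_surface")
}

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Evaluate a focal surface
#' @param surface a `focal_surface`.
#' @param x,y query coordinates in micrometres (vectors of equal length).
#' @return focal z in micrometres.
#' @export
query_focal_surface <- function(surface, x, y) {
  q <- cbind(as.numeric(x), as.numeric(y))
  switch(surface$kind,
    constant = rep(surface$z0, nrow(q)),
    linear_rbf = {
      D <- cross_dist(q, surface$xy)
      as.numeric(D %*% surface$w)
    },
    tps = {
      D <- tps_kernel(cross_dist(q, surface$xy))
      as.numeric(D %*% surface$w + cbind(1, q) %*% surface$poly)
    })
}

cross_dist <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}

#' Interpolation mesh of a focal surface over an ROI rectangle
#'
#' The z-offset evaluated on a regular mesh (10 x 10 um by default)
#' covering the ROI; tiles later take their z from the mesh node
#' closest to the tile position.
#'
#' @param surface a `focal_surface`.
#' @param roi_um c(xmin, xmax, ymin, ymax).
#' @param spacing_um mesh spacing.
#' @return data.frame `x_um`, `y_um`, `z_um`.
#' @export
focal_mesh <- function(surface, roi_um, spacing_um = surface$mesh_spacing_um) {
  gx <- seq(roi_um[1], roi_um[2], by = spacing_um)
  gy <- seq(roi_um[3], roi_um[4], by = spacing_um)
  if (max(gx) < roi_um[2]) gx <- c(gx, roi_um[2])
  if (max(gy) < roi_um[4]) gy <- c(gy, roi_um[4])
  g <- expand.grid(x_um = gx, y_um = gy)
  g$z_um <- query_focal_surface(surface, g$x_um, g$y_um)
  g
}

#' Focal z for a tile position: nearest mesh node
#' @param mesh data.frame from [focal_mesh()].
#' @param x,y tile centre in micrometres.
#' @export
tile_z_from_mesh <- function(mesh, x, y) {
  i <- which.min((mesh$x_um - x)^2 + (mesh$y_um - y)^2)
  mesh$z_um[i]
}

#' Tile grid for mosaic acquisition
#'
#' Abutting tiles of at most 100 x 100 um covering the ROI; camera
#' images are cropped to the tile cell and placed on the canvas by
#' their stage centre coordinates.
#'
#' @param roi_um c(xmin, xmax, ymin, ymax) of the ROI in stage
#'   micrometres.
#' @param tile_size_um tile cell edge (<= 100).
#' @param scale_factor micrometres per camera pixel.
#' @export
tile_grid <- function(roi_um, tile_size_um = 100, scale_factor) {
  stopifnot(tile_size_um > 0, tile_size_um <= 100, scale_factor > 0)
  nx <- ceiling((roi_um[2] - roi_um[1]) / tile_size_um - 1e-9)
  ny <- ceiling((roi_um[4] - roi_um[3]) / tile_size_um - 1e-9)
  cx <- roi_um[1] + (seq_len(nx) - 0.5) * tile_size_um
  cy <- roi_um[3] + (seq_len(ny) - 0.5) * tile_size_um
  centers <- expand.grid(x_um = cx, y_um = cy)
  structure(list(roi_um = as.numeric(roi_um), tile_size_um = tile_size_um,
                 scale_factor = scale_factor, nx = nx, ny = ny,
                 centers = centers),
            class = "tile_grid")
}

#' Stitch camera tiles onto the ROI canvas
#'
#' Each tile is cropped symmetrically from its edges to the tile cell
#' size and written into the canvas at its centre coordinate, so every
#' canvas pixel is written by exactly one tile (no blending).
#'
#' @param tiles list of camera images (matrices), one per row of
#'   `grid$centers`, all at `grid$scale_factor` um/px.
#' @param grid a [tile_grid()].
#' @return canvas as a [channel_image()] in the stage frame (origin at
#'   the ROI top-left corner).
#' @export
stitch <- function(tiles, grid) {
  if (!length(tiles)) stop("stitch: empty tile list")
  if (length(tiles) != nrow(grid$centers))
    stop("stitch: number of tiles does not match the grid")
  crop_px <- round(grid$tile_size_um / grid$scale_factor)
  cw <- grid$nx * crop_px; ch <- grid$ny * crop_px
  canvas <- matrix(0, ch, cw)
  for (i in seq_along(tiles)) {
    tile <- tiles[[i]]
    if (nrow(tile) < crop_px || ncol(tile) < crop_px)
      stop("stitch: tile smaller than the crop size")
    r0 <- floor((nrow(tile) - crop_px) / 2)
    c0 <- floor((ncol(tile) - crop_px) / 2)
    cropped <- tile[r0 + seq_len(crop_px), c0 + seq_len(crop_px)]
    ix <- round((grid$centers$x_um[i] - grid$roi_um[1]) / grid$tile_size_um + 0.5)
    iy <- round((grid$centers$y_um[i] - grid$roi_um[3]) / grid$tile_size_um + 0.5)
    canvas[(iy - 1) * crop_px + seq_len(crop_px),
           (ix - 1) * crop_px + seq_len(crop_px)] <- cropped
  }
  channel_image(canvas, grid$tile_size_um / crop_px, frame = "insource_fm")
}

#' Calibrate the pixel-to-stage scale from a periodic bar target
#'
#' Estimates the bar period in pixels from the dominant non-DC peak of
#' the Fourier spectrum of the column-mean profile (bars assumed
#' vertical; pass `t(image)` for horizontal bars) and divides the known
#' physical period by it.
#'
#' @param target_image image of a periodic bar pattern (e.g. a 1951
#'   USAF resolution target element).
#' @param known_spacing_um physical period of the bar pattern in
#'   micrometres.
#' @return scale factor in micrometres per pixel.
#' @export
calibrate_scale <- function(target_image, known_spacing_um) {
  stopifnot(is.matrix(target_image), known_spacing_um > 0)
  prof <- colMeans(target_image)
  prof <- prof - mean(prof)
  n <- length(prof)
  sp <- Mod(stats::fft(prof))[2:floor(n / 2)]
  k <- which.max(sp)                       # cycles over the window
  # refine by parabolic interpolation on the log-spectrum
  if (k > 1 && k < length(sp)) {
    a <- log(sp[k - 1] + 1e-12); b <- log(sp[k]); c <- log(sp[k + 1] + 1e-12)
    k <- k + 0.5 * (a - c) / (a - 2 * b + c)
  }
  period_px <- n / k
  known_spacing_um / period_px
}

#' Teaching points: canvas-pixel to stage-coordinate correspondences
#'
#' Exports the top-left, bottom-left and bottom-right tile centres of
#' the mosaic grid as (image pixel, stage um) pairs; an affine fit
#' through the three pairs reproduces the canvas-to-stage mapping
#' exactly.
#'
#' @param grid a [tile_grid()] with at least 2x2 tiles.
#' @param fine_offset_px optional (x, y) pixel offset applied to the
#'   image coordinates (laser-to-camera centring correction).
#' @return data.frame `corner`, `px_x`, `px_y` (canvas pixel,
#'   0-based continuous), `stage_x_um`, `stage_y_um`.
#' @export
teaching_points <- function(grid, fine_offset_px = c(0, 0)) {
  if (grid$nx < 2 || grid$ny < 2)
    stop("teaching_points needs a grid of at least 2x2 tiles")
  crop_px <- round(grid$tile_size_um / grid$scale_factor)
  px_per_um <- crop_px / grid$tile_size_um
  corners <- data.frame(
    corner = c("top_left", "bottom_left", "bottom_right"),
    ix = c(1, 1, grid$nx), iy = c(1, grid$ny, grid$ny))
  stage_x <- grid$roi_um[1] + (corners$ix - 0.5) * grid$tile_size_um
  stage_y <- grid$roi_um[3] + (corners$iy - 0.5) * grid$tile_size_um
  data.frame(corner = corners$corner,
             px_x = (stage_x - grid$roi_um[1]) * px_per_um + fine_offset_px[1],
             px_y = (stage_y - grid$roi_um[3]) * px_per_um + fine_offset_px[2],
             stage_x_um = stage_x, stage_y_um = stage_y)
}

#' Affine canvas-to-stage mapping from teaching points
#' @param tp data.frame from [teaching_points()].
#' @return an [affine2d()] mapping canvas pixel coordinates to stage
#'   micrometres.
#' @export
teaching_transform <- function(tp) {
  affine_fit(cbind(tp$px_x, tp$px_y), cbind(tp$stage_x_um, tp$stage_y_um),
             from = "canvas_px", to = "stage_um")
}
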