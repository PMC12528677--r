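# independent oracle: direct 3x3 four-neighbour Laplacian convolution
# followed by the variance of the valid responses
laplacian_variance_oracle <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- c()
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    out <- c(out, img[r - 1, c] + img[r + 1, c] + img[r, c - 1] +
               img[r, c + 1] - 4 * img[r, c])
  }
  stats::var(out)
}

test_that("sharpness matches the direct convolution oracle", {
  expect_equal(sharpness(matrix(7, 10, 10)), 0)
  set.seed(1)
  img <- matrix(runif(15 * 12), 15, 12)
  expect_equal(sharpness(img), laplacian_variance_oracle(img))
  # checkerboard of period 2 px, amplitude a
  a <- 2.5
  cb <- a * outer(1:12, 1:12, function(r, c) (-1)^(r + c))
  expect_equal(sharpness(cb), laplacian_variance_oracle(cb))
  expect_error(sharpness(matrix(1, 2, 2)), "3x3")
})

test_that("sharpness is offset-invariant, contrast-quadratic and blur-sensitive", {
  set.seed(2)
  img <- matrix(runif(40 * 40), 40)
  expect_equal(sharpness(img + 100), sharpness(img))
  expect_equal(sharpness(3 * img), 9 * sharpness(img))
  blurred <- generate_defocus_stack(img, 1, 0, blur_sigma_per_um = 2)[[1]]
  expect_gt(sharpness(img), sharpness(blurred))
})

test_that("autofocus finds the focal plane to one fine step", {
  set.seed(3)
  img <- matrix(runif(48 * 48), 48)
  reader_at <- function(focal_z) function(z)
    generate_defocus_stack(img, z, focal_z)[[1]]
  # focus exactly on a coarse grid point
  expect_equal(as.numeric(autofocus(reader_at(4), focus_scan(c(0, 8)))), 4)
  # focus between grid points
  z <- as.numeric(autofocus(reader_at(12.34), focus_scan(c(8, 16))))
  expect_lt(abs(z - 12.34), 0.1 + 1e-9)
  # featureless field
  expect_error(autofocus(function(z) matrix(1, 8, 8), focus_scan(c(0, 3))),
               "featureless")
})

test_that("a two-image stack returns the sharper image's z", {
  set.seed(4)
  img <- matrix(runif(32 * 32), 32)
  stack <- list(generate_defocus_stack(img, 0, 1)[[1]], img)
  reader <- function(z) stack[[which.min(abs(c(0, 1) - z))]]
  z <- as.numeric(autofocus(reader, focus_scan(c(0, 1), coarse_step_um = 1,
                                               fine_step_um = 0.5,
                                               fine_halfrange_um = 0.5)))
  expect_equal(z, 1)
})

test_that("focal surface interpolation is exact and recovers planes", {
  # single point: constant surface
  s1 <- fit_focal_surface(data.frame(x_um = 5, y_um = 7, z_um = 3.2))
  expect_equal(query_focal_surface(s1, c(0, 50), c(0, 90)), c(3.2, 3.2))
  # plane through three points
  pts <- data.frame(x_um = c(0, 80, 0), y_um = c(0, 0, 80))
  pts$z_um <- 2 + 0.01 * pts$x_um
  s3 <- fit_focal_surface(pts)
  expect_equal(query_focal_surface(s3, pts$x_um, pts$y_um), pts$z_um,
               tolerance = 1e-9)
  mesh <- focal_mesh(s3, c(0, 80, 0, 80))
  expect_lt(max(abs(mesh$z_um - (2 + 0.01 * mesh$x_um))), 1e-6)
  # arbitrary points reproduced exactly
  set.seed(5)
  p <- data.frame(x_um = runif(8, 0, 100), y_um = runif(8, 0, 100),
                  z_um = rnorm(8))
  sf <- fit_focal_surface(p)
  expect_equal(query_focal_surface(sf, p$x_um, p$y_um), p$z_um,
               tolerance = 1e-8)
  expect_error(fit_focal_surface(data.frame(x_um = numeric(),
                                            y_um = numeric(),
                                            z_um = numeric())), "one point")
})

test_that("tile z comes from the nearest mesh node", {
  pts <- data.frame(x_um = c(0, 100, 0), y_um = c(0, 0, 100),
                    z_um = c(1, 2, 3))
  mesh <- focal_mesh(fit_focal_surface(pts), c(0, 100, 0, 100))
  expect_equal(tile_z_from_mesh(mesh, 1, 2), mesh$z_um[1])
})

test_that("stitching reproduces a directly rendered scene", {
  set.seed(6)
  scale <- 0.5                                 # um per camera px
  grid <- tile_grid(c(0, 100, 0, 100), tile_size_um = 50, scale_factor = scale)
  scene_px <- 200
  margin <- 20                                 # camera sees beyond its cell
  big <- matrix(runif((scene_px + 2 * margin)^2),
                scene_px + 2 * margin)
  scene <- big[margin + 1:scene_px, margin + 1:scene_px]
  crop_px <- 100
  tiles <- lapply(seq_len(nrow(grid$centers)), function(i) {
    cx <- grid$centers$x_um[i] / scale; cy <- grid$centers$y_um[i] / scale
    big[margin + cy + seq(-crop_px / 2 - margin + 1, crop_px / 2 + margin),
        margin + cx + seq(-crop_px / 2 - margin + 1, crop_px / 2 + margin)]
  })
  canvas <- stitch(tiles, grid)
  expect_identical(dim(canvas), dim(scene))
  expect_equal(unclass(canvas), scene, ignore_attr = TRUE)
  # single tile grid
  g1 <- tile_grid(c(0, 50, 0, 50), 50, scale)
  c1 <- stitch(tiles[1], g1)
  expect_equal(dim(c1), c(100L, 100L))
  expect_error(stitch(list(), grid), "empty")
  expect_error(stitch(list(matrix(0, 10, 10)), g1), "smaller")
})

test_that("scale calibration recovers the bar period within 1%", {
  period_px <- 10; spacing_um <- 5
  x <- outer(rep(1, 120), 1:120, function(r, c) sin(2 * pi * c / period_px))
  expect_equal(calibrate_scale(x, spacing_um), spacing_um / period_px,
               tolerance = 0.01)
  # doubled resolution halves the scale factor
  x2 <- outer(rep(1, 240), 1:240, function(r, c) sin(2 * pi * c / (2 * period_px)))
  expect_equal(calibrate_scale(x2, spacing_um),
               calibrate_scale(x, spacing_um) / 2, tolerance = 0.01)
  set.seed(7)
  noisy <- x + matrix(rnorm(length(x), 0, 0.2), nrow(x))
  expect_equal(calibrate_scale(noisy, spacing_um), 0.5, tolerance = 0.005)
})

test_that("teaching points yield an exact canvas-to-stage mapping", {
  grid <- tile_grid(c(0, 300, 0, 200), tile_size_um = 100, scale_factor = 0.5)
  tp <- teaching_points(grid)
  expect_identical(tp$corner, c("top_left", "bottom_left", "bottom_right"))
  tf <- teaching_transform(tp)
  crop_px <- 200
  px_xy <- cbind((grid$centers$x_um - 0) / grid$tile_size_um * crop_px,
                 (grid$centers$y_um - 0) / grid$tile_size_um * crop_px)
  mapped <- affine_apply(tf, px_xy)
  expect_lt(max(abs(mapped - as.matrix(grid$centers))), 1e-9)
  # per-pixel fine offset shifts the mapping by exactly that offset
  tp_off <- teaching_points(grid, fine_offset_px = c(3, -2))
  tf_off <- teaching_transform(tp_off)
  mapped_off <- affine_apply(tf_off, sweep(px_xy, 2, c(-3, 2)))
  expect_lt(max(abs(mapped_off - as.matrix(grid$centers))), 1e-9)
  expect_error(teaching_points(tile_grid(c(0, 80, 0, 80), 100, 0.5)), "2x2")
})

test_that("canvas-stage round trip through stitching is lossless", {
  grid <- tile_grid(c(10, 210, 20, 220), tile_size_um = 100,
                    scale_factor = 0.5)
  tp <- teaching_points(grid)
  tf <- teaching_transform(tp)
  back <- affine_apply(affine_invert(tf), affine_apply(tf, cbind(37.5, 81.25)))
  expect_lt(max(abs(back - cbind(37.5, 81.25))), 1e-9)
})
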