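# supersampled-area oracle: fraction of an MSI pixel covered by each
# label, computed by dense point sampling independent of project_masks
coverage_oracle <- function(mask, transform, msi_grid, px, py, n = 40) {
  mpx <- msi_grid$pixel_size_um
  off <- (seq_len(n) - 0.5) / n
  g <- expand.grid(ox = off, oy = off)
  pts <- affine_apply(transform,
                      cbind((px - 1 + g$ox) * mpx, (py - 1 + g$oy) * mpx))
  fpx <- pixel_size(mask)
  cc <- floor(pts[, 1] / fpx) + 1
  rr <- floor(pts[, 2] / fpx) + 1
  ok <- cc >= 1 & cc <= ncol(mask) & rr >= 1 & rr <= nrow(mask)
  lab <- integer(nrow(pts))
  lab[ok] <- unclass(mask)[cbind(rr[ok], cc[ok])]
  tab <- table(lab[lab > 0])
  stats::setNames(as.numeric(tab) / n^2, names(tab))
}

test_that("pixel coverage fractions follow mask geometry", {
  # 8x8 fine mask at 0.5 um; MSI at 1 um: each MSI pixel = 2x2 fine px
  m <- matrix(0L, 8, 8)
  m[, 1:4] <- 1L                 # cell 1 covers the left half
  m[1:2, 5] <- 2L                # cell 2 covers part of one MSI pixel
  mask <- label_mask(m, 0.5)
  grid <- list(dims = c(4L, 4L), pixel_size_um = 1)
  cov <- project_masks(mask, affine_identity("msi", "external_fm"), grid)
  # pixel fully inside cell 1
  expect_equal(cov$fraction[cov$px == 1 & cov$py == 1], 1)
  # pixel (3,1): fine cols 5-6, rows 1-2 -> cell 2 covers cols 5 only
  f <- cov[cov$px == 3 & cov$py == 1, ]
  expect_equal(f$fraction[f$label == 2], 0.5)
  # background pixel: absent from the map
  expect_false(any(cov$px == 4 & cov$py == 4))
  # fractions per pixel never exceed 1
  per_pix <- rowsum(cov$fraction, paste(cov$px, cov$py))
  expect_true(all(per_pix <= 1 + 1e-12))
})

test_that("coverage agrees with a supersampled area oracle under a transform", {
  ph <- std_phantom()
  tf <- affine_invert(ph$truth$transform)
  grid <- list(dims = ph$msi$dims, pixel_size_um = ph$msi$pixel_size_um)
  cov <- project_masks(ph$truth$label_mask, tf, grid, supersample = 8)
  covered <- unique(cov[, c("px", "py")])
  set.seed(31)
  pick <- covered[sample(nrow(covered), 12), ]
  for (i in seq_len(nrow(pick))) {
    oracle <- coverage_oracle(ph$truth$label_mask, tf, grid,
                              pick$px[i], pick$py[i])
    got <- cov[cov$px == pick$px[i] & cov$py == pick$py[i], ]
    for (lab in names(oracle)) {
      g <- got$fraction[got$label == as.integer(lab)]
      expect_lt(abs((if (length(g)) g else 0) - as.numeric(oracle[lab])),
                0.05)
    }
  }
})

test_that("disjoint grids give an empty coverage map with a warning", {
  mask <- label_mask(matrix(1L, 4, 4), 0.5)
  grid <- list(dims = c(4L, 4L), pixel_size_um = 1)
  far <- affine2d(diag(2), c(1e5, 1e5), "msi", "external_fm")
  expect_warning(cov <- project_masks(mask, far, grid), "overlap")
  expect_identical(nrow(cov), 0L)
})

test_that("spectrum compilation sums and apportions intensity exactly", {
  peaks <- data.frame(px = c(1L, 2L, 3L), py = 1L, mz = 700.0,
                      intensity = c(3, 5, 4))
  msi <- msi_dataset(peaks, c(1L, 3L), 1)
  species <- data.frame(species = "S", mz = 700.0)
  # one cell fully covering pixels 1 and 2
  cov1 <- data.frame(px = 1:2, py = 1L, label = 1L, fraction = 1)
  tab <- compile_spectra(msi, cov1, species)
  expect_equal(tab$S, 8)
  # shared pixel split 0.25 / 0.75: contributions 1 and 3, sum 4
  cov2 <- data.frame(px = 3L, py = 1L, label = c(1L, 2L),
                     fraction = c(0.25, 0.75))
  tab2 <- compile_spectra(msi, cov2, species)
  expect_equal(tab2$S, c(1, 3))
  expect_equal(sum(tab2$S), 4)
})

test_that("assigned plus unassigned intensity equals the dataset total", {
  ph <- std_phantom()
  species <- phantom_species_table(ph)
  tf <- affine_invert(ph$truth$transform)
  grid <- list(dims = ph$msi$dims, pixel_size_um = ph$msi$pixel_size_um)
  cov <- project_masks(ph$truth$label_mask, tf, grid)
  tab <- compile_spectra(ph$msi, cov, species)
  psi <- pixel_species_intensity(ph$msi, species)
  total <- sum(psi$intensity)
  assigned <- sum(as.matrix(tab[, species$species]))
  # unassigned = per-pixel total weighted by uncovered fraction
  key <- paste(psi$px, psi$py)
  covfrac <- rowsum(cov$fraction, paste(cov$px, cov$py))
  pixcov <- stats::setNames(as.numeric(covfrac), rownames(covfrac))
  pixcov_of <- ifelse(key %in% names(pixcov), pixcov[key], 0)
  unassigned <- sum(psi$intensity * (1 - pixcov_of))
  expect_equal(assigned + unassigned, total, tolerance = 1e-9)
})

test_that("compilation is linear in MSI intensities", {
  ph <- clean_phantom()
  species <- phantom_species_table(ph)
  tf <- affine_invert(ph$truth$transform)
  grid <- list(dims = ph$msi$dims, pixel_size_um = ph$msi$pixel_size_um)
  cov <- project_masks(ph$truth$label_mask, tf, grid)
  tab1 <- compile_spectra(ph$msi, cov, species)
  msi2 <- ph$msi
  msi2$peaks$intensity <- 3 * msi2$peaks$intensity
  tab2 <- compile_spectra(msi2, cov, species)
  expect_equal(as.matrix(tab2[, species$species]),
               3 * as.matrix(tab1[, species$species]))
})

test_that("zero-noise phantoms recover the planted profiles", {
  ph <- clean_phantom()
  cfg <- ph$truth$config
  species <- phantom_species_table(ph)
  tf <- affine_invert(ph$truth$transform)
  grid <- list(dims = ph$msi$dims, pixel_size_um = ph$msi$pixel_size_um)
  cov <- project_masks(ph$truth$label_mask, tf, grid)
  tab <- normalize_cells(compile_spectra(ph$msi, cov, species),
                         species$species)
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]
    tp <- ph$truth$cells$type[ph$truth$cells$label == lab]
    prof <- type_profile(cfg, tp, species$species)
    prof <- prof / sum(prof)
    got <- as.numeric(tab[i, species$species])
    cossim <- sum(got * prof) / sqrt(sum(got^2) * sum(prof^2))
    expect_gt(cossim, 0.999)
  }
})

test_that("normalization behaves on simple and degenerate rows", {
  tab <- data.frame(label = 1:2, n_pixels = 1,
                    a = c(2, 0), b = c(2, 0), c = c(4, 0),
                    flag_empty = FALSE)
  out <- normalize_cells(tab, c("a", "b", "c"))
  expect_equal(as.numeric(out[1, c("a", "b", "c")]), c(0.25, 0.25, 0.5))
  expect_true(out$flag_empty[2])
  expect_equal(as.numeric(out[2, c("a", "b", "c")]), c(0, 0, 0))
  # idempotent on normalized rows
  out2 <- normalize_cells(out, c("a", "b", "c"))
  expect_equal(out2[1, ], out[1, ])
})

test_that("region comparison flags planted fold changes", {
  # region A mean = 8x region B mean -> log2 fold change 3, flagged
  peaks <- data.frame(px = rep(1:4, each = 1), py = 1L, mz = 700,
                      intensity = c(8, 8, 1, 1))
  msi <- msi_dataset(peaks, c(1L, 4L), 1)
  species <- data.frame(species = "S", mz = 700)
  A <- matrix(c(1, 1, 0, 0), 1); B <- matrix(c(0, 0, 1, 1), 1)
  rc <- region_compare(msi, A, B, species, pseudocount = 0)
  expect_equal(rc$log2fc, 3)
  expect_true(rc$flagged)
  # identical content in disjoint regions: fold change 0
  peaks2 <- data.frame(px = 1:4, py = 1L, mz = 700, intensity = c(5, 5, 5, 5))
  rc2 <- region_compare(msi_dataset(peaks2, c(1L, 4L), 1), A, B, species)
  expect_equal(rc2$log2fc, 0)
  expect_false(rc2$flagged)
  expect_error(region_compare(msi, A, A, species), "disjoint")
})

test_that("inclusion-only species are flagged against the remaining cell", {
  incl_types <- list(cell_type_spec(
    "macrophage", 1, radius_um = 8, radius_sd_um = 0.5,
    species_profile = c("PC(34:1)" = 10, "SM(34:1;O2)" = 4),
    inclusion = list(species_profile = c("PE(33:1)" = 20),
                     radius_frac = 0.3, channel = "Cy3")))
  cfg <- phantom_config(field_size_um = c(100, 100), n_cells = 12,
                        cell_types = incl_types, seed = 8,
                        misalignment = list(rotation_deg = 0, scale = 1,
                                            translation_um = c(0, 0)),
                        noise = list(fm_sigma = 0, msi_poisson_scale = 0,
                                     mz_jitter_ppm = 0))
  ph <- generate_phantom(cfg)
  species <- phantom_species_table(ph)
  # inclusion mask from the Cy3 channel, complemented by the cell mask
  feat_fm <- subcellular_mask(ph$fm_channels$Cy3, 0.5)
  ratio <- round(cfg$msi_pixel_um / cfg$fm_pixel_um)
  shrink <- function(m) {
    nr <- nrow(m) / ratio
    out <- matrix(0L, nr, nr)
    for (r in seq_len(nr)) for (c in seq_len(nr)) {
      blk <- m[(r - 1) * ratio + 1:ratio, (c - 1) * ratio + 1:ratio]
      out[r, c] <- as.integer(all(blk > 0))
    }
    out
  }
  A <- shrink(unclass(feat_fm))                      # pHrodo+ analogue
  cellm <- shrink(unclass(ph$truth$label_mask))      # whole cells
  B <- cellm * (A == 0)                              # remaining cell
  rc <- region_compare(ph$msi, A, B, species)
  expect_true(rc$flagged[rc$species == "PE(33:1)"])
  expect_false(rc$flagged[rc$species == "PC(34:1)"])
})
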