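#' Synthetic multimodal phantoms
#'
#' Generates ground-truth test scenes for the whole pipeline: a field
#' of elliptical cells with type-specific fluorescence markers and
#' lipid profiles, rendered both as fine-grid fluorescence channels in
#' the external-microscope frame and as a coarse-grid MSI peak-list
#' datacube in the instrument frame, displaced by a known affine
#' misalignment. Every quantity a downstream stage estimates
#' (registration transform, label masks, per-cell profiles, focal
#' surface) is returned as ground truth.
#'
#' @name phantom
NULL

#' Specification of one phantom cell type
#'
#' @param name type name.
#' @param fraction expected fraction of cells of this type (fractions
#'   over all types must sum to 1).
#' @param radius_um mean equivalent radius in micrometres.
#' @param radius_sd_um standard deviation of the radius.
#' @param marker_channels character vector of immunofluorescence
#'   channels ("TxRed", "Cy5", "Cy7") in which this type is "high".
#' @param species_profile named numeric vector: mean MSI intensity per
#'   unit area (per um^2) for each lipid species.
#' @param inclusion optional list(`species_profile`, `radius_frac`,
#'   `channel`): a bright subcellular inclusion (phagolysosome
#'   analogue) rendered into `channel` and carrying its own lipid
#'   profile on top of the cytoplasmic one.
#' @export
cell_type_spec <- function(name, fraction, radius_um = 6, radius_sd_um = 1,
                           marker_channels = character(),
                           species_profile, inclusion = NULL) {
  stopifnot(fraction >= 0, radius_um > 0, all(species_profile >= 0),
            !is.null(names(species_profile)))
  list(name = name, fraction = fraction, radius_um = radius_um,
       radius_sd_um = radius_sd_um, marker_channels = marker_channels,
       species_profile = species_profile, inclusion = inclusion)
}

#' Default phantom cell types
#'
#' Four types emulating the marker logic of a tumor section stained
#' for CD45 (Cy5), Ly6G (TxRed) and DcTRAIL-R1 (Cy7): tumor cells
#' (no markers), CD45+ immune cells, Ly6G+ neutrophils (TxRed + Cy5)
#' and DcTRAIL-R1+ T3 neutrophils (all three), each with a distinct
#' bulk lipid profile.
#' @export
default_cell_types <- function() {
  list(
    cell_type_spec("tumor", 0.55, radius_um = 7,
      species_profile = c("PC(34:1)" = 10, "PC(38:6)" = 6, "SM(34:1;O2)" = 2,
                          "PC(O-32:0)" = 0.2, "LPC(16:0)" = 0.5,
                          "ACAR(18:0)" = 0.2, "cholesterol" = 3)),
    cell_type_spec("immune", 0.20, radius_um = 5, marker_channels = "Cy5",
      species_profile = c("PC(34:1)" = 6, "PC(38:6)" = 2, "SM(34:1;O2)" = 8,
                          "PC(O-32:0)" = 0.5, "LPC(16:0)" = 1,
                          "ACAR(18:0)" = 0.3, "cholesterol" = 6)),
    cell_type_spec("neutrophil", 0.15, radius_um = 5,
      marker_channels = c("TxRed", "Cy5"),
      species_profile = c("PC(34:1)" = 4, "PC(38:6)" = 1, "SM(34:1;O2)" = 2,
                          "PC(O-32:0)" = 9, "LPC(16:0)" = 2,
                          "ACAR(18:0)" = 1, "cholesterol" = 2)),
    cell_type_spec("t3_neutrophil", 0.10, radius_um = 5,
      marker_channels = c("TxRed", "Cy5", "Cy7"),
      species_profile = c("PC(34:1)" = 3, "PC(38:6)" = 1, "SM(34:1;O2)" = 1,
                          "PC(O-32:0)" = 8, "LPC(16:0)" = 8,
                          "ACAR(18:0)" = 6, "cholesterol" = 2)))
}

#' Phantom configuration
#'
#' Defaults describe a desk-scale tissue scene: a 200 x 200 um field,
#' external fluorescence at 0.5 um pixels, MSI at 1 um pixels (the
#' instrument's tissue pixel size; 1.5 um is the cultured-cell
#' setting), 80 cells of the [default_cell_types()], a misalignment of
#' 2 degrees rotation, 1.01 scale and an (8, -5) um shift between the
#' external and instrument frames, a gently tilted focal surface, 1 ppm
#' m/z jitter, and counting-statistics (scaled Poisson) noise on MSI
#' intensities.
#'
#' @param field_size_um c(width, height) of the field.
#' @param fm_pixel_um fluorescence pixel size (must be <= msi_pixel_um).
#' @param msi_pixel_um MSI pixel size (1 or 1.5 in the intended use).
#' @param n_cells number of cells.
#' @param cell_types list of [cell_type_spec()]s.
#' @param misalignment list(rotation_deg, scale, translation_um): true
#'   transform from the external-FM frame to the instrument (MSI)
#'   frame, acting about the field centre.
#' @param focal_coeff polynomial coefficients c(z0, zx, zy) of the true
#'   focal surface z = z0 + zx*x + zy*y (um).
#' @param noise list(fm_sigma, msi_poisson_scale, mz_jitter_ppm). Set
#'   `fm_sigma = 0` and `msi_poisson_scale = 0` for a noise-free
#'   phantom; `msi_poisson_scale` is the intensity of one "count".
#' @param min_gap_um minimum edge-to-edge gap enforced between cells.
#' @param seed RNG seed; fixed seed gives bit-identical phantoms.
#' @export
phantom_config <- function(field_size_um = c(200, 200), fm_pixel_um = 0.5,
                           msi_pixel_um = 1.0, n_cells = 80,
                           cell_types = default_cell_types(),
                           misalignment = list(rotation_deg = 2, scale = 1.01,
                                               translation_um = c(8, -5)),
                           focal_coeff = c(2, 0.01, -0.005),
                           noise = list(fm_sigma = 0.02,
                                        msi_poisson_scale = 0.25,
                                        mz_jitter_ppm = 1),
                           min_gap_um = 2, seed = 1L) {
  stopifnot(all(field_size_um > 0), fm_pixel_um <= msi_pixel_um,
            fm_pixel_um > 0, n_cells >= 0)
  fr <- vapply(cell_types, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("cell type fractions must sum to 1")
  structure(list(field_size_um = field_size_um, fm_pixel_um = fm_pixel_um,
                 msi_pixel_um = msi_pixel_um, n_cells = n_cells,
                 cell_types = cell_types, misalignment = misalignment,
                 focal_coeff = focal_coeff, noise = noise,
                 min_gap_um = min_gap_um, seed = as.integer(seed)),
            class = "phantom_config")
}

#' True external-FM to MSI transform of a phantom configuration
#' @param config a [phantom_config()].
#' @export
phantom_truth_transform <- function(config) {
  m <- config$misalignment
  affine_from_params(m$rotation_deg, m$scale, m$translation_um,
                     center_um = config$field_size_um / 2,
                     from = "external_fm", to = "msi")
}

#' Generate a multimodal phantom
#'
#' @param config a [phantom_config()].
#' @return list with elements
#'   \describe{
#'     \item{fm_channels}{named list of [channel_image()]s (DAPI, FITC,
#'       TxRed, Cy5, Cy7, and Cy3 if any type has inclusions) on the
#'       fine grid in the `external_fm` frame.}
#'     \item{msi}{an [msi_dataset()] on the coarse grid in the `msi`
#'       frame.}
#'     \item{truth}{ground truth: `label_mask` (fine grid,
#'       external frame), `cells` table (type, centroids in both
#'       frames, radii, inclusion geometry), `transform`
#'       (external_fm -> msi), `species` (name, theoretical and
#'       rendered m/z), `pixel_truth` (noise-free per-pixel species
#'       intensities on the MSI grid), `focal_surface` function.}
#'   }
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)

  W <- config$field_size_um[1]; H <- config$field_size_um[2]
  cells <- place_cells(config)
  tf <- phantom_truth_transform(config)

  species <- phantom_species(config$cell_types)
  fm <- render_fm_channels(cells, config)
  mask <- render_label_mask(cells, config)
  msi_parts <- render_msi(cells, species, tf, config)

  if (nrow(cells)) {
    msi_cent <- affine_apply(tf, cbind(cells$x_um, cells$y_um))
    cells$x_msi_um <- msi_cent[, 1]; cells$y_msi_um <- msi_cent[, 2]
  } else {
    cells$x_msi_um <- numeric(0); cells$y_msi_um <- numeric(0)
  }

  fc <- config$focal_coeff
  focal <- function(x, y) fc[1] + fc[2] * x + fc[3] * y

  list(fm_channels = fm,
       msi = msi_parts$msi,
       truth = list(label_mask = mask, cells = cells, transform = tf,
                    species = species, pixel_truth = msi_parts$pixel_truth,
                    focal_surface = focal, config = config))
}

# -- internals ---------------------------------------------------------

phantom_species <- function(cell_types) {
  nm <- unique(unlist(lapply(cell_types, function(ct)
    c(names(ct$species_profile),
      if (!is.null(ct$inclusion)) names(ct$inclusion$species_profile)))))
  lib <- default_lipid_library()
  i <- match(nm, lib$name)
  if (anyNA(i)) stop("phantom species not in library: ",
                     paste(nm[is.na(i)], collapse = ", "))
  first_add <- vapply(strsplit(lib$adducts[i], ";"), function(a)
    trimws(a[[1]]), character(1))
  data.frame(species = nm, formula = lib$formula[i], adduct = first_add,
             mz = adduct_mz(monoisotopic_mass_vec(lib$formula[i]), first_add),
             stringsAsFactors = FALSE)
}

monoisotopic_mass_vec <- function(f) vapply(f, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)

place_cells <- function(config) {
  n <- config$n_cells
  empty <- data.frame(label = integer(), type = character(),
                      x_um = numeric(), y_um = numeric(), a_um = numeric(),
                      b_um = numeric(), theta = numeric(),
                      nucleus_frac = numeric(), incl_x_um = numeric(),
                      incl_y_um = numeric(), incl_r_um = numeric())
  if (n == 0) return(empty)
  fr <- vapply(config$cell_types, `[[`, numeric(1), "fraction")
  type_idx <- sample.int(length(fr), n, replace = TRUE, prob = fr)
  W <- config$field_size_um[1]; H <- config$field_size_um[2]
  out <- vector("list", n)
  placed_x <- placed_y <- placed_r <- numeric(0)
  area_covered <- 0
  for (k in seq_len(n)) {
    ct <- config$cell_types[[type_idx[k]]]
    r <- max(1.5, stats::rnorm(1, ct$radius_um, ct$radius_sd_um))
    ar <- stats::runif(1, 0.7, 1)          # axis ratio b/a
    a <- r / sqrt(ar); b <- r * sqrt(ar)
    th <- stats::runif(1, 0, pi)
    area_covered <- area_covered + pi * a * b   # requested area
    ok <- FALSE
    for (try in 1:200) {
      x <- stats::runif(1, a + 1, W - a - 1)
      y <- stats::runif(1, a + 1, H - a - 1)
      if (!length(placed_x) ||
          all(sqrt((placed_x - x)^2 + (placed_y - y)^2) >
              placed_r + a + config$min_gap_um)) { ok <- TRUE; break }
    }
    if (!ok) {
      if (area_covered > 0.9 * W * H)
        stop("degenerate phantom: requested cells cover > 90% of the field")
      next                                  # field crowded; skip this cell
    }
    placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
    placed_r <- c(placed_r, a)
    incl <- ct$inclusion
    has_incl <- !is.null(incl)
    ir <- if (has_incl) incl$radius_frac * r else NA_real_
    iphi <- stats::runif(1, 0, 2 * pi)
    ioff <- if (has_incl) (r - ir) * 0.5 else 0
    out[[k]] <- data.frame(
      label = 0L, type = ct$name, x_um = x, y_um = y, a_um = a, b_um = b,
      theta = th, nucleus_frac = 0.45,
      incl_x_um = if (has_incl) x + ioff * cos(iphi) else NA_real_,
      incl_y_um = if (has_incl) y + ioff * sin(iphi) else NA_real_,
      incl_r_um = ir)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  cells <- do.call(rbind, out)
  cells$label <- seq_len(nrow(cells))
  cells
}

# squared normalized elliptical radius of points relative to one cell
ell_rho2 <- function(px, py, cell) {
  dx <- px - cell$x_um; dy <- py - cell$y_um
  u <- dx * cos(cell$theta) + dy * sin(cell$theta)
  v <- -dx * sin(cell$theta) + dy * cos(cell$theta)
  (u / cell$a_um)^2 + (v / cell$b_um)^2
}

render_label_mask <- function(cells, config) {
  px <- config$fm_pixel_um
  d <- round(rev(config$field_size_um) / px)   # (rows, cols)
  m <- matrix(0L, d[1], d[2])
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    bb <- cell_bbox(cell, d, px)
    if (is.null(bb)) next
    rho2 <- ell_rho2(bb$x, bb$y, cell)
    sel <- rho2 <= 1
    m[bb$idx[sel]] <- cell$label
  }
  label_mask(m, px, frame = "external_fm")
}

cell_bbox <- function(cell, d, px, extra = 0) {
  rmax <- max(cell$a_um, cell$b_um) + extra
  c0 <- max(1L, floor((cell$x_um - rmax) / px)); c1 <- min(d[2], ceiling((cell$x_um + rmax) / px))
  r0 <- max(1L, floor((cell$y_um - rmax) / px)); r1 <- min(d[1], ceiling((cell$y_um + rmax) / px))
  if (c1 < c0 || r1 < r0) return(NULL)
  g <- expand.grid(r = r0:r1, c = c0:c1)
  list(x = (g$c - 0.5) * px, y = (g$r - 0.5) * px,
       idx = (g$c - 1L) * d[1] + g$r)
}

render_fm_channels <- function(cells, config) {
  px <- config$fm_pixel_um
  d <- round(rev(config$field_size_um) / px)
  marker_ch <- c("TxRed", "Cy5", "Cy7")
  has_incl <- any(vapply(config$cell_types, function(ct)
    !is.null(ct$inclusion), logical(1)))
  ch_names <- c("DAPI", "FITC", marker_ch, if (has_incl) "Cy3")
  imgs <- lapply(ch_names, function(ch) matrix(0, d[1], d[2]))
  names(imgs) <- ch_names
  type_by_name <- stats::setNames(config$cell_types,
    vapply(config$cell_types, `[[`, character(1), "name"))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    ct <- type_by_name[[cell$type]]
    bb <- cell_bbox(cell, d, px)
    if (is.null(bb)) next
    rho2 <- ell_rho2(bb$x, bb$y, cell)
    inside <- rho2 <= 1
    nucleus <- rho2 <= cell$nucleus_frac^2
    cyto <- inside & !nucleus
    imgs$DAPI[bb$idx[nucleus]] <- imgs$DAPI[bb$idx[nucleus]] + 1
    imgs$FITC[bb$idx[cyto]] <- imgs$FITC[bb$idx[cyto]] + 0.8
    imgs$FITC[bb$idx[nucleus]] <- imgs$FITC[bb$idx[nucleus]] + 0.2
    for (mc in marker_ch) {
      lvl <- if (mc %in% ct$marker_channels) 1 else 0.05
      imgs[[mc]][bb$idx[inside]] <- imgs[[mc]][bb$idx[inside]] + lvl
    }
    if (!is.na(cell$incl_r_um) && "Cy3" %in% ch_names) {
      din <- sqrt((bb$x - cell$incl_x_um)^2 + (bb$y - cell$incl_y_um)^2)
      imgs$Cy3[bb$idx[din <= cell$incl_r_um]] <- 1
    }
  }
  if (config$noise$fm_sigma > 0)
    imgs <- lapply(imgs, function(im)
      pmax(im + matrix(stats::rnorm(length(im), 0, config$noise$fm_sigma),
                       nrow(im)), 0))
  mapply(function(im, nm) channel_image(im, px, "external_fm", nm),
         imgs, names(imgs), SIMPLIFY = FALSE)
}

render_msi <- function(cells, species, tf, config) {
  mpx <- config$msi_pixel_um
  d <- round(rev(config$field_size_um) / mpx)   # MSI grid (rows, cols)
  ss <- max(1L, round(mpx / config$fm_pixel_um))
  type_by_name <- stats::setNames(config$cell_types,
    vapply(config$cell_types, `[[`, character(1), "name"))
  tf_inv <- affine_invert(tf)

  # subpixel centres of every MSI pixel, in the msi frame
  g <- expand.grid(py = seq_len(d[1]), px = seq_len(d[2]))
  off <- (seq_len(ss) - 0.5) / ss
  sub <- expand.grid(oy = off, ox = off)
  n_px <- nrow(g); n_sub <- nrow(sub)
  sx <- rep((g$px - 1) * mpx, each = n_sub) + rep(sub$ox, n_px) * mpx
  sy <- rep((g$py - 1) * mpx, each = n_sub) + rep(sub$oy, n_px) * mpx
  ext <- affine_apply(tf_inv, cbind(sx, sy))    # into external frame
  pix_of_sub <- rep(seq_len(n_px), each = n_sub)
  sub_area <- (mpx / ss)^2

  inten <- matrix(0, n_px, nrow(species),
                  dimnames = list(NULL, species$species))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    ct <- type_by_name[[cell$type]]
    rmax2 <- max(cell$a_um, cell$b_um)
    near <- which(abs(ext[, 1] - cell$x_um) <= rmax2 &
                  abs(ext[, 2] - cell$y_um) <= rmax2)
    if (!length(near)) next
    inside <- near[ell_rho2(ext[near, 1], ext[near, 2], cell) <= 1]
    if (!length(inside)) next
    cov <- rowsum(rep(sub_area, length(inside)), pix_of_sub[inside])
    rows <- as.integer(rownames(cov))
    for (s in names(ct$species_profile))
      inten[rows, s] <- inten[rows, s] + ct$species_profile[[s]] * cov[, 1]
    if (!is.na(cell$incl_r_um)) {
      din2 <- (ext[near, 1] - cell$incl_x_um)^2 + (ext[near, 2] - cell$incl_y_um)^2
      insub <- near[din2 <= cell$incl_r_um^2]
      if (length(insub)) {
        covi <- rowsum(rep(sub_area, length(insub)), pix_of_sub[insub])
        rowsi <- as.integer(rownames(covi))
        for (s in names(ct$inclusion$species_profile))
          inten[rowsi, s] <- inten[rowsi, s] +
            ct$inclusion$species_profile[[s]] * covi[, 1]
      }
    }
  }

  # noise-free truth table
  nz <- which(inten > 0, arr.ind = TRUE)
  pixel_truth <- data.frame(px = g$px[nz[, 1]], py = g$py[nz[, 1]],
                            species = species$species[nz[, 2]],
                            intensity = inten[nz])

  noisy <- inten
  scale <- config$noise$msi_poisson_scale
  if (scale > 0 && length(inten))
    noisy[] <- stats::rpois(length(inten), inten / scale) * scale

  nzn <- which(noisy > 0, arr.ind = TRUE)
  jit <- config$noise$mz_jitter_ppm
  mz0 <- species$mz[nzn[, 2]]
  mz <- mz0 * (1 + if (jit > 0)
    stats::runif(length(mz0), -jit, jit) * 1e-6 else 0)
  peaks <- data.frame(px = g$px[nzn[, 1]], py = g$py[nzn[, 1]],
                      mz = mz, intensity = noisy[nzn])
  peaks <- peaks[order(peaks$px, peaks$py, peaks$mz), ]
  rownames(peaks) <- NULL
  list(msi = msi_dataset(peaks, d, mpx, frame = "msi"),
       pixel_truth = pixel_truth)
}

#' Generate a defocus image stack over a focal plane
#'
#' Blur grows linearly with defocus: the image at stage position z is
#' the sharp image convolved with a Gaussian of
#' `sigma = blur_sigma_per_um * |z - focal_z|` pixels; the image at the
#' focal position itself is returned unchanged.
#'
#' @param sharp_image in-focus image (matrix).
#' @param z_list stage z positions (um), nonempty.
#' @param focal_z true focal position (um).
#' @param blur_sigma_per_um blur growth rate (px per um of defocus).
#' @return named list of images, one per z.
#' @export
generate_defocus_stack <- function(sharp_image, z_list, focal_z,
                                   blur_sigma_per_um = 2) {
  if (!length(z_list)) stop("generate_defocus_stack: empty z list")
  out <- lapply(z_list, function(z) {
    s <- blur_sigma_per_um * abs(z - focal_z)
    if (s < 1e-9) sharp_image else gaussian_blur(sharp_image, s)
  })
  names(out) <- format(z_list)
  out
}

# separable Gaussian convolution with edge replication; tolerates
# kernels wider than the image (heavy defocus of small fields)
gaussian_blur <- function(img, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  blur_rows <- function(m) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (o in -h:h)
      acc <- acc + w[o + h + 1] * m[pmin(pmax(seq_len(nrow(m)) + o, 1),
                                         nrow(m)), , drop = FALSE]
    acc
  }
  t(blur_rows(t(blur_rows(img))))
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
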