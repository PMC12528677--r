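#' End-to-end pipeline driver
#'
#' Runs the full workflow in acquisition order — microscopy math,
#' co-registration, segmentation, single-cell spectrum compilation,
#' annotation, classification/clustering and neighborhood analysis —
#' on a synthetic phantom (or user-supplied inputs), writing every
#' stage artifact plus a provenance log into an output directory.
#'
#' @name pipeline
NULL

#' Assemble a pipeline configuration
#'
#' @param output_dir artifact directory (created if missing).
#' @param seed global seed propagated to every stochastic stage.
#' @param phantom list of [phantom_config()] arguments (the pipeline's
#'   built-in data source), or `NULL` when `inputs` are given.
#' @param inputs optional list(`msi` = path, `channels` = named TIFF
#'   paths, `fm_pixel_um`, `mask` = optional label-mask TIFF).
#' @param registration [mi_registration_params()] list.
#' @param annotation list(`mode`, `tolerance_ppm`).
#' @param clustering list(`k`, `eps`, `min_pts`).
#' @param neighborhood list(`radius_um`, `tme_radius_um`).
#' @export
pipeline_config <- function(output_dir, seed = 1L, phantom = list(),
                            inputs = NULL,
                            registration = mi_registration_params(),
                            annotation = list(mode = "positive",
                                              tolerance_ppm = 3),
                            clustering = list(k = 4, eps = 0.7, min_pts = 7),
                            neighborhood = list(radius_um = 15,
                                                tme_radius_um = 40)) {
  list(output_dir = output_dir, seed = as.integer(seed), phantom = phantom,
       inputs = inputs, registration = registration,
       annotation = annotation, clustering = clustering,
       neighborhood = neighborhood)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the pipeline
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return invisibly, the artifact directory; a `log.json` there
#'   records the configuration hash, seed, package version and
#'   per-stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$output_dir
  if (is.null(out)) stop("pipeline config lacks output_dir")
  if (!is.null(config$inputs)) {
    missing <- Filter(function(p) is.character(p) && !file.exists(p),
                      unlist(config$inputs))
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("scmsi")),
              r_version = R.version.string,
              config_hash = config_hash(config),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  stage <- function(name, params) {
    log$stages[[name]] <<- list(params = params)
  }

  ## data source -------------------------------------------------------
  if (is.null(config$inputs)) {
    ph_args <- config$phantom
    ph_args$seed <- config$seed
    cfg <- do.call(phantom_config, ph_args)
    ph <- generate_phantom(cfg)
    msi <- ph$msi
    channels <- ph$fm_channels
    stage("simulate", list(n_cells = cfg$n_cells,
                           field_size_um = cfg$field_size_um))
    write_msi_csv(msi, file.path(out, "msi.csv"))
    for (nm in names(channels))
      write_channel_tiff(channels[[nm]],
                         file.path(out, paste0("fm_", nm, ".tiff")),
                         max_value = max(unlist(lapply(channels, max)), 1))
  } else {
    ph <- NULL
    msi <- read_msi(config$inputs$msi)
    channels <- lapply(names(config$inputs$channels), function(nm)
      read_channel_tiff(config$inputs$channels[[nm]],
                        config$inputs$fm_pixel_um, channel = nm))
    names(channels) <- names(config$inputs$channels)
    stage("load", config$inputs)
  }

  ## microscopy: autofocus + focal surface on the phantom scene --------
  if (!is.null(ph)) {
    af_pts <- expand.grid(x_um = c(30, 120), y_um = c(30, 120))
    scene <- unclass(channels$DAPI)
    af_pts$z_um <- vapply(seq_len(nrow(af_pts)), function(i) {
      true_z <- ph$truth$focal_surface(af_pts$x_um[i], af_pts$y_um[i])
      reader <- function(z) {
        generate_defocus_stack(scene, z, true_z)[[1]]
      }
      as.numeric(autofocus(reader, focus_scan(c(0, 6))))
    }, numeric(1))
    surf <- fit_focal_surface(af_pts)
    mesh <- focal_mesh(surf, c(0, 150, 0, 150))
    utils::write.csv(mesh, file.path(out, "focal_mesh.csv"),
                     row.names = FALSE)
    stage("focus", list(points = nrow(af_pts), mesh_nodes = nrow(mesh)))
  }

  ## registration ------------------------------------------------------
  if (!is.null(ph)) {
    pair <- phantom_registration_pair(ph)
    lm <- phantom_landmarks(ph, 11)
  } else {
    stop("registration from external inputs requires landmark files; ",
         "run the stages individually")
  }
  init <- landmark_init(lm, from = "insource_fm", to = "external_fm")
  reg_params <- config$registration
  reg_params$seed <- config$seed
  tf_reg <- register_mi(pair$fixed, pair$moving, init, reg_params)
  tre <- target_registration_error(lm, tf_reg)
  write_transform_json(tf_reg, file.path(out, "transform.json"))
  stage("register", list(mean_tre_um = tre$mean,
                         converged = isTRUE(attr(tf_reg, "converged"))))

  ## segmentation ------------------------------------------------------
  mask <- fallback_segment(channels$DAPI, channels$FITC)
  morpho <- morphometrics(mask, channels)
  utils::write.csv(morpho, file.path(out, "morphometrics.csv"),
                   row.names = FALSE)
  write_mask_tiff(mask, file.path(out, "mask.tiff"))
  stage("segment", list(n_cells = nrow(morpho)))

  ## annotation --------------------------------------------------------
  ms <- rasterize_spectrum(mean_spectrum(msi))
  pk <- remove_isotopes(pick_peaks(ms))
  hits <- match_library(pk, default_lipid_library(),
                        mode = config$annotation$mode,
                        tolerance_ppm = config$annotation$tolerance_ppm)
  utils::write.csv(hits, file.path(out, "annotations.csv"),
                   row.names = FALSE)
  species <- unique(data.frame(species = hits$species,
                               mz = hits$theoretical_mz))
  stage("annotate", list(n_peaks = nrow(pk), n_hits = nrow(hits),
                         n_species = nrow(species)))

  ## single-cell compilation -------------------------------------------
  msi_grid <- list(dims = msi$dims, pixel_size_um = msi$pixel_size_um)
  coverage <- project_masks(mask, tf_reg, msi_grid)
  cells <- compile_spectra(msi, coverage, species,
                           config$annotation$tolerance_ppm)
  cells_norm <- normalize_cells(cells, species$species)
  utils::write.csv(cells_norm, file.path(out, "cell_spectra.csv"),
                   row.names = FALSE)
  stage("compile", list(n_cells = nrow(cells),
                        n_covered_pixels = length(unique(
                          paste(coverage$px, coverage$py)))))

  ## classification / clustering ---------------------------------------
  classes <- classify_cells(morpho)
  names(classes) <- morpho$label
  keep <- !cells_norm$flag_empty & cells_norm$label %in% morpho$label
  feat <- as.matrix(cells_norm[keep, species$species, drop = FALSE])
  rownames(feat) <- cells_norm$label[keep]
  is_ly6g <- classes[rownames(feat)] %in% c("Ly6G+", "DcTRAIL-R1+")
  tme <- NULL; subtype <- NULL
  if (sum(!is_ly6g) >= config$clustering$k) {
    tme_lab <- cluster_tme(feat[!is_ly6g, , drop = FALSE],
                           k = config$clustering$k, seed = config$seed)
    tme <- stats::setNames(as.integer(tme_lab),
                           rownames(feat)[!is_ly6g])
  }
  if (sum(is_ly6g) >= config$clustering$min_pts) {
    st <- subtype_cells(feat[is_ly6g, , drop = FALSE],
                        eps = config$clustering$eps,
                        min_pts = config$clustering$min_pts,
                        seed = config$seed)
    subtype <- stats::setNames(st$labels, rownames(feat)[is_ly6g])
  }
  utils::write.csv(
    data.frame(label = names(classes), class = as.character(classes),
               tme = if (is.null(tme)) NA else tme[names(classes)],
               subtype = if (is.null(subtype)) NA
                         else subtype[names(classes)]),
    file.path(out, "cell_labels.csv"), row.names = FALSE)
  stage("classify", list(table = as.list(table(classes)),
                         n_tme = length(unique(tme)),
                         n_subtypes = length(unique(subtype[subtype > 0]))))

  ## neighborhood + summary --------------------------------------------
  nb <- neighborhood_counts(mask, classes,
                            radius_um = config$neighborhood$radius_um)
  utils::write.csv(nb, file.path(out, "neighborhood.csv"),
                   row.names = FALSE)
  summ <- NULL
  if (!is.null(tme) && !is.null(subtype) && length(subtype)) {
    tme_assign <- assign_tme(mask, as.integer(names(subtype)), tme,
                             radius_um = config$neighborhood$tme_radius_um)
    summ <- summary_matrix(subtype, tme_assign, classes, tme, nb)
    utils::write.csv(as.data.frame(summ$counts),
                     file.path(out, "summary_matrix.csv"))
  }
  stage("neighborhood", list(radius_um = config$neighborhood$radius_um))

  render_cell_map(mask, classes, file.path(out, "cell_map.png"))

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(out, "log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "output_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  # small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Render a colored cell map
#'
#' Cells are filled with a color per class/cluster and written as PNG
#' (the projection-style figure of classified masks).
#'
#' @param mask a [label_mask()].
#' @param labels factor/character per cell label (named by label).
#' @param path output PNG.
#' @param palette named colors per level (defaults chosen
#'   automatically).
#' @export
render_cell_map <- function(mask, labels, path, palette = NULL) {
  lv <- sort(unique(as.character(labels)))
  if (is.null(palette))
    palette <- stats::setNames(grDevices::hcl.colors(max(3, length(lv)),
                                                     "Dark 3")[seq_along(lv)], lv)
  m <- unclass(mask)
  rgb_arr <- array(0.12, c(nrow(m), ncol(m), 3))   # dark background
  if (is.null(names(labels))) names(labels) <- sort(unique(m[m > 0]))
  for (lb in names(labels)) {
    col <- grDevices::col2rgb(palette[[as.character(labels[[lb]])]]) / 255
    sel <- m == as.integer(lb)
    for (k in 1:3) {
      plane <- rgb_arr[, , k]; plane[sel] <- col[k]; rgb_arr[, , k] <- plane
    }
  }
  grDevices::png(path, width = ncol(m), height = nrow(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(rgb_arr, 0, 0, 1, 1, interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
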