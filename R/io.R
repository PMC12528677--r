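#' File formats
#'
#' MSI datacubes are exchanged as imzML (processed mode: one peak list
#' per pixel, XML index plus binary `.ibd` arrays) or as a plain CSV
#' dialect (`x,y,mz,intensity`) kept for inspectability. Images travel
#' as TIFF (16-bit channels, 32-bit label masks).
#'
#' @name io
NULL

#' Write / read an MSI dataset as CSV exchange format
#'
#' Columns `x`, `y` (1-based pixel indices), `mz`, `intensity`; a
#' header comment records grid dimensions, pixel size and frame.
#'
#' @param msi an [msi_dataset()].
#' @param path output path.
#' @export
write_msi_csv <- function(msi, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# msi_csv nrow=%d ncol=%d pixel_size_um=%.9g frame=%s",
                     msi$dims[1], msi$dims[2], msi$pixel_size_um, msi$frame),
             con)
  utils::write.csv(
    data.frame(x = msi$peaks$px, y = msi$peaks$py,
               mz = msi$peaks$mz, intensity = msi$peaks$intensity),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msi_csv
#' @export
read_msi_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# msi_csv ", hdr))
    stop("not an MSI CSV exchange file (missing header): ", path)
  field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) stop("malformed MSI CSV header: missing ", key)
    sub(paste0(key, "="), "", m)
  }
  df <- utils::read.csv(path, skip = 1)
  need <- c("x", "y", "mz", "intensity")
  if (!all(need %in% names(df)))
    stop("malformed MSI CSV: expected columns x,y,mz,intensity")
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("malformed coordinate record at data line ", bad[1], " of ", path)
  msi_dataset(data.frame(px = df$x, py = df$y, mz = df$mz,
                         intensity = df$intensity),
              dims = c(as.integer(field("nrow")), as.integer(field("ncol"))),
              pixel_size_um = as.numeric(field("pixel_size_um")),
              frame = field("frame"))
}

#' Write an MSI dataset as imzML (processed mode)
#'
#' Emits `<path>.imzML` (XML index) and `<path>.ibd` (binary arrays,
#' 64-bit floats, little endian) with matching UUIDs. One spectrum per
#' pixel with its own m/z and intensity arrays, as in processed-mode
#' imzML.
#'
#' @param msi an [msi_dataset()].
#' @param path output path without extension.
#' @return the `.imzML` path.
#' @export
write_msi_imzml <- function(msi, path) {
  path <- sub("\\.imzML$", "", path)
  uuid <- as.raw(sample.int(256, 16, replace = TRUE) - 1L)
  ibd <- file(paste0(path, ".ibd"), "wb")
  writeBin(uuid, ibd)
  off <- 16
  key <- interaction(msi$peaks$px, msi$peaks$py, drop = TRUE)
  groups <- split(seq_len(nrow(msi$peaks)), key)
  specs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    mz <- msi$peaks$mz[rows]; int <- msi$peaks$intensity[rows]
    writeBin(as.numeric(mz), ibd, size = 8, endian = "little")
    writeBin(as.numeric(int), ibd, size = 8, endian = "little")
    specs[[i]] <- list(x = msi$peaks$px[rows[1]], y = msi$peaks$py[rows[1]],
                       n = length(mz), mz_offset = off,
                       int_offset = off + 8 * length(mz))
    off <- off + 16 * length(mz)
  }
  close(ibd)
  uuid_str <- paste0(format(uuid), collapse = "")
  sp_xml <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, s$n, s$x, s$y, s$mz_offset, s$n, s$int_offset, s$n)
  }, character(1))
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            uuid_str),
    '</fileContent></fileDescription>',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            msi$dims[2]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            msi$dims[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%.9g"/>',
            msi$pixel_size_um),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%.9g"/>',
            msi$pixel_size_um),
    '</scanSettings></scanSettingsList>',
    sprintf('<run id="run1" frame="%s"><spectrumList count="%d">', msi$frame,
            length(specs)),
    sp_xml,
    '</spectrumList></run></mzML>')
  writeLines(xml, paste0(path, ".imzML"))
  invisible(paste0(path, ".imzML"))
}

#' Read a processed-mode imzML file
#' @param path `.imzML` path (`.ibd` expected alongside).
#' @export
read_msi_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ibd_path <- sub("\\.imzML$", ".ibd", path)
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  cvnum <- function(node, acc) {
    as.numeric(xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc)),
      "value"))
  }
  nx <- cvnum(doc, "IMS:1000042"); ny <- cvnum(doc, "IMS:1000043")
  pxs <- cvnum(doc, "IMS:1000046")
  frame <- xml2::xml_attr(xml2::xml_find_first(doc, ".//run"), "frame")
  if (is.na(frame)) frame <- "msi"
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  pk <- lapply(specs, function(s) {
    x <- cvnum(s, "IMS:1000050"); y <- cvnum(s, "IMS:1000051")
    arrs <- xml2::xml_find_all(s, ".//binaryDataArray")
    read_arr <- function(a) {
      offs <- cvnum(a, "IMS:1000102"); len <- cvnum(a, "IMS:1000103")
      seek(ibd, offs)
      readBin(ibd, "numeric", n = len, size = 8, endian = "little")
    }
    is_mz <- vapply(arrs, function(a)
      length(xml2::xml_find_all(a, ".//cvParam[@accession='MS:1000514']")) > 0,
      logical(1))
    mz <- read_arr(arrs[is_mz][[1]]); int <- read_arr(arrs[!is_mz][[1]])
    if (!length(mz)) return(NULL)
    data.frame(px = x, py = y, mz = mz, intensity = int)
  })
  pk <- do.call(rbind, pk)
  if (is.null(pk)) pk <- data.frame(px = integer(), py = integer(),
                                    mz = numeric(), intensity = numeric())
  msi_dataset(pk, dims = c(ny, nx), pixel_size_um = pxs, frame = frame)
}

#' Read or write an MSI dataset, dispatching on file extension
#' @param path `.imzML` or `.csv` path.
#' @export
read_msi <- function(path) {
  if (grepl("\\.imzML$", path, ignore.case = TRUE)) read_msi_imzml(path)
  else read_msi_csv(path)
}

#' @rdname read_msi
#' @param msi an [msi_dataset()].
#' @export
write_msi <- function(msi, path) {
  if (grepl("\\.imzML$", path, ignore.case = TRUE))
    write_msi_imzml(msi, path)
  else write_msi_csv(msi, path)
}

#' Write / read a channel image as 16-bit TIFF
#'
#' Intensities are scaled by `max_value` into [0, 1] for storage.
#'
#' @param img a [channel_image()].
#' @param path file path.
#' @param max_value full-scale intensity.
#' @export
write_channel_tiff <- function(img, path, max_value = max(img, 1)) {
  tiff::writeTIFF(pmin(pmax(unclass(img) / max_value, 0), 1), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @param pixel_size_um,frame,channel metadata to attach on read.
#' @export
read_channel_tiff <- function(path, pixel_size_um, frame = "external_fm",
                              channel = NA_character_, max_value = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  channel_image(m * max_value, pixel_size_um, frame, channel)
}

#' Write / read a label mask as TIFF (32-bit float of integer labels)
#' @param mask a [label_mask()].
#' @param path file path.
#' @export
write_mask_tiff <- function(mask, path) {
  # 32-bit samples are stored as round(v * (2^32 - 1))
  tiff::writeTIFF(unclass(mask) / (2^32 - 1), path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_size_um,frame metadata to attach on read.
#' @export
read_mask_tiff <- function(path, pixel_size_um, frame = "external_fm") {
  m <- tiff::readTIFF(path)
  label_mask(matrix(as.integer(round(m * (2^32 - 1))), nrow(m)),
             pixel_size_um, frame)
}
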