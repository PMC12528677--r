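#' Accurate-mass lipid annotation
#'
#' Ion signals from the mean spectrum are annotated by accurate mass
#' against a library of molecular formulas: peaks with S/N > 3 are
#' extracted, isotope peaks removed, and the remaining monoisotopic
#' peaks matched within a 3 ppm window to the theoretical m/z of the
#' allowed adducts of each library species, with ion-mode curation
#' rules applied (e.g. glycerophosphoinositols are not expected in
#' positive ion mode).
#'
#' @name annotation
NULL

# Most-abundant-isotope masses (Da). At a 3 ppm matching window the
# electron mass matters, so ion m/z are computed with explicit electron
# correction rather than by adding nominal hydrogen.
.monoiso <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Fe = 55.9349375
)

.electron_mass <- 0.00054857990907
.proton_mass <- .monoiso[["H"]] - .electron_mass
.h2o_mass <- 2 * .monoiso[["H"]] + .monoiso[["O"]]

#' Parse a molecular formula string into an element-count vector
#'
#' Supported elements: C, H, N, O, P, S, Na, K, Fe. Counts default to 1
#' when omitted (`CH4` = C1H4).
#'
#' @param formula string such as `"C46H80NO8P"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.monoiso)) stop("unsupported element: ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Format an element-count vector back to a formula string
#' @param counts named integer vector as returned by [parse_formula()].
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#' @param formula formula string or parsed count vector.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.monoiso[names(counts)] * counts)
}

#' Adduct definitions for singly charged ions
#'
#' Each adduct carries the neutral-mass delta and the charge sign; the
#' electron correction is applied in [adduct_mz()]. `[M]+.` is the
#' radical molecular ion observed for dyes (Hoechst 33342) and heme B.
#'
#' @return data.frame with columns `name`, `delta` (Da added to the
#'   neutral monoisotopic mass, electrons not yet counted), `charge`
#'   and `mode`.
#' @export
adduct_table <- function() {
  data.frame(
    name  = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H2O+H]+", "[M-H]-", "[M]+."),
    delta = c(.monoiso[["H"]], .monoiso[["Na"]], .monoiso[["K"]],
              .monoiso[["H"]] - .h2o_mass, -.monoiso[["H"]], 0),
    charge = c(1L, 1L, 1L, 1L, -1L, 1L),
    mode = c("positive", "positive", "positive", "positive",
             "negative", "positive"),
    stringsAsFactors = FALSE)
}

#' Theoretical m/z of an adduct ion
#'
#' `m/z = neutral + delta - charge * electron_mass` for the singly
#' charged adducts supported here.
#'
#' @param neutral_mass monoisotopic mass of the neutral species (Da).
#' @param adduct adduct name (a row of [adduct_table()]).
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (any(is.na(i))) stop("unknown adduct: ", paste(adduct[is.na(i)], collapse = ", "))
  neutral_mass + tab$delta[i] - tab$charge[i] * .electron_mass
}

#' Peak-picking parameters
#'
#' @param snr_threshold minimum signal-to-noise ratio (default 3).
#' @param noise_window_mz width (Da) of the sliding window used for the
#'   local noise estimate.
#' @param isotope_spacing_da spacing of the isotope pattern
#'   (1.00336 Da, the C13-C12 mass difference).
#' @param isotope_ppm relative window when matching isotope spacings.
#' @export
peak_pick_params <- function(snr_threshold = 3, noise_window_mz = 20,
                             isotope_spacing_da = 1.00336, isotope_ppm = 20) {
  stopifnot(snr_threshold > 0, noise_window_mz > 0)
  list(snr_threshold = snr_threshold, noise_window_mz = noise_window_mz,
       isotope_spacing_da = isotope_spacing_da, isotope_ppm = isotope_ppm)
}

#' Rasterize a centroid peak list into a dense profile spectrum
#'
#' Deposits each centroid as a Gaussian of the stated resolving-power
#' width onto a regular m/z axis. Used to turn sparse per-dataset mean
#' peak lists into profile spectra on which S/N peak extraction is
#' meaningful.
#'
#' @param spectrum data.frame `mz`, `intensity` (centroids).
#' @param step_da axis spacing in Da.
#' @param fwhm_ppm peak full width at half maximum, relative.
#' @param pad_da axis padding beyond the outermost centroids.
#' @return data.frame `mz`, `intensity` on the dense axis.
#' @export
rasterize_spectrum <- function(spectrum, step_da = 0.005, fwhm_ppm = 20,
                               pad_da = 2) {
  if (!nrow(spectrum))
    return(data.frame(mz = numeric(), intensity = numeric()))
  axis <- seq(min(spectrum$mz) - pad_da, max(spectrum$mz) + pad_da,
              by = step_da)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(spectrum))) {
    s <- fwhm_ppm * 1e-6 * spectrum$mz[i] / 2.3548
    j <- which(abs(axis - spectrum$mz[i]) < 5 * s)
    y[j] <- y[j] + spectrum$intensity[i] *
      exp(-(axis[j] - spectrum$mz[i])^2 / (2 * s^2))
  }
  data.frame(mz = axis, intensity = y)
}

#' Extract peaks with S/N above threshold from a mean spectrum
#'
#' Local maxima of the intensity trace are scored against a robust
#' local noise estimate (1.4826 x median absolute deviation of the
#' intensities inside a sliding m/z window); maxima with
#' S/N > `snr_threshold` are returned.
#'
#' @param spectrum data.frame with columns `mz` (sorted ascending) and
#'   `intensity`.
#' @param params a [peak_pick_params()] list.
#' @return data.frame `mz`, `intensity`, `snr`.
#' @export
pick_peaks <- function(spectrum, params = peak_pick_params()) {
  mz <- spectrum$mz; y <- spectrum$intensity
  n <- length(y)
  if (n < 3) return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  if (is.unsorted(mz)) stop("spectrum must be sorted by m/z")
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  half <- params$noise_window_mz / 2
  snr <- vapply(idx, function(i) {
    w <- y[mz >= mz[i] - half & mz <= mz[i] + half]
    noise <- stats::mad(w)            # 1.4826 * MAD, Gaussian-consistent
    if (noise <= 0) noise <- stats::sd(w)
    if (!is.finite(noise) || noise <= 0) return(Inf)
    (y[i] - stats::median(w)) / noise
  }, numeric(1))
  keep <- snr > params$snr_threshold
  kidx <- idx[keep]
  # refine apex m/z by a parabola through the log-intensities of the
  # apex and its direct neighbours (exact for Gaussian peak shapes)
  mz_ref <- vapply(kidx, function(i) {
    if (i <= 1 || i >= n || y[i - 1] <= 0 || y[i + 1] <= 0 || y[i] <= 0)
      return(mz[i])
    la <- log(y[i - 1]); lb <- log(y[i]); lc <- log(y[i + 1])
    den <- la - 2 * lb + lc
    if (den >= 0) return(mz[i])
    mz[i] + 0.5 * (la - lc) / den * (mz[i + 1] - mz[i])
  }, numeric(1))
  data.frame(mz = mz_ref, intensity = y[kidx], snr = snr[keep])
}

#' Remove isotope peaks from a peak list
#'
#' A peak sitting +n x 1.00336 Da (n = 1, 2) above a more intense peak,
#' within the relative isotope window, is taken to be an isotopologue
#' and removed.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param params a [peak_pick_params()] list.
#' @export
remove_isotopes <- function(peaks, params = peak_pick_params()) {
  if (nrow(peaks) < 2) return(peaks)
  o <- order(peaks$mz)
  pk <- peaks[o, ]
  drop <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    for (n in 1:2) {
      target <- pk$mz[i] - n * params$isotope_spacing_da
      tol <- params$isotope_ppm * 1e-6 * pk$mz[i]
      j <- which(abs(pk$mz - target) <= tol & pk$intensity > pk$intensity[i] & !drop)
      if (length(j)) { drop[i] <- TRUE; break }
    }
  }
  pk[!drop, , drop = FALSE]
}

#' Built-in lipid library
#'
#' Species reported in the intended acquisitions, with explicit bulk
#' formulas (isomers within a lipid class are not distinguishable by
#' accurate mass alone).
#'
#' @return data.frame `name`, `class`, `formula`, `adducts`
#'   (semicolon-separated allowed adducts).
#' @export
default_lipid_library <- function() {
  path <- system.file("extdata", "lipid_library.csv", package = "scmsi")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Lipid classes not expected in a given ion mode
#'
#' Positive-mode spectra of the matrix/instrument combination at hand do
#' not plausibly show glycerophosphoinositols or other acidic classes;
#' negative mode shows neither triacylglycerols nor the neutral sterols,
#' nor the cationic dyes.
#' @param mode `"positive"` or `"negative"`.
#' @export
mode_excluded_classes <- function(mode) {
  switch(match.arg(mode, c("positive", "negative")),
         positive = c("PI", "PG", "PA", "PS"),
         negative = c("TG", "DG", "sterol", "dye", "heme"))
}

#' Match peaks against a formula library by accurate mass
#'
#' Every (species, adduct) pair whose theoretical m/z lies within
#' `tolerance_ppm` of a peak is reported, restricted to the adducts
#' allowed in `mode` and curated: classes not expected in the ion mode
#' are dropped, and species with an odd total acyl carbon number can be
#' flagged or dropped.
#'
#' @param peaks data.frame with column `mz` (and optionally `intensity`).
#' @param library data.frame like [default_lipid_library()].
#' @param mode `"positive"` or `"negative"`.
#' @param tolerance_ppm accurate-mass window (default 3 ppm).
#' @param drop_odd_chain drop species with odd total acyl carbons.
#' @return data.frame of hits (`observed_mz`, `species`, `class`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, `odd_chain`), ranked by
#'   |ppm error| within each peak.
#' @export
match_library <- function(peaks, library, mode = "positive",
                          tolerance_ppm = 3, drop_odd_chain = FALSE) {
  if (is.null(library) || !nrow(library)) stop("empty annotation library")
  mode <- match.arg(mode, c("positive", "negative"))
  tab <- adduct_table()
  excl <- mode_excluded_classes(mode)
  cand <- do.call(rbind, lapply(seq_len(nrow(library)), function(i) {
    adds <- trimws(strsplit(library$adducts[i], ";")[[1]])
    adds <- adds[adds %in% tab$name[tab$mode == mode]]
    if (!length(adds)) return(NULL)
    data.frame(species = library$name[i], class = library$class[i],
               adduct = adds,
               theoretical_mz = adduct_mz(monoisotopic_mass(library$formula[i]), adds),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) return(empty_hits())
  cand <- cand[!cand$class %in% excl, , drop = FALSE]
  hits <- do.call(rbind, lapply(peaks$mz, function(obs) {
    ppm <- (obs - cand$theoretical_mz) / cand$theoretical_mz * 1e6
    sel <- which(abs(ppm) < tolerance_ppm)
    if (!length(sel)) return(NULL)
    sel <- sel[order(abs(ppm[sel]))]
    data.frame(observed_mz = obs, cand[sel, , drop = FALSE],
               ppm_error = ppm[sel], row.names = NULL)
  }))
  if (is.null(hits)) return(empty_hits())
  names(hits)[names(hits) == "species"] <- "species"
  hits$odd_chain <- odd_chain_species(hits$species)
  if (drop_odd_chain) hits <- hits[!hits$odd_chain, , drop = FALSE]
  hits
}

empty_hits <- function() {
  data.frame(observed_mz = numeric(), species = character(),
             class = character(), adduct = character(),
             theoretical_mz = numeric(), ppm_error = numeric(),
             odd_chain = logical())
}

# An odd total acyl carbon count ("PE(33:1)") is biologically unusual in
# mammalian tissue and is flagged for curation.
odd_chain_species <- function(name) {
  m <- regmatches(name, regexpr("[0-9]+:[0-9]+", name))
  has <- grepl("[0-9]+:[0-9]+", name)
  out <- logical(length(name))
  out[has] <- as.integer(sub(":.*", "", m)) %% 2L == 1L
  out
}
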