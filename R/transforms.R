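#' 2-D affine transforms between named coordinate frames
#'
#' An `affine2d` maps point coordinates (x, y), in micrometres, from the
#' frame named `from` into the frame named `to` via `p' = A %*% p + t`.
#' The pipeline names its frames `"external_fm"` (slide-scanner image),
#' `"insource_fm"` and `"msi"`; the latter two share one coordinate
#' system, which is what makes the in-source image usable as a
#' registration intermediate.
#'
#' @param A 2x2 linear part (must be invertible).
#' @param t length-2 translation (micrometres).
#' @param from,to frame identifiers.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), t = c(0, 0), from = "a", to = "b") {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("affine2d: linear part is singular")
  structure(list(A = A, t = as.numeric(t), from = from, to = to),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d %s -> %s>\n", x$from, x$to))
  print(cbind(x$A, x$t))
  invisible(x)
}

#' Identity transform between two frames
#' @inheritParams affine2d
#' @export
affine_identity <- function(from = "a", to = from) affine2d(diag(2), c(0, 0), from, to)

#' Build an affine transform from rotation, scale and translation
#'
#' Rotation and isotropic scaling act about `center`; the translation is
#' applied afterwards. Used both to specify phantom misalignments and to
#' parameterise registration refinements.
#'
#' @param rotation_deg counter-clockwise rotation in degrees (y axis
#'   points down, so visually the rotation is clockwise).
#' @param scale isotropic scale factor.
#' @param translation_um length-2 shift in micrometres.
#' @param center_um centre of rotation/scaling in micrometres.
#' @inheritParams affine2d
#' @export
affine_from_params <- function(rotation_deg = 0, scale = 1,
                               translation_um = c(0, 0),
                               center_um = c(0, 0), from = "a", to = "b") {
  th <- rotation_deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- as.numeric(center_um) - R %*% as.numeric(center_um) + as.numeric(translation_um)
  affine2d(R, t, from, to)
}

#' Apply an affine transform to points
#' @param tf an `affine2d`.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine_apply <- function(tf, xy) {
  xy <- rbind2cols(xy)
  out <- xy %*% t(tf$A)
  out[, 1] <- out[, 1] + tf$t[1]
  out[, 2] <- out[, 2] + tf$t[2]
  out
}

#' Compose two transforms: `affine_compose(g, f)` applies `f` first
#' @param g,f `affine2d` objects with `f$to == g$from`.
#' @export
affine_compose <- function(g, f) {
  if (!identical(f$to, g$from))
    warning(sprintf("composing %s->%s after %s->%s: frame mismatch",
                    g$from, g$to, f$from, f$to))
  affine2d(g$A %*% f$A, as.numeric(g$A %*% f$t) + g$t, from = f$from, to = g$to)
}

#' Invert a transform
#' @param tf an `affine2d`.
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  affine2d(Ai, -as.numeric(Ai %*% tf$t), from = tf$to, to = tf$from)
}

#' Least-squares affine fit through point correspondences
#'
#' Solves for the affine transform minimising the summed squared
#' distance between `affine_apply(tf, src)` and `dst`. Exact for three
#' non-collinear pairs (the teaching-point case).
#'
#' @param src,dst n x 2 matrices, n >= 3 non-collinear points.
#' @inheritParams affine2d
#' @export
affine_fit <- function(src, dst, from = "a", to = "b") {
  src <- rbind2cols(src); dst <- rbind2cols(dst)
  if (nrow(src) < 3) stop("affine_fit needs at least 3 point pairs")
  X <- cbind(src, 1)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, dst)),
                   error = function(e) stop("affine_fit: points are collinear"))
  affine2d(t(beta[1:2, ]), beta[3, ], from, to)
}

#' Serialize / deserialize transforms as JSON
#' @param tf an `affine2d`.
#' @param path file path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(
    list(matrix = cbind(tf$A, tf$t), from = tf$from, to = tf$to),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- j$matrix
  if (is.null(dim(m))) m <- matrix(as.numeric(m), 2, 3, byrow = TRUE)
  affine2d(m[, 1:2], m[, 3], j$from, j$to)
}

rbind2cols <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2, byrow = TRUE)
  matrix(as.numeric(xy), ncol = 2, dimnames = NULL)
}
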