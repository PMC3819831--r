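#' Scalar image container
#'
#' A `scalar_image` is an n-dimensional (2-D or 3-D) grid of real-valued
#' intensities together with the physical voxel spacing and origin. It is
#' the unit both input images and warped images live on. Image coordinates
#' are 0-based and voxel-centered: voxel `(0, 0)` sits at coordinate
#' `(0, 0)`, and an image of shape `X` spans the half-open domain
#' `[0, X)` per axis.
#'
#' @param data numeric matrix (2-D) or 3-D array of finite intensities.
#' @param spacing positive physical voxel size per axis (e.g. millimetres);
#'   defaults to 1 per axis. Spacing is carried for unit conversion and
#'   format headers; all deformation arithmetic is in voxel units.
#' @param origin physical coordinate of voxel 0 per axis; defaults to 0.
#' @return an object of class `scalar_image` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' img <- scalar_image(matrix(runif(64), 8, 8))
#' img_shape(img)
#' @export
scalar_image <- function(data, spacing = NULL, origin = NULL) {
  if (is.null(dim(data))) stop("'data' must be a matrix or array")
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L)
    stop("scalar_image supports 2-D and 3-D data, got ", nd, " dimensions")
  if (!all(is.finite(data))) stop("image intensities must all be finite")
  storage.mode(data) <- "double"
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (is.null(origin)) origin <- rep(0, nd)
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive and finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_image")
}

#' @rdname scalar_image
#' @param image a `scalar_image`.
#' @export
img_shape <- function(image) dim(as_intensity_array(image))

#' Coerce to a plain intensity array
#'
#' Accepts a `scalar_image` or a bare matrix/array and returns the
#' underlying numeric array. Used throughout so that metric and overlay
#' functions work on either representation.
#'
#' @param x a `scalar_image`, matrix or array.
#' @return the numeric intensity array.
#' @export
as_intensity_array <- function(x) {
  if (inherits(x, "scalar_image")) return(x$data)
  if (is.null(dim(x))) stop("expected a scalar_image or an array")
  x
}

#' @export
print.scalar_image <- function(x, ...) {
  cat("<scalar_image> ", paste(dim(x$data), collapse = " x "),
      " | spacing ", paste(format(x$spacing), collapse = " x "),
      " | intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  da <- dim(as_intensity_array(a))
  db <- dim(as_intensity_array(b))
  if (length(da) != length(db) || any(da != db))
    stop("shape mismatch: ", what, " have shapes (",
         paste(da, collapse = ", "), ") and (",
         paste(db, collapse = ", "), ")")
  invisible(da)
}
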