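#' Sample an image at arbitrary coordinates
#'
#' Interpolates intensities at fractional 0-based voxel coordinates.
#' Coordinates outside the closed grid bounds `[0, dim-1]` on any axis are
#' invalid: they receive the fill value 0 and `valid = FALSE`. The valid
#' set defines the overlap region used by the SSD metric.
#'
#' Interpolators: `nearest` (round to the closest voxel), `linear`
#' (multilinear; exact at integer coordinates and range-preserving) and
#' `cubic` (Keys cubic convolution, a = -1/2; interpolating but not
#' range-preserving, border taps replicated).
#'
#' @param image a [scalar_image] or intensity array.
#' @param coords numeric matrix, one row per sample, one column per axis.
#' @param interpolation one of `"linear"`, `"nearest"`, `"cubic"`.
#' @return list with `values` (numeric vector) and `valid` (logical).
#' @export
sample_image <- function(image, coords,
                         interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  arr <- as_intensity_array(image)
  shp <- dim(arr)
  nd <- length(shp)
  if (ncol(coords) != nd)
    stop("coords have ", ncol(coords), " columns for a ", nd, "-D image")
  n <- nrow(coords)
  valid <- rep(TRUE, n)
  for (a in seq_len(nd))
    valid <- valid & is.finite(coords[, a]) &
      coords[, a] >= 0 & coords[, a] <= shp[a] - 1
  values <- numeric(n)
  if (any(valid)) {
    cv <- coords[valid, , drop = FALSE]
    values[valid] <- switch(interpolation,
                            nearest = sample_nearest(arr, cv),
                            linear = sample_linear(arr, cv),
                            cubic = sample_cubic(arr, cv))
  }
  list(values = values, valid = valid)
}

# flat 1-based index from per-axis 0-based integer index columns
flat_index <- function(shp, idx) {
  f <- idx[, 1]
  m <- 1
  for (a in seq_along(shp)[-1]) {
    m <- m * shp[a - 1]
    f <- f + idx[, a] * m
  }
  f + 1
}

sample_nearest <- function(arr, cv) {
  shp <- dim(arr)
  idx <- cv
  for (a in seq_along(shp))
    idx[, a] <- pmin(pmax(round(cv[, a]), 0), shp[a] - 1)
  arr[flat_index(shp, idx)]
}

sample_linear <- function(arr, cv) {
  shp <- dim(arr)
  nd <- length(shp)
  n <- nrow(cv)
  # clamp the anchor to dim-2 so u in [0,1]; exact at integer coordinates
  i0 <- matrix(0, n, nd)
  u <- matrix(0, n, nd)
  for (a in seq_len(nd)) {
    i0[, a] <- pmin(pmax(floor(cv[, a]), 0), shp[a] - 2)
    u[, a] <- cv[, a] - i0[, a]
  }
  out <- numeric(n)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    w <- rep(1, n)
    idx <- i0
    for (a in seq_len(nd)) {
      if (corners[r, a] == 1L) {
        w <- w * u[, a]
        idx[, a] <- i0[, a] + 1
      } else {
        w <- w * (1 - u[, a])
      }
    }
    out <- out + w * arr[flat_index(shp, idx)]
  }
  out
}

# Keys cubic convolution kernel, a = -1/2
keys_kernel <- function(s) {
  s <- abs(s)
  w <- numeric(length(s))
  near <- s < 1
  mid <- !near & s < 2
  w[near] <- 1.5 * s[near]^3 - 2.5 * s[near]^2 + 1
  w[mid] <- -0.5 * s[mid]^3 + 2.5 * s[mid]^2 - 4 * s[mid] + 2
  w
}

sample_cubic <- function(arr, cv) {
  shp <- dim(arr)
  nd <- length(shp)
  n <- nrow(cv)
  fl <- floor(cv)
  out <- numeric(n)
  taps <- as.matrix(do.call(expand.grid, rep(list(-1:2), nd)))
  for (r in seq_len(nrow(taps))) {
    w <- rep(1, n)
    idx <- matrix(0, n, nd)
    for (a in seq_len(nd)) {
      pa <- fl[, a] + taps[r, a]
      w <- w * keys_kernel(cv[, a] - pa)
      idx[, a] <- pmin(pmax(pa, 0), shp[a] - 1)  # replicate border
    }
    keep <- w != 0
    if (any(keep))
      out[keep] <- out[keep] + w[keep] * arr[flat_index(shp, idx[keep, , drop = FALSE])]
  }
  out
}

# 0-based voxel index along axis a for every element of an array of shape
# shp, in R's column-major element order.
grid_axis_coords <- function(shp, a) {
  n <- prod(shp)
  stride <- if (a == 1) 1 else prod(shp[seq_len(a - 1)])
  ((seq_len(n) - 1) %/% stride) %% shp[a]
}

#' Warp an image through a multilevel deformation
#'
#' Backward (pull-back) resampling: each output voxel `x` takes its
#' intensity from the input image at `x + T(x)` where `T` is the total
#' displacement of the deformation. Backward mapping leaves no holes;
#' the consequence is that adding displacement `+d` at a control point
#' moves image content approximately by `-d`, which is why recorded drag
#' events store the negated content motion (see [apply_event()]).
#' Samples falling outside the input grid get fill value 0 and are marked
#' invalid; the valid mask is the overlap region for SSD.
#'
#' @param image a [scalar_image] whose shape equals the deformation's
#'   domain.
#' @param deformation a [multilevel_deformation].
#' @param interpolation `"linear"` (default; range-preserving),
#'   `"nearest"`, or `"cubic"`.
#' @return list with `image` (warped [scalar_image]) and `valid` (logical
#'   array, TRUE where the sample came from inside the input grid).
#' @examples
#' img <- scalar_image(matrix(runif(32 * 32), 32, 32))
#' def <- multilevel_deformation(c(32, 32), 8)
#' w <- warp_image(img, def)          # identity: w$image equals img
#' @export
warp_image <- function(image, deformation,
                       interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(deformation, "multilevel_deformation"))
  arr <- as_intensity_array(image)
  shp <- dim(arr)
  if (length(shp) != length(deformation$domain_shape) ||
      any(shp != deformation$domain_shape))
    stop("shape mismatch: image is (", paste(shp, collapse = ", "),
         ") but deformation domain is (",
         paste(deformation$domain_shape, collapse = ", "), ")")
  nd <- length(shp)
  field <- render_dense_field(deformation)
  n <- prod(shp)
  coords <- matrix(0, n, nd)
  fvec <- as.vector(field)
  for (a in seq_len(nd))
    coords[, a] <- grid_axis_coords(shp, a) + fvec[((a - 1) * n + 1):(a * n)]
  s <- sample_image(arr, coords, interpolation)
  out <- array(s$values, shp)
  spc <- if (inherits(image, "scalar_image")) image$spacing else NULL
  org <- if (inherits(image, "scalar_image")) image$origin else NULL
  list(image = scalar_image(out, spacing = spc, origin = org),
       valid = array(s$valid, shp))
}

# Warp only the product grid given by coords_list (per-axis 0-based voxel
# coordinate vectors). Used for interaction-speed local updates around a
# single control point. Returns values and valid arrays of the region shape.
warp_region <- function(image, deformation, coords_list,
                        interpolation = "linear") {
  arr <- as_intensity_array(image)
  nd <- length(dim(arr))
  field <- render_region_field(deformation, coords_list)
  rshape <- vapply(coords_list, length, integer(1))
  n <- prod(rshape)
  coords <- matrix(0, n, nd)
  fvec <- as.vector(field)
  for (a in seq_len(nd)) {
    base <- coords_list[[a]][grid_axis_coords(rshape, a) + 1]
    coords[, a] <- base + fvec[((a - 1) * n + 1):(a * n)]
  }
  s <- sample_image(arr, coords, interpolation)
  list(values = array(s$values, rshape), valid = array(s$valid, rshape))
}

# Extract a sub-block of an array at per-axis 0-based coordinate vectors.
extract_region <- function(arr, coords_list) {
  args <- c(list(arr), lapply(coords_list, function(v) v + 1), list(drop = FALSE))
  do.call(`[`, args)
}
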