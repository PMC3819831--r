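#' Uniform cubic B-spline basis functions
#'
#' The four piecewise-cubic blending polynomials of the uniform cubic
#' B-spline, evaluated at the intra-cell fraction `u`:
#' \deqn{B_0(u) = (1-u)^3/6}
#' \deqn{B_1(u) = (3u^3 - 6u^2 + 4)/6}
#' \deqn{B_2(u) = (-3u^3 + 3u^2 + 3u + 1)/6}
#' \deqn{B_3(u) = u^3/6}
#' They are nonnegative and sum to one for every `u` in `[0, 1]`
#' (partition of unity), which is what makes a lattice of displacement
#' vectors blend into a smooth interpolating field. `u = 1` is accepted at
#' the closed upper boundary (`B_3(1) = 1/6`) so domain edges are well
#' defined; interior decomposition always yields fractions in `[0, 1)`.
#'
#' @param l basis index, a single integer in `0..3`.
#' @param u evaluation fraction(s) in `[0, 1]`; vectorized.
#' @return numeric vector of weights `B_l(u)`.
#' @examples
#' cubic_basis(0, 0)    # 1/6
#' sum(sapply(0:3, cubic_basis, u = 0.37))  # 1
#' @export
cubic_basis <- function(l, u) {
  if (length(l) != 1L || is.na(l) || l != as.integer(l) || l < 0 || l > 3)
    stop("basis index 'l' must be a single integer in 0..3, got ", format(l))
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("'u' must lie in [0, 1]")
  switch(as.character(as.integer(l)),
         "0" = (1 - u)^3 / 6,
         "1" = (3 * u^3 - 6 * u^2 + 4) / 6,
         "2" = (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
         "3" = u^3 / 6)
}

#' Decompose a lattice-space point into cell index and fraction
#'
#' A point expressed in lattice units (image coordinate divided by the
#' control-point spacing) decomposes per axis into the anchor control-point
#' index `i = floor(x) - 1` and the intra-cell fraction `u = x - floor(x)`.
#' The anchor is the first of the four control points `i .. i+3` whose
#' basis functions support the point, so `cell_index + 1 + fraction`
#' reconstructs the input exactly.
#'
#' @param point numeric vector, one lattice-space coordinate per axis.
#' @return a `lattice_coordinate`: list with integer `cell_index` and
#'   numeric `fraction` (each component in `[0, 1)`).
#' @examples
#' decompose_point(2.25)   # cell_index 1, fraction 0.25
#' decompose_point(c(0, 5.999))
#' @export
decompose_point <- function(point) {
  if (any(!is.finite(point))) stop("'point' must be finite")
  fl <- floor(point)
  structure(list(cell_index = as.integer(fl) - 1L, fraction = point - fl),
            class = "lattice_coordinate")
}

# Domain check shared by point evaluators: 0 <= x_a < X_a, error names axis.
check_in_domain <- function(point, domain_shape) {
  for (a in seq_along(domain_shape)) {
    if (!is.finite(point[a]) || point[a] < 0 || point[a] >= domain_shape[a])
      stop("point outside the image domain on axis ", a, ": coordinate ",
           format(point[a]), " not in [0, ", domain_shape[a], ")")
  }
  invisible(TRUE)
}

# column-major flat offset (0-based) of a 1-based multi-index
flat_offset <- function(grid_shape, st) {
  f <- st[1] - 1
  m <- 1
  for (a in seq_along(grid_shape)[-1]) {
    m <- m * grid_shape[a - 1]
    f <- f + (st[a] - 1) * m
  }
  f
}

#' Evaluate one lattice level's displacement at a point
#'
#' Tensor-product cubic B-spline evaluation: the displacement at image
#' coordinate `x` is the sum over the 4x4 (2-D) or 4x4x4 (3-D) neighboring
#' control points of the control displacement weighted by the product of
#' per-axis basis values,
#' \deqn{T(x) = \sum_{l=0}^{3}\sum_{m=0}^{3} B_l(u) B_m(v)\, \Phi_{i+l, j+m}}
#' with `i = floor(x/s) - 1`, `u = x/s - floor(x/s)` for spacing `s`.
#' Control displacements are vectors added to the identity map, so the
#' all-zero lattice is the identity transform. Only control points within
#' the local support influence the result.
#'
#' @param lattice a [control_lattice].
#' @param point image coordinate (0-based voxels), one value per axis;
#'   must lie within the image domain.
#' @return numeric displacement vector (voxels), one component per axis.
#' @seealso [total_displacement()] for the multilevel sum,
#'   [render_dense_field()] for whole-image evaluation.
#' @export
evaluate_level_displacement <- function(lattice, point) {
  stopifnot(inherits(lattice, "control_lattice"))
  nd <- length(lattice$domain_shape)
  if (length(point) != nd)
    stop("point has ", length(point), " components, lattice domain has ", nd)
  check_in_domain(point, lattice$domain_shape)
  dec <- decompose_point(point / lattice$spacing)
  w <- lapply(seq_len(nd), function(a)
    vapply(0:3, cubic_basis, numeric(1), u = dec$fraction[a]))
  gs <- lattice$grid_shape
  ncp <- prod(gs)
  dvec <- as.vector(lattice$displacements)
  disp <- numeric(nd)
  offsets <- as.matrix(do.call(expand.grid, rep(list(0:3), nd)))
  for (r in seq_len(nrow(offsets))) {
    wgt <- 1
    for (a in seq_len(nd)) wgt <- wgt * w[[a]][offsets[r, a] + 1L]
    if (wgt == 0) next
    st <- dec$cell_index + offsets[r, ] + 2L  # storage is lattice index + 2
    f0 <- flat_offset(gs, st)
    for (cc in seq_len(nd))
      disp[cc] <- disp[cc] + wgt * dvec[f0 + (cc - 1) * ncp + 1]
  }
  disp
}
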