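#' Create a control lattice
#'
#' A control lattice is one level's uniform mesh of control-point
#' displacement vectors overlaid on the image domain. Control points sit at
#' integer multiples of the spacing, with lattice indices running
#' `-1, 0, ..., N+1` per axis where `N = ceiling(domain / spacing)`; the
#' margin of one point beyond each boundary means evaluation near the edge
#' never indexes outside storage. A freshly created lattice is all zero:
#' the identity transform.
#'
#' @param domain_shape integer image shape (voxel counts per axis), all
#'   `>= 2`.
#' @param spacing control-point spacing in voxels, one positive value per
#'   axis (a scalar is recycled). Anisotropic spacing is allowed.
#' @param level hierarchy level this lattice belongs to (1 = coarsest).
#' @return an object of class `control_lattice` with fields `level`,
#'   `spacing`, `grid_shape`, `displacements` (array of shape
#'   `c(grid_shape, n_axes)`, units voxels) and `domain_shape`.
#' @examples
#' lat <- create_lattice(c(64, 64), 16)
#' lat$grid_shape  # 7 7: indices -1..5 per axis
#' @export
create_lattice <- function(domain_shape, spacing, level = 1L) {
  nd <- length(domain_shape)
  if (nd < 2L || nd > 3L) stop("domain must be 2-D or 3-D")
  domain_shape <- as.integer(domain_shape)
  if (any(domain_shape < 2L)) stop("each domain axis must have >= 2 voxels")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("control-point spacing must be positive, got (",
         paste(format(spacing), collapse = ", "), ")")
  if (length(level) != 1L || level < 1L) stop("'level' must be a positive integer")
  grid_shape <- as.integer(ceiling(domain_shape / spacing)) + 3L
  structure(list(level = as.integer(level),
                 spacing = spacing,
                 grid_shape = grid_shape,
                 displacements = array(0, dim = c(grid_shape, nd)),
                 domain_shape = domain_shape),
            class = "control_lattice")
}

# lattice index range per axis: -1 .. N+1
lattice_index_range <- function(lattice) {
  n_int <- lattice$grid_shape - 3L
  list(lower = rep(-1L, length(n_int)), upper = n_int + 1L)
}

check_lattice_index <- function(lattice, index) {
  nd <- length(lattice$domain_shape)
  if (length(index) != nd) stop("control-point index needs ", nd, " components")
  rng <- lattice_index_range(lattice)
  bad <- which(index < rng$lower | index > rng$upper)
  if (length(bad))
    stop("control-point index out of bounds on axis ", bad[1], ": ",
         index[bad[1]], " not in [", rng$lower[bad[1]], ", ",
         rng$upper[bad[1]], "]")
  invisible(TRUE)
}

#' Displace one control point
#'
#' Adds `delta` to the stored displacement of the control point at lattice
#' `index` (margin points included). Because cubic B-splines have local
#' support, this changes the blended displacement field only within the
#' 4-cell neighborhood of that control point. Moves at distinct indices
#' commute and moves at the same index add.
#'
#' @param lattice a [control_lattice].
#' @param index integer lattice index per axis, each in `-1..N+1`.
#' @param delta displacement increment (voxels), one component per axis.
#' @return the revised `control_lattice` (input is untouched).
#' @export
move_control_point <- function(lattice, index, delta) {
  stopifnot(inherits(lattice, "control_lattice"))
  check_lattice_index(lattice, index)
  nd <- length(lattice$domain_shape)
  if (length(delta) != nd) stop("'delta' needs ", nd, " components")
  if (any(!is.finite(delta))) stop("'delta' must be finite")
  st <- as.integer(index) + 2L
  idx <- cbind(matrix(st, nrow = nd, ncol = nd, byrow = TRUE), seq_len(nd))
  lattice$displacements[idx] <- lattice$displacements[idx] + as.numeric(delta)
  lattice
}

#' Get one control point's displacement
#'
#' @param lattice a [control_lattice].
#' @param index integer lattice index per axis.
#' @return numeric displacement vector at that control point.
#' @export
control_point <- function(lattice, index) {
  check_lattice_index(lattice, index)
  nd <- length(lattice$domain_shape)
  st <- as.integer(index) + 2L
  idx <- cbind(matrix(st, nrow = nd, ncol = nd, byrow = TRUE), seq_len(nd))
  as.numeric(lattice$displacements[idx])
}

#' @export
print.control_lattice <- function(x, ...) {
  cat("<control_lattice> level ", x$level, " | spacing (",
      paste(format(x$spacing), collapse = ", "), ") voxels | grid ",
      paste(x$grid_shape, collapse = " x "), " | max |disp| ",
      format(max(abs(x$displacements))), "\n", sep = "")
  invisible(x)
}

#' Refine a multilevel deformation by one level
#'
#' Appends a new zero-initialized control lattice whose spacing is exactly
#' half that of the finest existing level. Existing levels are untouched,
#' so the total displacement field is unchanged by refinement alone: the
#' finer grid only adds capacity for subsequent local revision. Refinement
#' below one voxel of spacing is refused, since a grid finer than the
#' image carries no usable detail.
#'
#' @param deformation a [multilevel_deformation].
#' @return the deformation with one more (finer, zero) level appended.
#' @export
refine <- function(deformation) {
  stopifnot(inherits(deformation, "multilevel_deformation"))
  finest <- deformation$levels[[length(deformation$levels)]]
  new_spacing <- finest$spacing / 2
  if (any(new_spacing < 1))
    stop("refusing to refine: halved spacing (",
         paste(format(new_spacing), collapse = ", "),
         ") would fall below one voxel")
  new_level <- create_lattice(deformation$domain_shape, new_spacing,
                              level = finest$level + 1L)
  deformation$levels <- c(deformation$levels, list(new_level))
  deformation
}
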