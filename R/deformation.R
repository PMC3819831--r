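#' Multilevel B-spline deformation
#'
#' An ordered hierarchy of control lattices with spacing halved per level;
#' the per-level displacement fields sum to the total local transform.
#' Coarse levels capture large misregistration with few degrees of
#' freedom, finer levels add local detail. A new deformation starts with a
#' single zero lattice (the identity); grow it with [refine()] and edit it
#' with [move_control_point()] or recorded session events.
#'
#' @param domain_shape integer image shape (voxels per axis).
#' @param spacing level-1 control-point spacing in voxels (scalar or per
#'   axis).
#' @return an object of class `multilevel_deformation` with fields
#'   `levels` (list of [control_lattice]) and `domain_shape`.
#' @examples
#' def <- multilevel_deformation(c(64, 64), 16)
#' def <- refine(def)
#' vapply(def$levels, function(l) l$spacing[1], numeric(1))  # 16 8
#' @export
multilevel_deformation <- function(domain_shape, spacing) {
  lat <- create_lattice(domain_shape, spacing, level = 1L)
  structure(list(levels = list(lat), domain_shape = lat$domain_shape),
            class = "multilevel_deformation")
}

# Rebuild a multilevel_deformation from a list of lattices, validating the
# shared domain and strict halving of spacings.
as_multilevel_deformation <- function(levels) {
  if (!length(levels)) stop("a deformation needs at least one level")
  dom <- levels[[1]]$domain_shape
  for (k in seq_along(levels)) {
    lt <- levels[[k]]
    if (!inherits(lt, "control_lattice")) stop("level ", k, " is not a control_lattice")
    if (!identical(lt$domain_shape, dom))
      stop("level ", k, " has a different domain shape")
    if (k > 1 && max(abs(levels[[k - 1]]$spacing - 2 * lt$spacing)) > 1e-9)
      stop("level spacings must halve exactly: level ", k - 1, " -> ", k)
  }
  structure(list(levels = levels, domain_shape = dom),
            class = "multilevel_deformation")
}

#' @export
print.multilevel_deformation <- function(x, ...) {
  cat("<multilevel_deformation> ", length(x$levels), " level(s) on domain ",
      paste(x$domain_shape, collapse = " x "), "\n", sep = "")
  for (l in x$levels)
    cat("  level ", l$level, ": spacing (",
        paste(format(l$spacing), collapse = ", "), "), grid ",
        paste(l$grid_shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Total displacement at a point
#'
#' The overall local transform of a multilevel deformation is the sum over
#' levels of each lattice's B-spline displacement at the point.
#'
#' @param deformation a [multilevel_deformation].
#' @param point image coordinate (0-based voxels) inside the domain.
#' @return numeric displacement vector (voxels).
#' @export
total_displacement <- function(deformation, point) {
  stopifnot(inherits(deformation, "multilevel_deformation"))
  disp <- numeric(length(deformation$domain_shape))
  for (lat in deformation$levels)
    disp <- disp + evaluate_level_displacement(lat, point)
  disp
}

# Per-axis basis weight matrix: rows = evaluation coordinates (voxels),
# cols = lattice storage indices. Row x holds B_0..B_3(u) at storage
# columns i+2 .. i+5 where i = floor(x/s) - 1. Separable evaluation of the
# tensor product reduces dense rendering to small matrix products.
axis_weight_matrix <- function(coords, spacing, grid_shape, domain_extent) {
  if (any(coords < 0 | coords >= domain_extent))
    stop("coordinates outside the image domain")
  t <- coords / spacing
  fl <- floor(t)
  i <- as.integer(fl) - 1L
  u <- t - fl
  W <- matrix(0, nrow = length(coords), ncol = grid_shape)
  rows <- seq_along(coords)
  for (l in 0:3)
    W[cbind(rows, i + l + 2L)] <- cubic_basis(l, u)
  W
}

# Contract a control-displacement component array (dims = grid_shape) with
# per-axis weight matrices, giving the field on the product grid of the
# supplied coordinate vectors.
contract_weights <- function(D, Ws) {
  nd <- length(Ws)
  for (a in seq_len(nd)) {
    d <- dim(D)
    perm <- c(a, seq_len(nd)[-a])
    Dp <- aperm(D, perm)
    m <- Ws[[a]] %*% matrix(Dp, nrow = d[a])
    D <- aperm(array(m, c(nrow(Ws[[a]]), d[perm[-1]])), order(perm))
  }
  D
}

# Field of one lattice level on the product grid coords_list (list of
# per-axis voxel coordinate vectors). Returns array c(lengths, nd).
render_level_region <- function(lattice, coords_list) {
  nd <- length(lattice$domain_shape)
  Ws <- lapply(seq_len(nd), function(a)
    axis_weight_matrix(coords_list[[a]], lattice$spacing[a],
                       lattice$grid_shape[a], lattice$domain_shape[a]))
  out <- array(0, c(vapply(coords_list, length, integer(1)), nd))
  for (cc in seq_len(nd)) {
    comp <- contract_weights(slice_component(lattice$displacements, cc), Ws)
    out <- assign_component(out, cc, comp)
  }
  out
}

slice_component <- function(arr, cc) {
  nd <- length(dim(arr)) - 1L
  if (nd == 2L) arr[, , cc] else arr[, , , cc]
}

assign_component <- function(arr, cc, value) {
  nd <- length(dim(arr)) - 1L
  if (nd == 2L) arr[, , cc] <- value else arr[, , , cc] <- value
  arr
}

# Summed multilevel field on a product grid of voxel coordinates.
render_region_field <- function(deformation, coords_list) {
  out <- NULL
  for (lat in deformation$levels) {
    f <- render_level_region(lat, coords_list)
    out <- if (is.null(out)) f else out + f
  }
  out
}

#' Render the dense displacement field
#'
#' Evaluates the multilevel deformation at every voxel center and returns
#' the displacement grid: an array of shape `c(domain_shape, n_axes)` whose
#' last dimension indexes the displacement component along each image
#' axis, in voxels. Rendering is separable (per-axis basis weights along
#' grid lines) and agrees with pointwise [total_displacement()] to
#' floating tolerance.
#'
#' @param deformation a [multilevel_deformation].
#' @param level optional single level number; renders that lattice alone.
#' @return a `dense_field` array of shape `c(domain_shape, n_axes)`.
#' @export
render_dense_field <- function(deformation, level = NULL) {
  stopifnot(inherits(deformation, "multilevel_deformation"))
  coords <- lapply(deformation$domain_shape, function(n) seq(0, n - 1))
  f <- if (is.null(level)) {
    render_region_field(deformation, coords)
  } else {
    if (level < 1 || level > length(deformation$levels))
      stop("no level ", level, " in this deformation")
    render_level_region(deformation$levels[[level]], coords)
  }
  structure(f, class = "dense_field")
}

#' Convert a displacement field from voxels to physical units
#'
#' Displacements are stored in voxels of the image grid; multiply each
#' component by the voxel spacing to obtain physical units (typically
#' millimetres).
#'
#' @param field a `dense_field` (array `c(shape, n_axes)`).
#' @param spacing physical voxel size per axis.
#' @return array of the same shape, components scaled by `spacing`.
#' @export
field_voxels_to_mm <- function(field, spacing) {
  nd <- length(dim(field)) - 1L
  spacing <- rep_len(as.numeric(spacing), nd)
  for (cc in seq_len(nd))
    field <- assign_component(field, cc, slice_component(field, cc) * spacing[cc])
  field
}
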