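#' Generate a phantom image
#'
#' Builds a smooth low-intensity background (an oblique ramp in [20, 80])
#' with `n_blobs` ellipsoidal structures of distinct bright intensities
#' (in [140, 255]) and sharp boundaries — the distinctive edges and
#' salient objects that visual revision relies on. Fully deterministic per
#' seed; the caller's RNG state is untouched.
#'
#' @param shape image shape in voxels, each axis >= 32; 2-D or 3-D.
#' @param n_blobs number of ellipsoidal structures (>= 1).
#' @param seed integer seed.
#' @return a [scalar_image] with intensities in [0, 255].
#' @export
generate_phantom <- function(shape, n_blobs = 6, seed = 1) {
  nd <- length(shape)
  if (nd < 2L || nd > 3L) stop("phantom shape must be 2-D or 3-D")
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("each phantom axis must be >= 32 voxels")
  if (length(n_blobs) != 1L || n_blobs < 1L) stop("'n_blobs' must be >= 1")
  withr::with_seed(as.integer(seed), {
    n <- prod(shape)
    coords <- lapply(seq_len(nd), function(a) grid_axis_coords(shape, a))
    # oblique smooth background, range within [20, 80]
    wdir <- stats::runif(nd, 0.3, 1)
    ramp <- 0
    for (a in seq_len(nd)) ramp <- ramp + wdir[a] * coords[[a]] / (shape[a] - 1)
    ramp <- ramp / sum(wdir)
    img <- 20 + 60 * ramp
    # bright ellipsoids, later blobs overwrite earlier ones where they overlap
    intensities <- sample(seq(140, 255, length.out = max(n_blobs, 2)))[seq_len(n_blobs)]
    rmin <- 0.05 * min(shape)
    rmax <- 0.12 * min(shape)
    for (k in seq_len(n_blobs)) {
      center <- vapply(shape, function(s) stats::runif(1, 0.2 * s, 0.8 * s), 0)
      axes <- stats::runif(nd, rmin, rmax)
      q <- 0
      for (a in seq_len(nd)) q <- q + ((coords[[a]] - center[a]) / axes[a])^2
      img[q <= 1] <- intensities[k]
    }
    scalar_image(array(img, shape))
  })
}

#' Generate a ground-truth deformation
#'
#' Draws control displacements uniformly in
#' `[-max_magnitude, +max_magnitude]` per axis on a fresh lattice (for two
#' levels, each level draws from half that range so the summed field keeps
#' the same bound). All control points within one cell of the image
#' boundary (lattice index < 2 or > N-2) are pinned to zero, so the image
#' border stays fixed and the warped phantom keeps a full overlap mask.
#' By nonnegativity and partition of unity of the basis, the dense field's
#' per-axis magnitude never exceeds `max_magnitude`. Requiring
#' `max_magnitude < spacing/2` keeps the warp well-behaved (no folding in
#' practice).
#'
#' @param shape image shape in voxels.
#' @param spacing level-1 control-point spacing in voxels.
#' @param max_magnitude largest control displacement per axis (voxels);
#'   must be `< min(spacing)/2`.
#' @param seed integer seed.
#' @param levels 1 (default) or 2 lattice levels.
#' @return a [multilevel_deformation].
#' @export
generate_truth_deformation <- function(shape, spacing, max_magnitude, seed = 1,
                                       levels = 1) {
  nd <- length(shape)
  spacing <- rep_len(as.numeric(spacing), nd)
  if (length(max_magnitude) != 1L || max_magnitude < 0)
    stop("'max_magnitude' must be a single nonnegative number")
  if (max_magnitude >= min(spacing) / 2)
    stop("'max_magnitude' (", format(max_magnitude),
         ") must stay below spacing/2 (", format(min(spacing) / 2),
         "): larger control displacements risk folding the grid")
  if (!levels %in% c(1, 2)) stop("'levels' must be 1 or 2")
  def <- multilevel_deformation(shape, spacing)
  if (levels == 2) def <- refine(def)
  withr::with_seed(as.integer(seed), {
    for (lv in seq_len(levels)) {
      mag <- max_magnitude / levels
      lat <- def$levels[[lv]]
      n_int <- lat$grid_shape - 3L
      free <- lapply(seq_len(nd), function(a) {
        v <- (-1):(n_int[a] + 1L)
        v[v >= 2L & v <= n_int[a] - 2L]
      })
      if (any(vapply(free, length, integer(1)) == 0L)) next
      idx_grid <- as.matrix(do.call(expand.grid, free))
      for (r in seq_len(nrow(idx_grid))) {
        delta <- stats::runif(nd, -mag, mag)
        lat <- move_control_point(lat, as.integer(idx_grid[r, ]), delta)
      }
      def$levels[[lv]] <- lat
    }
  })
  def
}

#' Build a synthetic registration case
#'
#' A phantom reference image, a known ground-truth deformation, and the
#' transformed image obtained by warping the reference through it — the
#' testable stand-in for a clinical pair whose misregistration is known
#' exactly.
#'
#' @inheritParams generate_truth_deformation
#' @param n_blobs structures in the phantom.
#' @param interpolation interpolator used to produce the transformed
#'   image.
#' @return a `synthetic_case`: list with `reference`, `transformed`,
#'   `truth` (the [multilevel_deformation]), `valid` (warp overlap mask)
#'   and `seed`.
#' @examples
#' cs <- make_case(c(64, 64), spacing = 8, max_magnitude = 2, seed = 7)
#' ssd(cs$reference, cs$transformed)   # baseline misregistration > 0
#' @export
make_case <- function(shape, spacing = 16, max_magnitude = 4, seed = 1,
                      n_blobs = 6, levels = 1,
                      interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  seed <- as.integer(seed)
  reference <- generate_phantom(shape, n_blobs = n_blobs, seed = seed)
  truth <- generate_truth_deformation(shape, spacing, max_magnitude,
                                      seed = seed + 1000L, levels = levels)
  w <- warp_image(reference, truth, interpolation)
  structure(list(reference = reference, transformed = w$image,
                 truth = truth, valid = w$valid, seed = seed),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("<synthetic_case> seed ", x$seed, " | domain ",
      paste(img_shape(x$reference), collapse = " x "), " | baseline SSD ",
      format(ssd(x$reference, x$transformed), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Session that undoes a known ground-truth deformation
#'
#' Converts a synthetic case's truth lattice into a replayable session:
#' one drag per nonzero control point with content motion equal to the
#' stored truth displacement (the engine negates it on application, so the
#' revision lattice approximates the inverse warp), with refine events
#' inserted between levels. Replaying it on the case should recover the
#' reference up to interpolation error.
#'
#' @param case a `synthetic_case` from [make_case()].
#' @return a [revision_session()].
#' @export
session_from_truth <- function(case) {
  stopifnot(inherits(case, "synthetic_case"))
  truth <- case$truth
  nd <- length(truth$domain_shape)
  events <- list()
  for (lv in seq_along(truth$levels)) {
    if (lv > 1) events <- c(events, list(refine_event()))
    lat <- truth$levels[[lv]]
    n_int <- lat$grid_shape - 3L
    idx_grid <- as.matrix(do.call(expand.grid,
                                  lapply(seq_len(nd), function(a) (-1):(n_int[a] + 1L))))
    for (r in seq_len(nrow(idx_grid))) {
      index <- as.integer(idx_grid[r, ])
      d <- control_point(lat, index)
      if (any(d != 0))
        events <- c(events, list(drag_event(lv, index, d)))
    }
  }
  revision_session(truth$levels[[1]]$spacing, events,
                   list(origin = "ground-truth inverse", seed = case$seed))
}
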