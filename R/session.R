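#' Revision events
#'
#' The interactive revision process is recorded as an ordered list of two
#' event kinds. A *drag* moves one control point of one level so that
#' image content under it moves by `content_motion` (voxels): because
#' warping is backward (pull-back), the engine stores the negated vector
#' into the lattice, keeping the user-facing convention "drag content
#' right, content moves right". A *refine* appends a finer lattice with
#' half the spacing and carries no payload.
#'
#' @param level lattice level the drag applies to (1 = coarsest).
#' @param index integer lattice index of the control point per axis.
#' @param content_motion desired content motion in voxels per axis.
#' @return a `revision_event` list with field `kind` plus, for drags,
#'   `level`, `index`, `content_motion`.
#' @export
drag_event <- function(level, index, content_motion) {
  if (length(level) != 1L || level < 1) stop("'level' must be a positive integer")
  if (any(!is.finite(content_motion))) stop("'content_motion' must be finite")
  structure(list(kind = "drag", level = as.integer(level),
                 index = as.integer(index),
                 content_motion = as.numeric(content_motion)),
            class = "revision_event")
}

#' @rdname drag_event
#' @export
refine_event <- function() {
  structure(list(kind = "refine"), class = "revision_event")
}

#' Revision session
#'
#' A deterministic, replayable record of manual revision: the initial
#' control-point spacing, an ordered event list, and free-form metadata
#' (image identifiers, interpolation choice, display threshold). Replaying
#' the same session on the same inputs reproduces the final deformation
#' bit for bit; sessions serialize to diffable JSON via [write_session()].
#'
#' @param initial_spacing level-1 control-point spacing in voxels (scalar
#'   or per axis).
#' @param events list of [drag_event()] / [refine_event()] objects.
#' @param metadata named list of free-form metadata; the `interpolation`
#'   entry, when present, is used by [replay()].
#' @return a `revision_session`.
#' @export
revision_session <- function(initial_spacing, events = list(), metadata = list()) {
  if (any(!is.finite(initial_spacing)) || any(initial_spacing <= 0))
    stop("'initial_spacing' must be positive")
  for (k in seq_along(events))
    if (!inherits(events[[k]], "revision_event"))
      stop("event ", k, " is not a revision_event")
  structure(list(initial_spacing = as.numeric(initial_spacing),
                 events = events, metadata = metadata),
            class = "revision_session")
}

#' @export
print.revision_session <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, "", "kind")
  cat("<revision_session> spacing (",
      paste(format(x$initial_spacing), collapse = ", "), ") | ",
      length(x$events), " events (", sum(kinds == "drag"), " drag, ",
      sum(kinds == "refine"), " refine)\n", sep = "")
  invisible(x)
}

#' Append events to a session
#'
#' @param session a [revision_session()].
#' @param ... events to append, in order.
#' @return the extended session.
#' @export
append_events <- function(session, ...) {
  stopifnot(inherits(session, "revision_session"))
  revision_session(session$initial_spacing,
                   c(session$events, list(...)), session$metadata)
}

#' Apply one revision event to a deformation
#'
#' Drags call [move_control_point()] with the *negated* content motion
#' (backward-warp convention); refines call [refine()]. Dragging a level
#' coarser than the current finest one warns: after refinement, coarse
#' levels are normally left frozen and only fine-level control points in
#' still-misregistered areas are revised.
#'
#' @param state a [multilevel_deformation].
#' @param event a revision event.
#' @param ordinal optional event position, quoted in error messages.
#' @return the updated deformation.
#' @export
apply_event <- function(state, event, ordinal = NULL) {
  stopifnot(inherits(state, "multilevel_deformation"))
  where <- if (is.null(ordinal)) "" else paste0(" (event ", ordinal, ")")
  if (!inherits(event, "revision_event") || !event$kind %in% c("drag", "refine"))
    stop("invalid event", where)
  if (event$kind == "refine") return(refine(state))
  if (event$level > length(state$levels))
    stop("drag references level ", event$level, " but the deformation has ",
         length(state$levels), " level(s)", where)
  if (event$level < length(state$levels))
    warning("revising coarse level ", event$level,
            " after refinement; fine levels are normally revised instead", where)
  lat <- state$levels[[event$level]]
  lat <- tryCatch(move_control_point(lat, event$index, -event$content_motion),
                  error = function(e) stop(conditionMessage(e), where, call. = FALSE))
  state$levels[[event$level]] <- lat
  state
}

#' Replay a revision session
#'
#' Applies the session's events in order, starting from the identity
#' deformation at the session's initial spacing. After every event the
#' transformed image is re-warped *from the original transformed input*
#' (never cumulatively resampled, so interpolation blur does not compound)
#' and the SSD over the current overlap (validity mask, intersected with
#' `roi` if given) is recorded. The trace has one entry per event plus the
#' pre-revision baseline at ordinal 0.
#'
#' @param reference reference [scalar_image].
#' @param transformed coarsely registered [scalar_image], same shape.
#' @param session a [revision_session()].
#' @param roi optional logical array restricting the SSD.
#' @param interpolation overrides the session metadata's interpolation
#'   (default linear).
#' @return a `replay_result`: list with `image` (final warped
#'   [scalar_image]), `valid` (final overlap mask), `deformation`, and
#'   `trace` (data.frame with columns `event`, `ssd`).
#' @export
replay <- function(reference, transformed, session, roi = NULL,
                   interpolation = NULL) {
  stopifnot(inherits(session, "revision_session"))
  check_same_shape(reference, transformed)
  if (is.null(interpolation))
    interpolation <- session$metadata$interpolation %||% "linear"
  shp <- dim(as_intensity_array(reference))
  if (!is.null(roi)) check_same_shape(reference, roi, what = "image and roi")
  base_mask <- if (is.null(roi)) array(TRUE, shp) else roi
  state <- multilevel_deformation(shp, session$initial_spacing)
  trace_ssd <- ssd(reference, transformed, base_mask)
  out_image <- if (inherits(transformed, "scalar_image")) transformed
               else scalar_image(as_intensity_array(transformed))
  out_valid <- array(TRUE, shp)
  for (k in seq_along(session$events)) {
    state <- apply_event(state, session$events[[k]], ordinal = k)
    w <- warp_image(transformed, state, interpolation)
    out_image <- w$image
    out_valid <- w$valid
    m <- w$valid & base_mask
    trace_ssd <- c(trace_ssd, ssd(reference, w$image, m))
  }
  structure(list(image = out_image, valid = out_valid, deformation = state,
                 trace = data.frame(event = seq_along(trace_ssd) - 1L,
                                    ssd = trace_ssd)),
            class = "replay_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.replay_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<replay_result> ", n - 1L, " events | SSD ",
      format(x$trace$ssd[1], digits = 6), " -> ",
      format(x$trace$ssd[n], digits = 6), "\n", sep = "")
  invisible(x)
}

# Voxel coordinate vectors of the support region of control point `index`
# at a given lattice: all voxels whose 4-point support includes it, i.e.
# x/s in [index-2, index+2), clipped to the domain.
support_coords <- function(lattice, index) {
  nd <- length(lattice$domain_shape)
  lapply(seq_len(nd), function(a) {
    s <- lattice$spacing[a]
    lo <- max(0, ceiling((index[a] - 2) * s))
    hi <- min(lattice$domain_shape[a] - 1, ceiling((index[a] + 2) * s) - 1)
    if (lo > hi) integer(0) else seq(lo, hi)
  })
}

# SSD of reference vs transformed-warped-by-state restricted to the
# support region of one control point. Returns +Inf on empty overlap.
support_ssd <- function(state, reference, transformed, level, index,
                        interpolation) {
  lat <- state$levels[[level]]
  coords <- support_coords(lat, index)
  if (any(vapply(coords, length, integer(1)) == 0)) return(Inf)
  w <- warp_region(transformed, state, coords, interpolation)
  ref_block <- extract_region(as_intensity_array(reference), coords)
  if (!any(w$valid)) return(Inf)
  mean((ref_block[w$valid] - w$values[w$valid])^2)
}

#' Suggest a drag direction from SSD probes
#'
#' For each axis, probes a content motion of `+probe_step` and
#' `-probe_step` voxels at the given control point and compares the SSD
#' restricted to that point's support region against the current value.
#' Returns the sign that lowers SSD (0 if neither probe improves). This
#' encodes the supervision rule that a drag which increases SSD should be
#' inverted; restricting SSD to the B-spline support region is equivalent
#' in effect to the global metric for a single control point, since
#' nothing outside the support changes. The state is not modified.
#'
#' @param state a [multilevel_deformation].
#' @param reference,transformed the image pair (equal shapes).
#' @param level,index control point to probe.
#' @param probe_step probe magnitude in voxels (> 0).
#' @param interpolation interpolator used for the probes.
#' @return integer vector of signs (-1, 0, +1) per axis, in the
#'   content-motion convention of [drag_event()].
#' @export
suggest_direction <- function(state, reference, transformed, level, index,
                              probe_step = 1,
                              interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(state, "multilevel_deformation"))
  if (length(probe_step) != 1L || !is.finite(probe_step) || probe_step <= 0)
    stop("'probe_step' must be a single positive number")
  if (level < 1 || level > length(state$levels))
    stop("no level ", level, " in this deformation")
  check_lattice_index(state$levels[[level]], index)
  nd <- length(state$domain_shape)
  base <- support_ssd(state, reference, transformed, level, index, interpolation)
  out <- integer(nd)
  for (a in seq_len(nd)) {
    scores <- vapply(c(1, -1), function(sgn) {
      motion <- numeric(nd)
      motion[a] <- sgn * probe_step
      probed <- suppressWarnings(
        apply_event(state, drag_event(level, index, motion)))
      support_ssd(probed, reference, transformed, level, index, interpolation)
    }, numeric(1))
    if (min(scores) < base)
      out[a] <- if (scores[1] <= scores[2]) 1L else -1L
  }
  out
}

#' Greedy SSD-guided auto-revision
#'
#' A scripted stand-in for a human operator: sweeps over the finest
#' level's control points, asks [suggest_direction()] for the improving
#' sign per axis, and takes repeated steps of the current step size in
#' that direction while the support-region SSD keeps decreasing. Each
#' sweep halves the step size (coarse-to-fine in step length rather than
#' grid spacing). Every committed step is recorded as a drag event, so the
#' result is an ordinary replayable session.
#'
#' @param reference,transformed the image pair (equal shapes).
#' @param initial_spacing level-1 control-point spacing in voxels.
#' @param sweeps number of passes over the control points.
#' @param initial_step first sweep's step size in voxels; halved per
#'   sweep.
#' @param max_moves cap on committed steps per control point, axis and
#'   sweep.
#' @param interpolation interpolator for probes and the final warp.
#' @return list with `session` (the recorded [revision_session()]),
#'   `deformation`, `image` (final warp), `valid`, and `ssd_trace`
#'   (global SSD: baseline then after each sweep).
#' @export
greedy_revise <- function(reference, transformed, initial_spacing,
                          sweeps = 3, initial_step = 2, max_moves = 8,
                          interpolation = c("linear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  check_same_shape(reference, transformed)
  shp <- dim(as_intensity_array(reference))
  state <- multilevel_deformation(shp, initial_spacing)
  events <- list()
  nd <- length(shp)
  ssd_trace <- ssd(reference, transformed)
  for (sweep in seq_len(sweeps)) {
    step <- initial_step / 2^(sweep - 1)
    level <- length(state$levels)
    lat <- state$levels[[level]]
    n_int <- lat$grid_shape - 3L
    grid_idx <- do.call(expand.grid, lapply(seq_len(nd), function(a) 0:n_int[a]))
    for (r in seq_len(nrow(grid_idx))) {
      index <- as.integer(grid_idx[r, ])
      dirs <- suggest_direction(state, reference, transformed, level, index,
                                probe_step = step, interpolation = interpolation)
      for (a in which(dirs != 0L)) {
        motion <- numeric(nd)
        motion[a] <- dirs[a] * step
        cur <- support_ssd(state, reference, transformed, level, index,
                           interpolation)
        for (mv in seq_len(max_moves)) {
          cand <- apply_event(state, drag_event(level, index, motion))
          val <- support_ssd(cand, reference, transformed, level, index,
                             interpolation)
          if (val >= cur) break
          state <- cand
          cur <- val
          events <- c(events, list(drag_event(level, index, motion)))
        }
      }
    }
    w <- warp_image(transformed, state, interpolation)
    ssd_trace <- c(ssd_trace, ssd(reference, w$image, w$valid))
  }
  w <- warp_image(transformed, state, interpolation)
  list(session = revision_session(initial_spacing, events,
                                  list(interpolation = interpolation)),
       deformation = state, image = w$image, valid = w$valid,
       ssd_trace = ssd_trace)
}
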