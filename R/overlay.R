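#' Joint display rescaling
#'
#' Maps two images onto a shared [0, 255] display scale using their joint
#' minimum and maximum. A shared scale is what makes "gray" meaningful in
#' the RGB overlay: equal raw intensities map to equal display values.
#' If both images are constant and equal-valued the scale is degenerate
#' and both map to 0.
#'
#' @param a,b intensity arrays or [scalar_image]s of equal shape.
#' @return list of the two rescaled arrays (`a`, `b`), values in [0, 255].
#' @keywords internal
joint_rescale <- function(a, b) {
  a <- as_intensity_array(a)
  b <- as_intensity_array(b)
  lo <- min(min(a), min(b))
  hi <- max(max(a), max(b))
  if (hi == lo) return(list(a = array(0, dim(a)), b = array(0, dim(b))))
  list(a = (a - lo) * (255 / (hi - lo)), b = (b - lo) * (255 / (hi - lo)))
}

#' RGB misregistration overlay
#'
#' Fuses a reference and a transformed image into one color image: the
#' reference fills the green band, the transformed image fills the red and
#' blue bands (both images first rescaled to a shared [0, 255] display
#' range). Where the two agree all three bands are equal and the pixel is
#' gray; where the reference is brighter the pixel trends green, where the
#' transformed image is brighter it trends purple. Colored regions are
#' exactly the misregistered (or occluded) regions.
#'
#' @param reference reference [scalar_image] (or array).
#' @param transformed transformed/test [scalar_image] (or array), same
#'   shape.
#' @return an `rgb_overlay`: list of channel arrays `r`, `g`, `b` in
#'   [0, 255].
#' @examples
#' ref <- matrix(c(255, 0, 100, 100), 2, 2)
#' trn <- matrix(c(0, 255, 100, 100), 2, 2)
#' ov <- rgb_overlay(ref, trn)  # one green, one purple, two gray pixels
#' @export
rgb_overlay <- function(reference, transformed) {
  check_same_shape(reference, transformed)
  sc <- joint_rescale(reference, transformed)
  structure(list(r = sc$b, g = sc$a, b = sc$b), class = "rgb_overlay")
}

#' @export
print.rgb_overlay <- function(x, ...) {
  gray <- mean(abs(x$g - x$r) < 1)  # within one display unit
  cat("<rgb_overlay> ", paste(dim(x$g), collapse = " x "), " | ",
      format(100 * gray, digits = 4), "% gray\n", sep = "")
  invisible(x)
}

#' Mean squared intensity difference (SSD)
#'
#' The supervision metric for interactive revision:
#' \deqn{SSD = \frac{1}{n}\sum_{x \in mask} (I_{ref}(x) - I_{trans}(x))^2}
#' where the sum runs over the `n` masked voxels — by default the whole
#' grid; in practice the warp validity mask (the overlap of both images),
#' optionally intersected with a region of interest. SSD is symmetric in
#' its two images, nonnegative, and zero exactly when they agree on the
#' mask. It decreases as the transformed image is revised toward the
#' reference, which is what lets it supervise dragging in real time: if a
#' drag makes SSD larger, the drag direction should be inverted.
#'
#' @param reference,transformed [scalar_image]s or arrays of equal shape.
#' @param mask optional logical array (same shape) restricting the sum;
#'   must contain at least one `TRUE` voxel.
#' @return the mean squared difference (single number).
#' @seealso [ssd_stats()] for the auxiliary variance, [replay()] for the
#'   per-event SSD trace.
#' @export
ssd <- function(reference, transformed, mask = NULL) {
  ssd_stats(reference, transformed, mask)$mean
}

#' SSD with auxiliary statistics
#'
#' @inheritParams ssd
#' @return list with `mean` (the SSD), `variance` (variance of the squared
#'   differences over the mask) and `n` (number of masked voxels).
#' @export
ssd_stats <- function(reference, transformed, mask = NULL) {
  shp <- check_same_shape(reference, transformed)
  a <- as_intensity_array(reference)
  b <- as_intensity_array(transformed)
  if (is.null(mask)) {
    sq <- as.vector((a - b)^2)
  } else {
    if (!is.logical(mask)) stop("'mask' must be logical")
    check_same_shape(a, mask, what = "image and mask")
    if (!any(mask)) stop("empty mask: SSD needs at least one voxel")
    sq <- (a - b)[mask]^2
  }
  list(mean = mean(sq),
       variance = if (length(sq) > 1) stats::var(sq) else 0,
       n = length(sq))
}

#' Misregistration mask
#'
#' The machine-readable counterpart of "pixels that appear green or
#' purple": voxels where the jointly rescaled reference and transformed
#' intensities differ by more than `threshold` display units.
#'
#' @inheritParams ssd
#' @param threshold nonnegative difference threshold on the [0, 255]
#'   display scale.
#' @return logical array, `TRUE` at misregistered voxels.
#' @export
misregistration_mask <- function(reference, transformed, threshold) {
  check_same_shape(reference, transformed)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("'threshold' must be a single nonnegative number")
  sc <- joint_rescale(reference, transformed)
  abs(sc$a - sc$b) > threshold
}
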