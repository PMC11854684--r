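#' Displacement estimate for a ghost image
#'
#' Output of the quantitative arm: the adjacent-copy ghost offset in
#' pixels, the rotation component in degrees, the number of visible
#' images, and the strength of the supporting evidence.
#'
#' Sign conventions: a still photograph cannot distinguish the beat
#' direction of the nystagmus, so the offset sign is canonicalized to
#' `dx >= 0` (tie broken toward `dy >= 0`) and the rotation is reported
#' as a nonnegative magnitude.
#'
#' @param dx_px,dy_px adjacent-copy offset, pixels.
#' @param rotation_deg adjacent-copy rotation magnitude, degrees.
#' @param n_images number of visible images (1, 2 or 3).
#' @param peak_strength off-center autocorrelation peak height relative to
#'   the central peak (or consensus support fraction for the landmark
#'   method), in `[0, 1]`.
#' @param method `"autocorrelation"` or `"landmark"`.
#' @param arc_radius_px optional radius (pixels) at which a rotation is
#'   converted to arc length when grading rotation-only images.
#' @return An object of class `displacement_estimate`.
#' @export
displacement_estimate <- function(dx_px, dy_px, rotation_deg = 0,
                                  n_images = 1, peak_strength = 0,
                                  method = c("autocorrelation", "landmark"),
                                  arc_radius_px = NULL) {
  method <- match.arg(method)
  if (!n_images %in% 1:3)
    stop_ghostgrade("`n_images` must be 1, 2 or 3", "invalid_parameter")
  if (peak_strength < 0 || peak_strength > 1)
    stop_ghostgrade("`peak_strength` must be in [0, 1]", "invalid_parameter")
  structure(list(dx_px = dx_px, dy_px = dy_px, rotation_deg = rotation_deg,
                 n_images = as.integer(n_images),
                 peak_strength = peak_strength, method = method,
                 arc_radius_px = arc_radius_px),
            class = "displacement_estimate")
}

#' @export
print.displacement_estimate <- function(x, ...) {
  cat(sprintf(
    "<displacement_estimate> (%s) d = (%.2f, %.2f) px, rot = %.2f deg, %d image(s), strength %.2f\n",
    x$method, x$dx_px, x$dy_px, x$rotation_deg, x$n_images, x$peak_strength))
  invisible(x)
}

displacement_norm <- function(est) sqrt(est$dx_px^2 + est$dy_px^2)

#' Distance between ghost offsets up to the beat-direction ambiguity
#'
#' A still photograph cannot distinguish `+v` from `-v`, so two offset
#' estimates agree when either representation matches:
#' `min(|a - b|, |a + b|)`. Use this whenever comparing offsets from
#' different estimators (or against ground truth) -- near-vertical
#' ghosts can legitimately come out with opposite `dy` signs under the
#' `dx >= 0` canonicalization.
#'
#' @param a,b length-2 offsets `(dx, dy)`, or [displacement_estimate()]s.
#' @return Euclidean distance after sign folding.
#' @export
ghost_offset_distance <- function(a, b) {
  if (inherits(a, "displacement_estimate")) a <- c(a$dx_px, a$dy_px)
  if (inherits(b, "displacement_estimate")) b <- c(b$dx_px, b$dy_px)
  min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
}
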