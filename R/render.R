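#' Render a ghost image from a phantom and a trajectory
#'
#' Image formation follows the discrete-foveation model: the composite is
#' an exposure-weighted sum of rigidly transformed copies of the retina,
#' with copy `i` (of `n`) offset by `(i - (n-1)/2) * (dx, dy)` and rotated
#' by `(i - (n-1)/2) * rotation_deg` about the fixation center (the macula),
#' so adjacent copies are separated by exactly the trajectory's
#' displacement and rotation and the set is symmetric about the nominal
#' position. Gaussian intensity noise of s.d. `noise_sigma` is then added
#' and the result clipped to `[0, 1]`.
#'
#' Noise is drawn from the current RNG stream; seed the session (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param phantom a [generate_vessel_phantom()] result (or any
#'   `fundus_image`-like object with `canvas`/`pixels`, `disc_center`,
#'   `disc_diameter_px`).
#' @param truth a [trajectory_truth()].
#' @param eye_id identifier for the output image.
#' @return A [fundus_image()] carrying the phantom's disc geometry.
#' @export
render_ghost_image <- function(phantom, truth, eye_id = "eye") {
  if (!inherits(truth, "trajectory_truth"))
    stop_ghostgrade("`truth` must be a trajectory_truth", "invalid_parameter")
  canvas <- phantom$canvas %||% phantom$pixels
  if (is.null(canvas))
    stop_ghostgrade("`phantom` carries no canvas", "invalid_parameter")
  center <- phantom$macula_center %||%
    c((ncol(canvas) - 1) / 2, (nrow(canvas) - 1) / 2)
  n <- truth$n_images
  offs <- (seq_len(n) - 1 - (n - 1) / 2)
  for (k in seq_len(n)) {
    fr <- inside_fraction(dim(canvas), offs[k] * truth$displacement_px[1],
                          offs[k] * truth$displacement_px[2],
                          offs[k] * truth$rotation_deg, center)
    if (fr < 0.9)
      stop_ghostgrade(
        "displacement/rotation pushes a copy more than 10% off canvas",
        "out_of_bounds")
  }
  out <- matrix(0, nrow(canvas), ncol(canvas))
  for (k in seq_len(n)) {
    if (offs[k] == 0) {
      copy <- canvas
    } else {
      copy <- warp_rigid(canvas,
                         dx = offs[k] * truth$displacement_px[1],
                         dy = offs[k] * truth$displacement_px[2],
                         theta_deg = offs[k] * truth$rotation_deg,
                         center = center)
    }
    out <- out + truth$exposure_weights[k] * copy
  }
  if (truth$noise_sigma > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, truth$noise_sigma),
                        nrow(out), ncol(out))
  fundus_image(clamp(out, 0, 1),
               disc_center = phantom$disc_center,
               disc_diameter_px = phantom$disc_diameter_px,
               eye_id = eye_id)
}
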