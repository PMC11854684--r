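#' Ground-truth nystagmus trajectory for the simulator
#'
#' Describes the discrete foveation positions that produce a ghost image:
#' `n_images` rigid copies of the retina, adjacent copies separated by
#' `displacement_px` and rotated by `rotation_deg` about the fixation
#' center, with exposure-time weights `exposure_weights`. Copies are
#' placed symmetrically about the nominal position, so `displacement_px`
#' is always the adjacent-copy offset -- the quantity the estimators
#' recover.
#'
#' @param direction_class one of `"horizontal"`, `"vertical"`, `"rotary"`,
#'   `"combined"`, `"none"`.
#' @param displacement_px adjacent-copy offset `(dx, dy)` in pixels,
#'   image coordinates (x rightward, y downward).
#' @param rotation_deg adjacent-copy rotation about the fixation center,
#'   degrees, counterclockwise on screen.
#' @param n_images number of discrete foveation positions, 1, 2 or 3
#'   (single image, double or triple ghost).
#' @param exposure_weights nonnegative weights of length `n_images`
#'   summing to 1; `NULL` means uniform.
#' @param noise_sigma Gaussian intensity noise s.d. added at render time.
#' @param floors detectability floors used to validate the `"none"` class
#'   (a [detect_params()] object).
#' @return An object of class `trajectory_truth`.
#' @export
trajectory_truth <- function(direction_class, displacement_px = c(0, 0),
                             rotation_deg = 0, n_images = 2,
                             exposure_weights = NULL, noise_sigma = 0,
                             floors = detect_params()) {
  direction_class <- match.arg(direction_class, c("horizontal", "vertical",
                                                  "rotary", "combined", "none"))
  if (length(displacement_px) != 2L || anyNA(displacement_px))
    stop_ghostgrade("`displacement_px` must be a (dx, dy) pair",
                    "invalid_parameter")
  assert_scalar_number(rotation_deg, "rotation_deg")
  if (!n_images %in% 1:3)
    stop_ghostgrade("`n_images` must be 1, 2 or 3", "invalid_parameter")
  n_images <- as.integer(n_images)
  if (is.null(exposure_weights)) exposure_weights <- rep(1 / n_images, n_images)
  if (length(exposure_weights) != n_images)
    stop_ghostgrade("`exposure_weights` must have length n_images",
                    "invalid_parameter")
  if (any(exposure_weights < 0) || abs(sum(exposure_weights) - 1) > 1e-9)
    stop_ghostgrade("`exposure_weights` must be nonnegative and sum to 1",
                    "invalid_parameter")
  if (noise_sigma < 0)
    stop_ghostgrade("`noise_sigma` must be nonnegative", "invalid_parameter")
  disp <- sqrt(sum(displacement_px^2))
  sub_floor <- disp < floors$floor_px && abs(rotation_deg) < floors$floor_deg &&
    n_images == 1L
  if ((direction_class == "none") != sub_floor)
    stop_ghostgrade(paste("direction_class 'none' requires (and is required",
                          "by) sub-floor displacement and rotation with",
                          "n_images = 1"), "invalid_parameter")
  structure(list(direction_class = direction_class,
                 displacement_px = as.numeric(displacement_px),
                 rotation_deg = rotation_deg, n_images = n_images,
                 exposure_weights = as.numeric(exposure_weights),
                 noise_sigma = noise_sigma),
            class = "trajectory_truth")
}

#' Dominant-foveation exposure weights
#'
#' Preset weights for the common situation where the foveation period
#' dominates dwell time, producing one strong and one weak copy.
#'
#' @param n_images 2 or 3.
#' @return Numeric weight vector summing to 1.
#' @export
dominant_foveation_weights <- function(n_images = 2) {
  switch(as.character(n_images),
         "2" = c(0.7, 0.3),
         "3" = c(0.2, 0.6, 0.2),
         stop_ghostgrade("`n_images` must be 2 or 3", "invalid_parameter"))
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat(sprintf(
    "<trajectory_truth> %s: d = (%.1f, %.1f) px, rot = %.1f deg, %d image(s)\n",
    x$direction_class, x$displacement_px[1], x$displacement_px[2],
    x$rotation_deg, x$n_images))
  invisible(x)
}
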