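#' Ordinal photographic nystagmus grade
#'
#' The photographic assessment of one eye: an amplitude grade on the 0-3
#' scale (0 = no visible nystagmus, 1 = small, 2 = medium, 3 = large) and
#' a direction class. Grade 0 and direction `"undetected"` imply each
#' other.
#'
#' @param eye_id identifier.
#' @param amplitude_grade integer 0-3.
#' @param direction_class one of `"horizontal"`, `"vertical"`, `"rotary"`,
#'   `"combined"`, `"undetected"`.
#' @param arm `"quantitative"` or `"qualitative"`.
#' @param normalized_displacement displacement in disc diameters.
#' @param rotation_deg rotation magnitude, degrees.
#' @return An object of class `photo_grade`.
#' @export
photo_grade <- function(eye_id, amplitude_grade, direction_class,
                        arm = c("quantitative", "qualitative"),
                        normalized_displacement = 0, rotation_deg = 0) {
  arm <- match.arg(arm)
  direction_class <- match.arg(direction_class,
                               c("horizontal", "vertical", "rotary",
                                 "combined", "undetected"))
  if (!amplitude_grade %in% 0:3)
    stop_ghostgrade("`amplitude_grade` must be 0, 1, 2 or 3",
                    "invalid_parameter")
  if ((amplitude_grade == 0) != (direction_class == "undetected"))
    stop_ghostgrade("grade 0 and direction 'undetected' imply each other",
                    "invalid_parameter")
  if (normalized_displacement < 0)
    stop_ghostgrade("`normalized_displacement` must be nonnegative",
                    "invalid_parameter")
  structure(list(eye_id = as.character(eye_id),
                 amplitude_grade = as.integer(amplitude_grade),
                 direction_class = direction_class, arm = arm,
                 normalized_displacement = normalized_displacement,
                 rotation_deg = rotation_deg),
            class = "photo_grade")
}

#' @export
print.photo_grade <- function(x, ...) {
  cat(sprintf("<photo_grade> %s (%s): grade %d, %s (d = %.3f DD)\n",
              x$eye_id, x$arm, x$amplitude_grade, x$direction_class,
              x$normalized_displacement))
  invisible(x)
}

#' @export
as.data.frame.photo_grade <- function(x, ...) {
  data.frame(eye_id = x$eye_id, arm = x$arm,
             amplitude_grade = x$amplitude_grade,
             direction_class = x$direction_class,
             normalized_displacement = x$normalized_displacement,
             rotation_deg = x$rotation_deg, stringsAsFactors = FALSE)
}

# normalized displacement in disc diameters; rotation-only images grade by
# the arc length swept at the annulus mid-radius
normalized_displacement_of <- function(estimate, disc_diameter_px, floors) {
  disp <- displacement_norm(estimate)
  if (disp >= floors$floor_px) return(disp / disc_diameter_px)
  if (abs(estimate$rotation_deg) >= floors$floor_deg) {
    r_mid <- estimate$arc_radius_px %||% (3.75 * disc_diameter_px)
    return(deg2rad(abs(estimate$rotation_deg)) * r_mid / disc_diameter_px)
  }
  0
}

#' Map a displacement estimate to the 0-3 amplitude grade
#'
#' Displacement is normalized by the optic-disc diameter (DD), the
#' standard fundus yardstick, which removes magnification and resolution
#' dependence. With the default cut-points, normalized displacement
#' `d < 0.15` DD is grade 1, `0.15 <= d < 0.40` grade 2 and `d >= 0.40`
#' grade 3 (bins lower-inclusive on the upper side); below the
#' detectability floor the grade is 0. A rotation-only image grades by
#' the arc length swept at the rotation-annulus mid-radius, converted to
#' the same normalized scale.
#'
#' @param estimate a [displacement_estimate()].
#' @param disc_diameter_px optic-disc diameter, pixels.
#' @param thresholds a [grade_thresholds()].
#' @param floors a [detect_params()] supplying the detectability floors.
#' @return Integer grade in 0-3.
#' @export
amplitude_grade <- function(estimate, disc_diameter_px,
                            thresholds = grade_thresholds(),
                            floors = detect_params()) {
  assert_scalar_number(disc_diameter_px, "disc_diameter_px", positive = TRUE)
  if (!inherits(thresholds, "grade_thresholds"))
    thresholds <- grade_thresholds(thresholds)
  d <- normalized_displacement_of(estimate, disc_diameter_px, floors)
  if (d == 0) return(0L)
  if (d < thresholds$cuts[1]) return(1L)
  if (d < thresholds$cuts[2]) return(2L)
  3L
}

#' Classify nystagmus direction from a displacement estimate
#'
#' Below both detectability floors the class is `"undetected"`. Otherwise
#' the offset angle is folded to `[0, 90]` degrees from horizontal:
#' within `angle_bins[1]` (default 30) of horizontal is `"horizontal"`,
#' beyond `angle_bins[2]` (default 60) is `"vertical"`, else
#' `"combined"`. A rotation above floor with no linear component is
#' `"rotary"`; rotation plus a linear component is `"combined"` (the
#' multi-component class).
#'
#' @param estimate a [displacement_estimate()].
#' @param floors a [detect_params()].
#' @param angle_bins two increasing angles (degrees) bounding the
#'   horizontal and vertical sectors.
#' @return One of `"horizontal"`, `"vertical"`, `"rotary"`, `"combined"`,
#'   `"undetected"`.
#' @export
classify_direction <- function(estimate, floors = detect_params(),
                               angle_bins = c(30, 60)) {
  if (length(angle_bins) != 2L || angle_bins[1] <= 0 ||
      angle_bins[2] <= angle_bins[1] || angle_bins[2] >= 90)
    stop_ghostgrade("`angle_bins` must be increasing within (0, 90)",
                    "invalid_parameter")
  disp <- displacement_norm(estimate)
  linear <- disp >= floors$floor_px
  rotary <- abs(estimate$rotation_deg) >= floors$floor_deg
  if (!linear && !rotary) return("undetected")
  if (!linear) return("rotary")
  if (rotary) return("combined")
  alpha <- atan2(abs(estimate$dy_px), abs(estimate$dx_px)) * 180 / pi
  if (alpha <= angle_bins[1]) "horizontal"
  else if (alpha >= angle_bins[2]) "vertical"
  else "combined"
}

#' Grade a quantified fundus photograph
#'
#' Combines [amplitude_grade()] and [classify_direction()] into a
#' [photo_grade()].
#'
#' @param fit a [quantify_ghosts()] result, or a
#'   [displacement_estimate()] (then `disc_diameter_px` is required).
#' @param disc_diameter_px optic-disc diameter, pixels.
#' @param thresholds a [grade_thresholds()].
#' @param floors a [detect_params()].
#' @param angle_bins passed to [classify_direction()].
#' @param arm label recorded on the grade.
#' @param eye_id identifier override.
#' @return A [photo_grade()].
#' @export
grade_photo <- function(fit, disc_diameter_px = NULL,
                        thresholds = grade_thresholds(),
                        floors = detect_params(), angle_bins = c(30, 60),
                        arm = "quantitative", eye_id = NULL) {
  if (inherits(fit, "ghost_fit")) {
    estimate <- fit$estimate
    disc_diameter_px <- disc_diameter_px %||% fit$disc_diameter_px
    eye_id <- eye_id %||% fit$eye_id
  } else if (inherits(fit, "displacement_estimate")) {
    estimate <- fit
    if (is.null(disc_diameter_px))
      stop_ghostgrade("`disc_diameter_px` is required with a bare estimate",
                      "invalid_parameter")
    eye_id <- eye_id %||% "eye"
  } else {
    stop_ghostgrade("`fit` must be a ghost_fit or displacement_estimate",
                    "invalid_parameter")
  }
  g <- amplitude_grade(estimate, disc_diameter_px, thresholds, floors)
  dir <- classify_direction(estimate, floors, angle_bins)
  photo_grade(eye_id, g, if (g == 0L) "undetected" else dir, arm = arm,
              normalized_displacement =
                normalized_displacement_of(estimate, disc_diameter_px, floors),
              rotation_deg = estimate$rotation_deg)
}

#' Emulate the qualitative (by-eye) grading arm
#'
#' The qualitative arm judges overall appearance rather than measuring
#' pixels, so its emulation runs the autocorrelation estimator at a
#' coarser tolerance: peak threshold lowered to `0.15`, no sub-pixel
#' refinement, and the grade cut-points widened by 20% (lower cut scaled
#' by 0.8, upper by 1.2). Near the cut-points the two arms can therefore
#' disagree by one grade, as human raters do.
#'
#' @param image a [fundus_image()] or matrix.
#' @param params a [detect_params()]; the coarsening is applied on top.
#' @param thresholds quantitative-arm [grade_thresholds()]; the
#'   qualitative widening is applied to these.
#' @param angle_bins passed to [classify_direction()].
#' @return A [photo_grade()] with `arm = "qualitative"`.
#' @export
qualitative_emulation <- function(image, params = detect_params(),
                                  thresholds = grade_thresholds(),
                                  angle_bins = c(30, 60)) {
  qp <- params
  qp$theta_peak <- 0.15
  qp$subpixel <- FALSE
  qt <- grade_thresholds(thresholds$cuts * c(0.8, 1.2))
  fit <- quantify_ghosts(image, method = "autocorr", params = qp)
  grade_photo(fit, thresholds = qt, floors = qp, angle_bins = angle_bins,
              arm = "qualitative")
}
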