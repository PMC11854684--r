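#' Detection parameters for ghost-image estimators
#'
#' Tunable parameters shared by the autocorrelation, rotation and landmark
#' estimators.
#'
#' @param theta_peak minimum off-center autocorrelation peak height, as a
#'   fraction of the central peak (default 0.2).
#' @param s_min minimum separation between the central and any qualifying
#'   off-center peak, pixels (default 4). Peaks closer than this are
#'   suppressed, not errors.
#' @param floor_px detectability floor on linear displacement, pixels
#'   (default 3): small-amplitude nystagmus produces minimal artifact on a
#'   still photo, so estimates below the floor are reported as a single
#'   image / grade 0.
#' @param floor_deg detectability floor on rotation, degrees (default 1.5).
#' @param subpixel refine the autocorrelation peak by a quadratic fit
#'   (default `TRUE`).
#' @param scales Gaussian scales (pixels) of the Hessian ridge filter used
#'   to enhance vessels before matching or correlation.
#' @param annulus inner/outer radii of the rotation-estimation annulus, as
#'   fractions of the shorter image side (default `c(0.15, 0.45)`).
#' @param m_min minimum number of supporting bifurcation pairs for a
#'   landmark translation consensus (default 3).
#' @param bin_px offset-histogram bin width for the landmark consensus,
#'   pixels (default 2).
#' @param search_radius maximum landmark pair offset considered, pixels;
#'   `NULL` means 0.45 of the shorter image side.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(theta_peak = 0.2, s_min = 4, floor_px = 3,
                          floor_deg = 1.5, subpixel = TRUE,
                          scales = c(1.5, 3), annulus = c(0.15, 0.45),
                          m_min = 3, bin_px = 2, search_radius = NULL) {
  assert_scalar_number(theta_peak, "theta_peak", positive = TRUE)
  if (theta_peak >= 1)
    stop_ghostgrade("`theta_peak` must be in (0, 1)", "invalid_parameter")
  assert_scalar_number(s_min, "s_min", positive = TRUE)
  assert_scalar_number(floor_px, "floor_px", positive = TRUE)
  assert_scalar_number(floor_deg, "floor_deg", positive = TRUE)
  if (length(annulus) != 2L || annulus[1] <= 0 || annulus[2] <= annulus[1])
    stop_ghostgrade("`annulus` must be increasing positive radii fractions",
                    "invalid_parameter")
  structure(list(theta_peak = theta_peak, s_min = s_min, floor_px = floor_px,
                 floor_deg = floor_deg, subpixel = isTRUE(subpixel),
                 scales = scales, annulus = annulus, m_min = m_min,
                 bin_px = bin_px, search_radius = search_radius),
            class = "detect_params")
}

#' Amplitude grade thresholds
#'
#' Cut-points on displacement normalized by optic-disc diameter (DD) that
#' map a measurement to the ordinal 0-3 amplitude scale. Grade 0 means no
#' detectable ghost; grades 1-3 are small / medium / large. Bins are
#' half-open and lower-inclusive on the upper side: `d < cuts[1]` is grade
#' 1, `cuts[1] <= d < cuts[2]` grade 2, `d >= cuts[2]` grade 3.
#'
#' @param cuts increasing positive pair of normalized-displacement
#'   cut-points, disc diameters (default `c(0.15, 0.40)`).
#' @return A list of class `grade_thresholds`.
#' @export
grade_thresholds <- function(cuts = c(0.15, 0.40)) {
  if (!is.numeric(cuts) || length(cuts) != 2L || anyNA(cuts))
    stop_ghostgrade("`cuts` must be two numbers", "invalid_parameter")
  if (cuts[1] <= 0 || cuts[2] <= cuts[1])
    stop_ghostgrade("`cuts` must be positive and strictly increasing",
                    "invalid_parameter")
  structure(list(cuts = as.numeric(cuts)), class = "grade_thresholds")
}
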