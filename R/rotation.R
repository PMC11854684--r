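#' Estimate the rotation component of a ghost image
#'
#' Torsional nystagmus rotates the globe about the line of sight, so the
#' ghost copies are angular, not translational. The estimator resamples an
#' annulus around `center` to polar coordinates (half-degree angular bins,
#' radius bins spanning `params$annulus` times the shorter image side),
#' vessel-enhances first, and computes the circular angular
#' autocorrelation of every ring.
#'
#' A true rotation peaks at the same angular lag on every ring, whereas a
#' translated ghost produces an apparent angular offset that shrinks like
#' `1/r`; and close to the center a small rotation cannot separate the
#' copies of a vessel at all (the vessel's own angular width exceeds the
#' lag). The estimator therefore collects candidate peaks per ring,
#' masks each ring's lags below the translation-induced bound
#' `1.6 * exclude_translation_px / r` when a linear displacement is
#' known, and accepts a rotation only when a sufficient share of the
#' rings that detect anything agree on one lag. The consensus lag is
#' refined to sub-degree precision by a quadratic fit on the
#' radius-summed autocorrelation; with no consistent qualifying peak the
#' result is 0.
#'
#' An autocorrelation is an even function and symmetric exposure weights
#' make the +theta and -theta images identical, so torsion sign is not
#' recoverable from a still photograph; the magnitude is returned
#' (nonnegative, the angular analogue of the `dx >= 0` convention).
#'
#' @param image a [fundus_image()] or matrix.
#' @param center rotation center as a 0-based `(x, y)` pair. The default
#'   is the anatomical fixation center (the macula), located 2.5 disc
#'   diameters temporal to the disc when disc geometry is available, else
#'   the canvas center.
#' @param params a [detect_params()].
#' @param n_radii number of radius bins.
#' @param consistency_deg width (degrees) of the lag window within which
#'   rings are considered to agree.
#' @param exclude_translation_px magnitude of a known linear ghost
#'   displacement; per-ring lags below the offset such a translation can
#'   induce are ignored. 0 disables the mask.
#' @return Rotation magnitude in degrees (0 when no angular ghost peak).
#' @export
estimate_rotation <- function(image, center = NULL, params = detect_params(),
                              n_radii = 42, consistency_deg = 1.5,
                              exclude_translation_px = 0) {
  px <- as_pixels(image)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(center) && inherits(image, "fundus_image") &&
      !is.null(image$disc_center) && !is.null(image$disc_diameter_px))
    center <- image$disc_center + c(2.5 * image$disc_diameter_px, 0)
  if (is.null(center)) center <- c((nc - 1) / 2, (nr - 1) / 2)
  if (center[1] < 0 || center[1] > nc - 1 || center[2] < 0 ||
      center[2] > nr - 1)
    stop_ghostgrade("`center` must lie inside the image", "invalid_parameter")
  radii <- params$annulus * min(nr, nc)
  if (center[1] - radii[2] < 0 || center[1] + radii[2] > nc - 1 ||
      center[2] - radii[2] < 0 || center[2] + radii[2] > nr - 1)
    stop_ghostgrade("annulus exceeds image bounds", "invalid_parameter")

  enh <- vessel_enhance(px, params$scales)
  rs <- seq(radii[1], radii[2], length.out = n_radii)
  bin_deg <- 0.5                            # half-degree bins for sub-degree peaks
  n_ang <- round(360 / bin_deg)
  th <- deg2rad(seq(0, 360 - bin_deg, by = bin_deg))
  # polar sampling; angle increases counterclockwise on screen (y down)
  pol <- matrix(0, n_radii, n_ang)
  for (i in seq_len(n_radii)) {
    pol[i, ] <- bilinear_sample(enh, center[1] + rs[i] * cos(th),
                                center[2] - rs[i] * sin(th))
  }
  pol <- pol - rowMeans(pol)
  # circular autocorrelation along angle, per ring (fft down columns)
  ft <- stats::mvfft(t(pol))                # n_ang x n_radii
  ac <- Re(stats::mvfft(Mod(ft)^2, inverse = TRUE)) / n_ang
  lag_max <- round(90 / bin_deg)
  # all qualifying local maxima of one ring's normalized autocorrelation
  # above `lo_deg` (degrees)
  ring_candidates <- function(i, lo_deg) {
    a <- ac[, i]
    if (a[1] <= 0) return(numeric(0))
    a <- a / a[1]
    lo <- max(2L, ceiling(lo_deg / bin_deg))
    search <- (lo + 1):(lag_max + 1)
    vals <- a[search]
    cand <- which(vals >= 0.75 * params$theta_peak &
                    vals >= a[search - 1] & vals >= a[search + 1])
    (search[cand] - 1) * bin_deg
  }
  lo_for_ring <- function(i)
    max(1, 1.6 * exclude_translation_px / rs[i] * 180 / pi)
  cands <- lapply(seq_len(n_radii), function(i)
    ring_candidates(i, lo_for_ring(i)))
  detected <- which(lengths(cands) > 0)
  if (length(detected) < 8) return(0)
  # consensus: the lag around which the most rings place a candidate
  centers <- sort(unique(unlist(cands)))
  votes <- vapply(centers, function(ctr)
    sum(vapply(cands[detected], function(l)
      any(abs(l - ctr) <= consistency_deg / 2), FALSE)), 0L)
  best <- which.max(votes)
  if (votes[best] < max(8, 0.4 * length(detected))) return(0)
  voters <- detected[vapply(cands[detected], function(l)
    any(abs(l - centers[best]) <= consistency_deg / 2), FALSE)]
  med <- stats::median(unlist(lapply(cands[voters], function(l)
    l[abs(l - centers[best]) <= consistency_deg / 2])))
  # final estimate from the autocorrelation summed over the voting rings
  # (summing all rings lets the slowly decaying small-lag shoulder of the
  # inner rings swamp a small consensus peak)
  acs <- rowSums(ac[, voters, drop = FALSE])
  acs <- acs / acs[1]
  lo <- max(2L, round((med - 1) / bin_deg))
  hi <- min(lag_max, round((med + 1) / bin_deg))
  search <- (lo + 1):(hi + 1)
  vals <- acs[search]
  cand2 <- which(vals >= acs[search - 1] & vals >= acs[search + 1])
  if (length(cand2) == 0) {
    lag <- med
  } else {
    lag <- search[cand2[which.max(vals[cand2])]] - 1
    idx <- lag + 1
    lag <- (lag + quad_refine(acs[idx - 1], acs[idx], acs[idx + 1])) * bin_deg
  }
  if (lag < params$floor_deg) return(0)
  lag
}
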