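# Autocorrelation displacement estimator.
#
# A ghost image is (approximately) a sum of shifted copies of the same
# retina, so its spatial autocorrelation carries off-center peaks at the
# copy offsets: +-d for a double, +-d and +-2d for an equally spaced
# triple. The estimator vessel-enhances the image, computes the normalized
# autocorrelation by FFT with zero padding (so peaks are not aliased by
# circular wraparound), and reads displacement and image count off the
# significant off-center peaks.

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

# normalized autocorrelation of a mean-subtracted field, centered;
# returns list(acf = matrix, cx, cy) with 1-based center indices
normalized_autocorr <- function(field, pad_px) {
  nr <- nrow(field); nc <- ncol(field)
  # even FFT sizes only: the centered zero-lag index floor(n/2)+1 assumed
  # below is off by one for odd n, which would bias every offset by +1
  pr <- stats::nextn(nr + pad_px, c(2, 3, 5))
  while (pr %% 2) pr <- stats::nextn(pr + 1, c(2, 3, 5))
  pc <- stats::nextn(nc + pad_px, c(2, 3, 5))
  while (pc %% 2) pc <- stats::nextn(pc + 1, c(2, 3, 5))
  padded <- matrix(0, pr, pc)
  padded[seq_len(nr), seq_len(nc)] <- field - mean(field)
  fp <- stats::fft(padded)
  a <- Re(stats::fft(Mod(fp)^2, inverse = TRUE)) / length(padded)
  a <- fftshift2(a)
  cy <- floor(pr / 2) + 1L; cx <- floor(pc / 2) + 1L
  list(acf = a / a[cy, cx], cx = cx, cy = cy)
}

# local maxima above `thresh` within `max_r` of the center, excluding a
# blind disk of radius `s_min`; greedy non-maximum suppression at s_min
acf_peaks <- function(acf, cx, cy, thresh, s_min, max_r) {
  nr <- nrow(acf); nc <- ncol(acf)
  is_max <- acf >= thresh
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    sh <- matrix(-Inf, nr, nc)
    ys <- seq_len(nr) - s[1]; xs <- seq_len(nc) - s[2]
    oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
    sh[oky, okx] <- acf[ys[oky], xs[okx]]
    is_max <- is_max & acf >= sh
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  dx <- idx[, 2] - cx; dy <- idx[, 1] - cy
  r <- sqrt(dx^2 + dy^2)
  keep <- r >= s_min & r <= max_r
  if (!any(keep)) return(NULL)
  p <- data.frame(dx = dx[keep], dy = dy[keep],
                  value = acf[idx[keep, , drop = FALSE]])
  p <- p[order(-p$value), , drop = FALSE]
  kept <- logical(0); out <- p[0, ]
  for (i in seq_len(nrow(p))) {
    if (nrow(out) == 0 ||
        all((out$dx - p$dx[i])^2 + (out$dy - p$dy[i])^2 >= s_min^2))
      out <- rbind(out, p[i, ])
  }
  out
}

# 3-point quadratic sub-pixel refinement along one axis
quad_refine <- function(vm1, v0, vp1) {
  den <- vm1 - 2 * v0 + vp1
  if (!is.finite(den) || den >= 0) return(0)
  clamp(0.5 * (vm1 - vp1) / den, -0.5, 0.5)
}

#' Estimate ghost displacement by autocorrelation
#'
#' Finds the off-center peaks of the normalized autocorrelation of the
#' vessel-enhanced image. The strongest off-center peak gives the
#' adjacent-copy offset (sign canonicalized to `dx >= 0`, tie toward
#' `dy >= 0`); the number of visible images is inferred from the peak
#' pattern (no qualifying peak gives 1; peaks at `+-d` give 2; peaks at
#' `+-d` and `+-2d`, collinear within tolerance, give 3). Estimates below
#' the detectability floor are reported as a single image at `(0, 0)`.
#'
#' @param image a [fundus_image()] or intensity matrix, at least
#'   128 x 128.
#' @param params a [detect_params()].
#' @return A [displacement_estimate()] with `method = "autocorrelation"`.
#' @export
estimate_displacement_autocorr <- function(image, params = detect_params()) {
  px <- as_pixels(image)
  if (nrow(px) < 128 || ncol(px) < 128)
    stop_ghostgrade("image must be at least 128 x 128", "invalid_parameter")
  if (max(px) - min(px) < 1e-9)
    stop_ghostgrade("image is constant; nothing to correlate",
                    "degenerate_input")
  enh <- vessel_enhance(px, params$scales)
  max_r <- floor(0.45 * min(dim(px)))
  ac <- normalized_autocorr(enh, pad_px = max_r + 8L)
  peaks <- acf_peaks(ac$acf, ac$cx, ac$cy, params$theta_peak, params$s_min,
                     max_r)
  none <- displacement_estimate(0, 0, 0, n_images = 1, peak_strength = 0,
                                method = "autocorrelation")
  if (is.null(peaks)) return(none)
  # autocorrelation peaks come in +- pairs; keep the canonical half-plane
  half <- peaks[peaks$dx > 0 | (peaks$dx == 0 & peaks$dy > 0), , drop = FALSE]
  if (nrow(half) == 0) return(none)
  p1 <- half[1, ]
  d <- c(p1$dx, p1$dy)
  if (params$subpixel) {
    iy <- ac$cy + p1$dy; ix <- ac$cx + p1$dx
    d[1] <- d[1] + quad_refine(ac$acf[iy, ix - 1], ac$acf[iy, ix],
                               ac$acf[iy, ix + 1])
    d[2] <- d[2] + quad_refine(ac$acf[iy - 1, ix], ac$acf[iy, ix],
                               ac$acf[iy + 1, ix])
  }
  if (sqrt(sum(d^2)) < params$floor_px) return(none)
  n_images <- 2L
  if (nrow(half) > 1) {
    tol <- max(3, params$s_min)
    harm <- sqrt((half$dx[-1] - 2 * d[1])^2 + (half$dy[-1] - 2 * d[2])^2)
    if (any(harm <= tol)) n_images <- 3L
  }
  displacement_estimate(d[1], d[2], 0, n_images = n_images,
                        peak_strength = clamp(p1$value, 0, 1),
                        method = "autocorrelation")
}
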