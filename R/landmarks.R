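#' Estimate ghost displacement by vessel-landmark matching
#'
#' Implements the measurement between identical anatomical landmarks:
#' vessels are ridge-enhanced, binarized and skeletonized; bifurcations
#' (skeleton pixels with 3 or more branches) are detected; all pairwise
#' offsets between bifurcations within a search radius are formed; and the
#' displacement is the modal offset by translation consensus (a 2-D offset
#' histogram with `bin_px`-pixel bins, requiring at least `m_min`
#' supporting pairs). In a double image every duplicated bifurcation
#' contributes one pair at the true ghost offset, so the consensus bin
#' stands out against the scatter of unrelated pairs.
#'
#' Two guards keep the consensus honest: a pair only counts when the
#' ridge-response patches around its two endpoints actually resemble each
#' other (duplicated landmarks carry duplicated surroundings; unrelated
#' bifurcations rarely do), and the modal bin must stand clear of the
#' background pair density at the same offset radius. A secondary
#' consensus at twice the modal offset with a comparable share of
#' supporting pairs indicates a triple image.
#'
#' @param image a [fundus_image()] or intensity matrix.
#' @param params a [detect_params()].
#' @return A [displacement_estimate()] with `method = "landmark"`;
#'   `peak_strength` is the consensus support divided by the number of
#'   detected bifurcations (clamped to `[0, 1]`).
#' @export
match_landmarks <- function(image, params = detect_params()) {
  px <- as_pixels(image)
  v <- vessel_response(px, params)
  bif <- bifurcations_from_response(v)
  if (nrow(bif) < 2 * params$m_min)
    stop_ghostgrade(sprintf(
      "only %d bifurcations detected (need at least %d)",
      nrow(bif), 2 * params$m_min), "insufficient_landmarks")
  radius <- params$search_radius %||% (0.45 * min(dim(px)))
  ut <- which(upper.tri(matrix(0, nrow(bif), nrow(bif))), arr.ind = TRUE)
  dx <- bif[ut[, 2], 1] - bif[ut[, 1], 1]
  dy <- bif[ut[, 2], 2] - bif[ut[, 1], 2]
  r <- sqrt(dx^2 + dy^2)
  ok <- r >= params$s_min & r <= radius
  none <- displacement_estimate(0, 0, 0, n_images = 1, peak_strength = 0,
                                method = "landmark")
  if (!any(ok)) return(none)
  # duplicated landmarks carry duplicated surroundings: gate pairs on the
  # correlation of their local ridge-response patches
  sim <- patch_similarity(v, bif, ut[ok, , drop = FALSE])
  ok[ok] <- sim >= 0.4
  if (!any(ok)) return(none)
  # each unordered pair enters the histogram at both +v and -v, so clusters
  # straddling the dx = 0 axis (near-vertical ghosts) are not split by a
  # premature sign canonicalization
  dx <- c(dx[ok], -dx[ok]); dy <- c(dy[ok], -dy[ok]); r <- c(r[ok], r[ok])
  bx <- floor(dx / params$bin_px); by <- floor(dy / params$bin_px)
  key <- paste(bx, by)
  tab <- sort(table(key), decreasing = TRUE)
  # bin edges can split a cluster, so refine each of the top candidate bins
  # (average every offset within 1.5 bins of the bin mean) and keep the
  # refinement recruiting the most pairs
  near <- logical(length(dx)); support <- 0L
  for (modal in names(tab)[seq_len(min(8L, length(tab)))]) {
    in_modal <- key == modal
    d0 <- c(mean(dx[in_modal]), mean(dy[in_modal]))
    cand <- sqrt((dx - d0[1])^2 + (dy - d0[2])^2) <= 1.5 * params$bin_px
    if (sum(cand) > support) { near <- cand; support <- sum(cand) }
  }
  # a genuine consensus recruits a visible fraction of the landmark set;
  # a handful of coincident pairs among many bifurcations does not
  if (support < max(params$m_min, 0.08 * nrow(bif))) return(none)
  d <- c(mean(dx[near]), mean(dy[near]))
  # background check at the same offset radius (bifurcations cluster along
  # vessels, so short spurious offsets are common in single images)
  r_modal <- sqrt(sum(d^2))
  ring <- abs(r - r_modal) <= 2 * params$bin_px & !near
  ring_area <- pi * 8 * r_modal * params$bin_px        # full-plane annulus
  bg_per_bin <- sum(ring) * pi * (1.5 * params$bin_px)^2 / max(ring_area, 1)
  if (support < 2.5 * bg_per_bin) return(none)
  if (r_modal < params$floor_px) return(none)
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d     # canonical sign
  # secondary consensus at twice the modal offset -> triple image; a true
  # triple supports the 2d bin with roughly half the pairs of the d bin
  tol <- max(3, params$bin_px * 1.5)
  near2 <- sqrt((dx - 2 * d[1])^2 + (dy - 2 * d[2])^2) <= tol
  n_images <- if (sum(near2) >= max(params$m_min, 0.25 * support)) 3L else 2L
  displacement_estimate(d[1], d[2], 0, n_images = n_images,
                        peak_strength = clamp(support / nrow(bif), 0, 1),
                        method = "landmark")
}

# correlation of square ridge-response patches around the two endpoints of
# each candidate pair; pairs whose patch falls off canvas get similarity 0
patch_similarity <- function(v, bif, pairs, half = 9L) {
  n <- nrow(pairs)
  if (n == 0) return(numeric(0))
  nr <- nrow(v); nc <- ncol(v)
  patch <- function(p) {
    x <- round(p[1]); y <- round(p[2])
    if (x - half < 0 || x + half > nc - 1 || y - half < 0 || y + half > nr - 1)
      return(NULL)
    v[(y - half):(y + half) + 1, (x - half):(x + half) + 1]
  }
  patches <- apply(bif, 1, patch, simplify = FALSE)
  vapply(seq_len(n), function(k) {
    a <- patches[[pairs[k, 1]]]; b <- patches[[pairs[k, 2]]]
    if (is.null(a) || is.null(b)) return(0)
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa < 1e-9 || sb < 1e-9) return(0)
    stats::cor(as.vector(a), as.vector(b))
  }, 0)
}
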