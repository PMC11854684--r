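# Vessel enhancement and skeleton analysis.
#
# Ghost contrast lives in the vessel structure, so both estimators work on
# a ridge-enhanced image: a multiscale Hessian filter that responds to dark
# line-like structures and suppresses the low-frequency shading of the disc
# and background.

#' Enhance retinal vessels with a multiscale Hessian ridge filter
#'
#' For each Gaussian scale the image is convolved with second-derivative
#' kernels; at a dark ridge the larger Hessian eigenvalue is strongly
#' positive while the smaller one stays near zero. The response is the
#' scale-normalized positive principal eigenvalue damped by the eigenvalue
#' ratio (so blob-like structures such as the disc edge are attenuated),
#' maximized over scales and rescaled to `[0, 1]`.
#'
#' @param image a [fundus_image()] or intensity matrix.
#' @param scales Gaussian scales, pixels.
#' @return Matrix of vesselness responses in `[0, 1]`.
#' @export
vessel_enhance <- function(image, scales = c(1.5, 3)) {
  px <- as_pixels(image)
  resp <- matrix(0, nrow(px), ncol(px))
  for (s in scales) {
    k <- gauss_deriv_kernels(s)
    gxx <- conv2_replicate(px, k$xx)
    gyy <- conv2_replicate(px, k$yy)
    gxy <- conv2_replicate(px, k$xy)
    tr <- gxx + gyy
    dsc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    l1 <- (tr + dsc) / 2             # principal (most positive) eigenvalue
    l2 <- (tr - dsc) / 2
    r <- abs(l2) / pmax(abs(l1), 1e-12)
    v <- s^2 * pmax(l1, 0) * exp(-2 * r^2)
    resp <- pmax(resp, v)
  }
  mx <- max(resp)
  if (mx > 0) resp <- resp / mx
  resp
}

# sampled Gaussian second-derivative kernels at scale sigma
gauss_deriv_kernels <- function(sigma) {
  r <- as.integer(ceiling(3.5 * sigma))
  u <- -r:r
  g <- exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  g2 <- (u^2 / sigma^4 - 1 / sigma^2) * g   # d2/du2 of the 1-D Gaussian
  g1 <- (-u / sigma^2) * g                  # d/du
  list(xx = outer(g, g2), yy = outer(g2, g), xy = outer(g1, g1))
}

shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  ok_y <- ys >= 1 & ys <= nr; ok_x <- xs >= 1 & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Skeletonize a binary vessel mask
#'
#' Morphological thinning (Zhang-Suen) applied until convergence, yielding
#' a 1-pixel-wide centerline on which bifurcations can be detected.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety cap on thinning iterations.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask, max_iter = 100) {
  p <- mask > 0
  # 8-neighborhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
  nbr_shifts <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                     c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- lapply(nbr_shifts, function(s) shift_mat(p, s[1], s[2]))
      bsum <- Reduce(`+`, nb)
      a <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        a <- a + (!nb[[i]] & nb[[j]])
      }
      if (phase == 1) {
        cond <- !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- p & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) { p <- p & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  p
}

neighbor_count <- function(sk) {
  Reduce(`+`, lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                          c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                     function(s) shift_mat(sk, s[1], s[2])))
}

# crossing number: 0->1 transitions around the 8-neighborhood; 1 for line
# ends, 2 along a line, >= 3 at branch points (robust to staircase corners,
# which have 3 raw neighbors but only 2 transitions)
crossing_number <- function(sk) {
  shifts <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(shifts, function(s) shift_mat(sk, s[1], s[2]))
  a <- matrix(0L, nrow(sk), ncol(sk))
  for (i in 1:8) {
    j <- if (i == 8) 1 else i + 1
    a <- a + (!nb[[i]] & nb[[j]])
  }
  a
}

# iteratively remove skeleton endpoints; kills spurs up to `n_iter` px long
# (spurs from mask raggedness create false T-junctions)
prune_spurs <- function(sk, n_iter = 6) {
  for (i in seq_len(n_iter)) {
    ends <- sk & neighbor_count(sk) <= 1
    if (!any(ends)) break
    sk <- sk & !ends
  }
  sk
}

#' Detect vessel bifurcations in a fundus image
#'
#' Vessels are ridge-enhanced, binarized (Otsu on the response, bounded
#' below by a high quantile because vessels cover only a few percent of a
#' fundus photo), skeletonized, and spur-pruned; bifurcations are skeleton
#' pixels with at least 3 skeleton neighbors, with clustered detections
#' within `merge_px` merged.
#'
#' @param image a [fundus_image()] or matrix.
#' @param params a [detect_params()].
#' @param merge_px cluster-merge radius, pixels.
#' @return n x 2 matrix of 0-based `(x, y)` bifurcation coordinates.
#' @export
detect_bifurcations <- function(image, params = detect_params(), merge_px = 4) {
  v <- vessel_response(as_pixels(image), params)
  bifurcations_from_response(v, merge_px)
}

# blurred, normalized ridge response shared by the bifurcation detector and
# the landmark matcher (the blur merges the double-edge responses a wide
# vessel produces at small filter scales)
vessel_response <- function(px, params) {
  v <- gauss_blur(vessel_enhance(px, params$scales), 1.5)
  v / max(v, 1e-12)
}

bifurcations_from_response <- function(v, merge_px = 4) {
  thr <- max(stats::quantile(v, 0.90), 0.08)
  sk <- prune_spurs(skeletonize(v > thr))
  idx <- which(sk & crossing_number(sk) >= 3, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("x", "y"))))
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  merge_close_points(pts, merge_px)
}

# greedy cluster merge: average points within `r` of an unclaimed point
merge_close_points <- function(pts, r) {
  if (nrow(pts) <= 1) return(pts)
  used <- rep(FALSE, nrow(pts))
  out <- list()
  for (i in seq_len(nrow(pts))) {
    if (used[i]) next
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    grp <- !used & d2 <= r^2
    used[grp] <- TRUE
    out[[length(out) + 1L]] <- colMeans(pts[grp, , drop = FALSE])
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y")
  m
}
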