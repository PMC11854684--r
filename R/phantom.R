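#' Branching parameters for the synthetic vessel tree
#'
#' Controls the random binary-branching vessel tree drawn on the phantom.
#' Calibers decrease monotonically from trunk to periphery, as in real
#' retinal arcades.
#'
#' @param n_trunks number of arcade trunks leaving the disc.
#' @param trunk_caliber trunk vessel caliber, pixels.
#' @param step walk step length, pixels.
#' @param drift_sd s.d. of the per-step direction drift, degrees.
#' @param branch_prob per-step probability of a bifurcation.
#' @param caliber_ratio caliber multipliers `(continuation, branch)` applied
#'   at each bifurcation; both must be in (0, 1).
#' @param min_caliber caliber, pixels, at which a vessel terminates.
#' @param branch_angle range (degrees) of the angle between a new branch
#'   and its parent.
#' @param margin border margin, pixels, inside which vessels stop.
#' @return A list of class `branching_params`.
#' @export
branching_params <- function(n_trunks = 4, trunk_caliber = 5, step = 6,
                             drift_sd = 8, branch_prob = 0.12,
                             caliber_ratio = c(0.85, 0.7), min_caliber = 1.1,
                             branch_angle = c(25, 50), margin = 12) {
  vals <- c(n_trunks, trunk_caliber, step, drift_sd, branch_prob,
            caliber_ratio, min_caliber, branch_angle, margin)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_ghostgrade("branching parameters must be positive", "invalid_parameter")
  if (any(caliber_ratio >= 1))
    stop_ghostgrade("`caliber_ratio` must be < 1 so caliber decreases",
                    "invalid_parameter")
  structure(list(n_trunks = n_trunks, trunk_caliber = trunk_caliber,
                 step = step, drift_sd = drift_sd, branch_prob = branch_prob,
                 caliber_ratio = caliber_ratio, min_caliber = min_caliber,
                 branch_angle = branch_angle, margin = margin),
            class = "branching_params")
}

#' Generate a synthetic fundus phantom
#'
#' Builds a grayscale retinal phantom: a smoothly shaded background, a
#' bright optic disc, a darker macula temporal to the disc, and a dark
#' random binary-branching vessel tree rooted at the disc whose caliber
#' decreases monotonically toward the periphery. Vessel bifurcations --
#' the anatomical landmarks used for displacement measurement -- are
#' returned as ground truth. The phantom is a pure function of
#' `(size_px, seed, branching)`; identical inputs give a bit-identical
#' canvas.
#'
#' @param size_px image size as `(width, height)` in pixels; at least
#'   256 x 256.
#' @param seed integer RNG seed.
#' @param branching a [branching_params()] object.
#' @param disc_frac optic-disc diameter as a fraction of image width
#'   (default 0.08, the typical disc-to-field ratio of a 45-degree
#'   fundus photograph).
#' @return An object of class `vessel_phantom` with fields `canvas`
#'   (matrix in `[0, 1]`, rows = y), `disc_center`, `disc_diameter_px`,
#'   `macula_center`, `bifurcations` (n x 2 matrix of 0-based `(x, y)`),
#'   and `seed`.
#' @examples
#' ph <- generate_vessel_phantom(c(320, 320), seed = 7)
#' nrow(ph$bifurcations) >= 10
#' @export
generate_vessel_phantom <- function(size_px = c(512, 512), seed = 1,
                                    branching = branching_params(),
                                    disc_frac = 0.08) {
  if (length(size_px) != 2L || any(size_px < 256))
    stop_ghostgrade("`size_px` must be a (width, height) pair, each >= 256",
                    "invalid_parameter")
  if (!inherits(branching, "branching_params"))
    branching <- do.call(branching_params, as.list(branching))
  if (disc_frac <= 0 || disc_frac > 0.15)
    stop_ghostgrade("`disc_frac` must be in (0, 0.15]", "invalid_parameter")
  w <- as.integer(size_px[1]); h <- as.integer(size_px[2])
  disc_d <- disc_frac * w
  disc_c <- c(0.30 * (w - 1), 0.50 * (h - 1))
  if (disc_c[1] - disc_d / 2 < 0 || disc_c[1] + disc_d / 2 > w - 1 ||
      disc_c[2] - disc_d / 2 < 0 || disc_c[2] + disc_d / 2 > h - 1)
    stop_ghostgrade("image too small to contain the optic disc",
                    "invalid_parameter")
  macula_c <- disc_c + c(2.5 * disc_d, 0)

  set.seed(as.integer(seed))
  g <- expand_grid_xy(w, h)

  # background: mid-gray with low-frequency texture and a mild vignette
  tex <- gauss_blur(matrix(stats::rnorm(w * h), h, w), 18)
  tex <- tex / max(abs(range(tex)), 1e-12)
  rad2 <- ((g$x - (w - 1) / 2)^2 + (g$y - (h - 1) / 2)^2) /
    ((min(w, h) / 2)^2)
  canvas <- matrix(0.45, h, w) + 0.05 * tex -
    matrix(0.06 * clamp(rad2, 0, 1), h, w)

  # bright disc with a soft edge
  dd <- sqrt((g$x - disc_c[1])^2 + (g$y - disc_c[2])^2)
  edge <- 0.12 * disc_d
  canvas <- canvas +
    matrix(0.38 * clamp((disc_d / 2 - dd) / edge + 0.5, 0, 1), h, w)

  # darker macula (Gaussian darkening, sd ~ 0.6 disc diameters)
  dm2 <- (g$x - macula_c[1])^2 + (g$y - macula_c[2])^2
  canvas <- canvas - matrix(0.13 * exp(-dm2 / (2 * (0.6 * disc_d)^2)), h, w)

  # vessel tree: retry deterministically (same RNG stream) until enough
  # bifurcations land on the canvas
  tree <- NULL
  for (attempt in 1:8) {
    tree <- grow_vessel_tree(w, h, disc_c, disc_d, branching)
    if (nrow(tree$bifurcations) >= 10) break
  }
  if (nrow(tree$bifurcations) < 10)
    stop_ghostgrade("failed to grow a vessel tree with >= 10 bifurcations",
                    "degenerate_input")
  mask <- rasterize_vessels(w, h, tree$points)
  canvas <- canvas * (1 - 0.55 * mask)

  structure(list(canvas = clamp(canvas, 0, 1),
                 disc_center = disc_c, disc_diameter_px = disc_d,
                 macula_center = macula_c,
                 bifurcations = tree$bifurcations,
                 seed = as.integer(seed), branching = branching),
            class = "vessel_phantom")
}

# random binary-branching walk from the disc rim; returns stamped centerline
# points (x, y, caliber) and bifurcation coordinates
grow_vessel_tree <- function(w, h, disc_c, disc_d, bp) {
  pts <- vector("list", 256); npts <- 0L
  bifs <- vector("list", 64); nbif <- 0L
  trunk_angles <- seq(0, 360, length.out = bp$n_trunks + 1)[-(bp$n_trunks + 1)] +
    45 + stats::rnorm(bp$n_trunks, 0, 8)
  stack <- lapply(trunk_angles, function(a) {
    u <- c(cos(deg2rad(a)), -sin(deg2rad(a)))
    list(pos = disc_c + u * disc_d / 2, angle = a,
         caliber = bp$trunk_caliber * stats::runif(1, 0.85, 1), depth = 0L)
  })
  max_steps <- ceiling(1.2 * max(w, h) / bp$step)
  while (length(stack) > 0) {
    br <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    pos <- br$pos; angle <- br$angle; cal <- br$caliber
    for (s in seq_len(max_steps)) {
      u <- c(cos(deg2rad(angle)), -sin(deg2rad(angle)))
      new <- pos + bp$step * u
      if (new[1] < bp$margin || new[1] > w - 1 - bp$margin ||
          new[2] < bp$margin || new[2] > h - 1 - bp$margin) break
      # stamp the segment densely
      nseg <- max(2L, ceiling(bp$step / 0.75))
      tt <- seq(0, 1, length.out = nseg)
      npts <- npts + 1L
      pts[[npts]] <- cbind(pos[1] + tt * (new[1] - pos[1]),
                           pos[2] + tt * (new[2] - pos[2]), cal)
      pos <- new
      angle <- angle + stats::rnorm(1, 0, bp$drift_sd)
      if (cal > bp$min_caliber / bp$caliber_ratio[2] && br$depth < 6L &&
          stats::runif(1) < bp$branch_prob) {
        nbif <- nbif + 1L
        bifs[[nbif]] <- pos
        side <- sample(c(-1, 1), 1)
        bang <- stats::runif(1, bp$branch_angle[1], bp$branch_angle[2])
        stack[[length(stack) + 1L]] <- list(
          pos = pos, angle = angle + side * bang,
          caliber = cal * bp$caliber_ratio[2], depth = br$depth + 1L)
        angle <- angle - side * bang * 0.4
        cal <- cal * bp$caliber_ratio[1]
      }
      if (cal < bp$min_caliber) break
    }
  }
  bifm <- if (nbif > 0) do.call(rbind, bifs[seq_len(nbif)]) else
    matrix(numeric(0), 0, 2)
  colnames(bifm) <- c("x", "y")
  list(points = do.call(rbind, pts[seq_len(max(npts, 1L))]),
       bifurcations = bifm)
}

# stamp soft disks of radius caliber/2 along the centerline into a [0,1] mask
rasterize_vessels <- function(w, h, points) {
  mask <- matrix(0, h, w)
  if (is.null(points) || nrow(points) == 0) return(mask)
  for (i in seq_len(nrow(points))) {
    x <- points[i, 1]; y <- points[i, 2]; r <- points[i, 3] / 2
    x0 <- max(0L, floor(x - r - 1)); x1 <- min(w - 1L, ceiling(x + r + 1))
    y0 <- max(0L, floor(y - r - 1)); y1 <- min(h - 1L, ceiling(y + r + 1))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d <- sqrt(outer((ys - y)^2, (xs - x)^2, `+`))
    stamp <- clamp(r + 0.5 - d, 0, 1)
    sub <- mask[ys + 1, xs + 1, drop = FALSE]
    mask[ys + 1, xs + 1] <- pmax(sub, stamp)
  }
  mask
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf(
    "<vessel_phantom> %d x %d px, disc (%.0f, %.0f) d=%.1f, %d bifurcations, seed %d\n",
    ncol(x$canvas), nrow(x$canvas), x$disc_center[1], x$disc_center[2],
    x$disc_diameter_px, nrow(x$bifurcations), x$seed))
  invisible(x)
}

#' @export
plot.vessel_phantom <- function(x, ...) {
  plot(fundus_image(x$canvas, x$disc_center, x$disc_diameter_px,
                    eye_id = sprintf("phantom seed %d", x$seed)), ...)
}
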