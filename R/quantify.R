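#' Quantify the ghost structure of a fundus photograph
#'
#' The main per-image entry point of the quantitative arm: estimates the
#' ghost displacement (by autocorrelation, vessel-landmark matching, or
#' both), the rotation component about the fixation center, and the optic
#' disc geometry used for normalization, and bundles everything in a
#' `ghost_fit` object with `print`, `summary`, `coef` and `plot` methods.
#'
#' @param image a [fundus_image()] or intensity matrix.
#' @param method `"autocorr"`, `"landmark"`, or `"both"`. With `"both"`,
#'   the autocorrelation estimate is the primary one and the landmark
#'   estimate is kept for cross-checking.
#' @param params a [detect_params()].
#' @return An object of class `ghost_fit` with fields `estimate` (the
#'   primary [displacement_estimate()], rotation filled in), `landmark`
#'   (secondary estimate or `NULL`), `disc_center`, `disc_diameter_px`,
#'   `eye_id`, `params`.
#' @examples
#' ph <- generate_vessel_phantom(c(320, 320), seed = 3)
#' tr <- trajectory_truth("horizontal", c(20, 0), n_images = 2)
#' img <- render_ghost_image(ph, tr)
#' fit <- quantify_ghosts(img)
#' coef(fit)
#' @export
quantify_ghosts <- function(image, method = c("autocorr", "landmark", "both"),
                            params = detect_params()) {
  method <- match.arg(method)
  px <- as_pixels(image)
  if (inherits(image, "fundus_image") && !is.null(image$disc_center) &&
      !is.null(image$disc_diameter_px)) {
    disc <- list(disc_center = image$disc_center,
                 disc_diameter_px = image$disc_diameter_px)
  } else {
    disc <- estimate_disc_geometry(px)
  }
  fix_center <- disc$disc_center + c(2.5 * disc$disc_diameter_px, 0)
  fix_center <- clamp(fix_center,
                      params$annulus[2] * min(dim(px)) + 1,
                      c(ncol(px), nrow(px)) - 1 -
                        params$annulus[2] * min(dim(px)))
  est <- lm_est <- NULL
  if (method %in% c("autocorr", "both"))
    est <- estimate_displacement_autocorr(px, params)
  if (method %in% c("landmark", "both"))
    lm_est <- match_landmarks(px, params)
  if (is.null(est)) { est <- lm_est; lm_est <- NULL }
  rot <- estimate_rotation(px, center = fix_center, params = params,
                           exclude_translation_px = displacement_norm(est))
  est$rotation_deg <- rot
  est$arc_radius_px <- mean(params$annulus) * min(dim(px))
  if (est$n_images == 1L && rot >= params$floor_deg)
    est$n_images <- 2L  # rotation-only ghost still means a duplicated image
  structure(list(estimate = est, landmark = lm_est,
                 disc_center = disc$disc_center,
                 disc_diameter_px = disc$disc_diameter_px,
                 eye_id = if (inherits(image, "fundus_image")) image$eye_id
                          else "eye",
                 params = params),
            class = "ghost_fit")
}

#' @export
print.ghost_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("<ghost_fit> %s\n", x$eye_id))
  cat(sprintf("  displacement: (%.2f, %.2f) px  |d| = %.2f px\n",
              e$dx_px, e$dy_px, displacement_norm(e)))
  cat(sprintf("  rotation:     %.2f deg\n", e$rotation_deg))
  cat(sprintf("  images:       %d   peak strength: %.2f   method: %s\n",
              e$n_images, e$peak_strength, e$method))
  cat(sprintf("  disc:         (%.1f, %.1f), diameter %.1f px\n",
              x$disc_center[1], x$disc_center[2], x$disc_diameter_px))
  invisible(x)
}

#' @export
summary.ghost_fit <- function(object, thresholds = grade_thresholds(), ...) {
  g <- grade_photo(object, thresholds = thresholds)
  out <- list(fit = object, grade = g,
              normalized_displacement = g$normalized_displacement)
  class(out) <- "summary.ghost_fit"
  out
}

#' @export
print.summary.ghost_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  normalized:   %.3f disc diameters\n",
              x$normalized_displacement))
  cat(sprintf("  grade:        %d (%s)\n", x$grade$amplitude_grade,
              x$grade$direction_class))
  if (!is.null(x$fit$landmark))
    cat(sprintf("  landmark xcheck: (%.2f, %.2f) px, %d image(s)\n",
                x$fit$landmark$dx_px, x$fit$landmark$dy_px,
                x$fit$landmark$n_images))
  invisible(x)
}

#' @export
coef.ghost_fit <- function(object, ...) {
  e <- object$estimate
  c(dx_px = e$dx_px, dy_px = e$dy_px,
    displacement_px = displacement_norm(e),
    rotation_deg = e$rotation_deg, n_images = e$n_images,
    peak_strength = e$peak_strength)
}

#' @export
plot.ghost_fit <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    plot(image, ...)
    px <- as_pixels(image)
    e <- x$estimate
    cx <- (x$disc_center[1] + 0.5) / ncol(px)
    cy <- 1 - (x$disc_center[2] + 0.5) / nrow(px)
    graphics::symbols(cx, cy, circles = x$disc_diameter_px / 2 / ncol(px),
                      inches = FALSE, add = TRUE, fg = "yellow")
    graphics::arrows(cx, cy, cx + e$dx_px / ncol(px), cy - e$dy_px / nrow(px),
                     col = "red", length = 0.08)
  } else {
    graphics::plot(c(-1, 1), c(-1, 1), type = "n", xlab = "dx (px)",
                   ylab = "dy (px)", main = x$eye_id, asp = 1)
    e <- x$estimate
    m <- max(1, displacement_norm(e))
    graphics::arrows(0, 0, e$dx_px / m, -e$dy_px / m, col = "red",
                     length = 0.08)
  }
  invisible(x)
}

#' Per-image quantification results as a CSV row
#'
#' @param fit a [quantify_ghosts()] result.
#' @return One-row data frame with columns `eye_id`, `method`, `dx_px`,
#'   `dy_px`, `displacement_px`, `rotation_deg`, `n_images`,
#'   `peak_strength`, `disc_diameter_px`.
#' @export
as.data.frame.ghost_fit <- function(x, ...) {
  e <- x$estimate
  data.frame(eye_id = x$eye_id, method = e$method, dx_px = e$dx_px,
             dy_px = e$dy_px, displacement_px = displacement_norm(e),
             rotation_deg = e$rotation_deg, n_images = e$n_images,
             peak_strength = e$peak_strength,
             disc_diameter_px = x$disc_diameter_px,
             stringsAsFactors = FALSE)
}
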