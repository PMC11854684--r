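#' Fundus image container
#'
#' A `fundus_image` bundles a grayscale raster (intensities in `[0, 1]`,
#' stored as a matrix with rows = y, columns = x) with the pixel-geometry
#' metadata every measurement relies on: the optic-disc center and diameter
#' (the standard anatomical yardstick used to normalize displacement), eye
#' identity and laterality, and an optional session date for longitudinal
#' series.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' x rightward and y downward; angles are degrees, counterclockwise on
#' screen. A nystagmus displacement of the eye is reported as the
#' displacement of the retinal image, with no sign flip.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]` (rows = y).
#' @param disc_center optional optic-disc center, 0-based `(x, y)` pair.
#' @param disc_diameter_px optional optic-disc diameter in pixels.
#' @param eye_id identifier string.
#' @param laterality `"OD"`, `"OS"` or `"unknown"`.
#' @param session_date optional ISO-8601 date string or `Date`.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, disc_center = NULL, disc_diameter_px = NULL,
                         eye_id = "eye", laterality = "unknown",
                         session_date = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_ghostgrade("`pixels` must be a numeric matrix", "invalid_parameter")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_ghostgrade("`pixels` must be finite", "invalid_parameter")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_ghostgrade("`pixels` must lie in [0, 1]", "invalid_parameter")
  if (!is.null(disc_diameter_px))
    assert_scalar_number(disc_diameter_px, "disc_diameter_px", positive = TRUE)
  if (!is.null(disc_center) && length(disc_center) != 2L)
    stop_ghostgrade("`disc_center` must be an (x, y) pair", "invalid_parameter")
  laterality <- match.arg(laterality, c("OD", "OS", "unknown"))
  if (!is.null(session_date)) session_date <- as.Date(session_date)
  structure(
    list(pixels = pixels,
         disc_center = if (!is.null(disc_center)) as.numeric(disc_center),
         disc_diameter_px = disc_diameter_px,
         eye_id = as.character(eye_id),
         laterality = laterality,
         session_date = session_date),
    class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %s (%s), %d x %d px\n", x$eye_id, x$laterality,
              ncol(x$pixels), nrow(x$pixels)))
  if (!is.null(x$disc_center))
    cat(sprintf("  disc: center (%.1f, %.1f), diameter %.1f px\n",
                x$disc_center[1], x$disc_center[2],
                x$disc_diameter_px %||% NA_real_))
  if (!is.null(x$session_date)) cat("  session:", format(x$session_date), "\n")
  invisible(x)
}

#' @export
plot.fundus_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5)); on.exit(graphics::par(op))
  graphics::image(t(x$pixels)[, nrow(x$pixels):1], col = grDevices::gray(0:255 / 255),
                  axes = FALSE, asp = nrow(x$pixels) / ncol(x$pixels),
                  main = x$eye_id, ...)
  invisible(x)
}

# accept either a fundus_image or a bare matrix in estimator entry points
as_pixels <- function(image) {
  if (inherits(image, "fundus_image")) image$pixels
  else if (is.matrix(image)) image
  else stop_ghostgrade("expected a fundus_image or numeric matrix",
                       "invalid_parameter")
}

#' Read a fundus photograph from disk
#'
#' Reads PNG, TIFF or JPEG rasters and converts them to grayscale in
#' `[0, 1]` using luma weights 0.299/0.587/0.114.
#'
#' @param path image file path.
#' @param eye_id identifier; defaults to the file name without extension.
#' @param ... further arguments passed to [fundus_image()].
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path, eye_id = NULL, ...) {
  if (!file.exists(path))
    stop_ghostgrade(sprintf("file not found: '%s'", path), "io_error")
  a <- EBImage::imageData(EBImage::readImage(path))  # [x, y(, c)]
  if (length(dim(a)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    nch <- min(dim(a)[3], 3L)
    g <- matrix(0, dim(a)[1], dim(a)[2])
    for (ch in seq_len(nch)) g <- g + w[ch] * a[, , ch]
    if (nch == 1L) g <- a[, , 1]
    a <- g
  }
  fundus_image(clamp(t(a), 0, 1),
               eye_id = eye_id %||% tools::file_path_sans_ext(basename(path)),
               ...)
}

#' Write a fundus image as an 8-bit grayscale PNG
#'
#' @param image a [fundus_image()] or intensity matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(image, path) {
  px <- as_pixels(image)
  write_atomic(function(tmp) png::writePNG(clamp(px, 0, 1), tmp), path)
}
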