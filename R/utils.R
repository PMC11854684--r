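# Internal helpers shared across the package.
#
# Coordinate convention (documented in the I/O contract and used everywhere):
# pixel coordinates are 0-based, origin at the top-left corner, x rightward,
# y downward. A canvas is stored as a base R numeric matrix with rows = y and
# columns = x, so pixel (x, y) lives at canvas[y + 1, x + 1]. Angles are in
# degrees, measured counterclockwise as seen on screen (i.e. from +x toward
# -y in matrix terms).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ghostgrade <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ghostgrade_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ghostgrade(sprintf("`%s` must be a finite numeric scalar", name),
                    "invalid_parameter")
  if (positive && x <= 0)
    stop_ghostgrade(sprintf("`%s` must be positive", name), "invalid_parameter")
  invisible(x)
}

# round-half-up, matching clinical-table style (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180

# rotation matrix for screen-counterclockwise rotation in (x, y-down) coords:
# theta > 0 moves (1, 0) toward (cos, -sin), i.e. visually counterclockwise.
rot_mat <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2, byrow = TRUE)
}

# Bilinear sample of matrix `m` (rows = y, cols = x) at 0-based fractional
# coordinates; out-of-range coordinates are clamped (edge replication).
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- clamp(x, 0, nc - 1)
  y <- clamp(y, 0, nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + nr * x0; i10 <- y0 + 1 + nr * x1
  i01 <- y1 + 1 + nr * x0; i11 <- y1 + 1 + nr * x1
  (m[i00] * (1 - fx) + m[i10] * fx) * (1 - fy) +
    (m[i01] * (1 - fx) + m[i11] * fx) * fy
}

# Rigid warp: the image CONTENT is rotated by theta_deg about `center`
# (0-based (x, y)) and then translated by (dx, dy). Implemented by inverse
# mapping with bilinear interpolation and edge replication.
warp_rigid <- function(m, dx = 0, dy = 0, theta_deg = 0, center = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- c((nc - 1) / 2, (nr - 1) / 2)
  g <- expand_grid_xy(nc, nr)
  R <- rot_mat(-theta_deg)  # inverse rotation
  qx <- g$x - dx - center[1]
  qy <- g$y - dy - center[2]
  sx <- R[1, 1] * qx + R[1, 2] * qy + center[1]
  sy <- R[2, 1] * qx + R[2, 2] * qy + center[2]
  matrix(bilinear_sample(m, sx, sy), nr, nc)
}

# fraction of output pixels whose source location under the inverse rigid
# transform falls inside the canvas (used for the off-canvas precondition)
inside_fraction <- function(dim_rc, dx, dy, theta_deg, center) {
  nr <- dim_rc[1]; nc <- dim_rc[2]
  xs <- seq(0, nc - 1, by = 4); ys <- seq(0, nr - 1, by = 4)
  g <- list(x = rep(xs, each = length(ys)), y = rep(ys, length(xs)))
  R <- rot_mat(-theta_deg)
  qx <- g$x - dx - center[1]
  qy <- g$y - dy - center[2]
  sx <- R[1, 1] * qx + R[1, 2] * qy + center[1]
  sy <- R[2, 1] * qx + R[2, 2] * qy + center[2]
  mean(sx >= 0 & sx <= nc - 1 & sy >= 0 & sy <= nr - 1)
}

expand_grid_xy <- function(nc, nr) {
  list(x = rep(0:(nc - 1), each = nr), y = rep.int(0:(nr - 1), nc))
}

# Gaussian blur through EBImage (FFT convolution, replicated boundary).
# EBImage stores images as [x, y]; our matrices are [y, x], so transpose.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sz <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  k <- EBImage::makeBrush(sz, shape = "gaussian", sigma = sigma)
  t(EBImage::filter2(t(m), k, boundary = "replicate"))
}

conv2_replicate <- function(m, k) {
  t(EBImage::filter2(t(m), k, boundary = "replicate"))
}

# atomic write: write to a sibling temp file, then rename into place
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop_ghostgrade(sprintf("failed to move temporary file into '%s'", path),
                    "io_error")
  invisible(path)
}
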