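# Shared fixtures. Phantoms are deterministic in (size, seed, params), so a
# per-session cache keeps the suite fast without coupling tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(seed = 1, size = c(384, 384), disc_frac = 0.08) {
  key <- paste(seed, size[1], size[2], disc_frac)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_vessel_phantom(size, seed = seed,
                                                     disc_frac = disc_frac)
  .fixture_cache[[key]]
}

# noise-free ghost image with the given adjacent-copy offset/rotation
ghost_fixture <- function(d = c(24, 0), rot = 0, n = 2, seed = 1,
                          size = c(384, 384), noise = 0,
                          class = "combined") {
  ph <- cached_phantom(seed, size)
  cls <- if (n == 1) "none" else class
  tr <- trajectory_truth(cls,
                         if (n == 1) c(0, 0) else d,
                         if (n == 1) 0 else rot,
                         n_images = n, noise_sigma = noise)
  render_ghost_image(ph, tr)
}

# independent bilinear sampler used as an oracle for the warp/render tests
# (deliberately written from scratch, scalar loops, no shared code paths)
oracle_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- min(max(x, 0), nc - 1); y <- min(max(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, nc - 1); y1 <- min(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  (m[y0 + 1, x0 + 1] * (1 - fx) + m[y0 + 1, x1 + 1] * fx) * (1 - fy) +
    (m[y1 + 1, x0 + 1] * (1 - fx) + m[y1 + 1, x1 + 1] * fx) * fy
}
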