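test_that("identity trajectory reproduces the phantom exactly (no noise)", {
  ph <- cached_phantom(seed = 1)
  tr <- trajectory_truth("none", c(0, 0), 0, n_images = 1, noise_sigma = 0)
  img <- render_ghost_image(ph, tr)
  expect_equal(img$pixels, ph$canvas, tolerance = 1e-12)
})

test_that("a noise-free double is the mean of the two shifted copies", {
  ph <- cached_phantom(seed = 1)
  tr <- trajectory_truth("horizontal", c(24, 0), 0, n_images = 2,
                         noise_sigma = 0)
  img <- render_ghost_image(ph, tr)
  # copies sit symmetrically at +-(12, 0); with integer offsets the warp is
  # exact, so direct matrix indexing is the oracle
  P <- ph$canvas
  ys <- 50:300; xs <- 50:300
  expected <- 0.5 * (P[ys + 1, xs + 1 - 12] + P[ys + 1, xs + 1 + 12])
  expect_equal(img$pixels[ys + 1, xs + 1], expected, tolerance = 1e-10)
})

test_that("a rotation-6-degree double is two copies rotated +-3 degrees", {
  ph <- cached_phantom(seed = 2)
  tr <- trajectory_truth("rotary", c(0, 0), 6, n_images = 2, noise_sigma = 0)
  img <- render_ghost_image(ph, tr)
  ctr <- ph$macula_center
  set.seed(42)
  pts <- cbind(x = sample(80:300, 60), y = sample(80:300, 60))
  for (k in seq_len(nrow(pts))) {
    q <- as.numeric(pts[k, ])
    vals <- sapply(c(-3, 3), function(th) {
      # inverse-rotate the output location by th about the macula
      # (screen-CCW convention: y grows downward)
      tr_ <- -th * pi / 180
      dx <- q[1] - ctr[1]; dy <- q[2] - ctr[2]
      sx <- ctr[1] + cos(tr_) * dx + sin(tr_) * dy
      sy <- ctr[2] - sin(tr_) * dx + cos(tr_) * dy
      oracle_bilinear(ph$canvas, sx, sy)
    })
    expect_equal(img$pixels[q[2] + 1, q[1] + 1], mean(vals),
                 tolerance = 1e-8)
  }
})

test_that("mean intensity is preserved within 2 percent before noise", {
  ph <- cached_phantom(seed = 1)
  for (tr in list(trajectory_truth("horizontal", c(30, 8), 0, n_images = 2),
                  trajectory_truth("combined", c(14, 14), 3, n_images = 3),
                  trajectory_truth("rotary", c(0, 0), 8, n_images = 2))) {
    img <- render_ghost_image(ph, tr)
    expect_lt(abs(mean(img$pixels) - mean(ph$canvas)) / mean(ph$canvas),
              0.02)
  }
})

test_that("non-uniform exposure weights must sum to one", {
  expect_error(trajectory_truth("horizontal", c(10, 0), 0, n_images = 2,
                                exposure_weights = c(0.7, 0.4)),
               class = "invalid_parameter")
  expect_error(trajectory_truth("horizontal", c(10, 0), 0, n_images = 1,
                                exposure_weights = c(0.5, 0.5)),
               class = "invalid_parameter")
  w <- dominant_foveation_weights(2)
  expect_equal(sum(w), 1)
  tr <- trajectory_truth("horizontal", c(20, 0), 0, n_images = 2,
                         exposure_weights = w)
  img <- render_ghost_image(cached_phantom(seed = 1), tr)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
})

test_that("displacement pushing content off canvas raises out_of_bounds", {
  ph <- cached_phantom(seed = 1)
  tr <- trajectory_truth("horizontal", c(300, 0), 0, n_images = 2)
  expect_error(render_ghost_image(ph, tr), class = "out_of_bounds")
})

test_that("the 'none' class is only consistent with a static single image", {
  expect_error(trajectory_truth("none", c(10, 0), 0, n_images = 2),
               class = "invalid_parameter")
  expect_error(trajectory_truth("horizontal", c(0, 0), 0, n_images = 1),
               class = "invalid_parameter")
})
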