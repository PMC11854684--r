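test_that("phantom generation is deterministic in the seed", {
  a <- generate_vessel_phantom(c(320, 320), seed = 7)
  b <- generate_vessel_phantom(c(320, 320), seed = 7)
  expect_identical(a$canvas, b$canvas)
  expect_identical(a$bifurcations, b$bifurcations)
})

test_that("different seeds give substantially different canvases", {
  a <- generate_vessel_phantom(c(320, 320), seed = 7)
  b <- generate_vessel_phantom(c(320, 320), seed = 8)
  expect_gte(mean(a$canvas != b$canvas), 0.01)
})

test_that("phantom satisfies its structural invariants", {
  ph <- cached_phantom(seed = 1)
  expect_true(all(ph$canvas >= 0 & ph$canvas <= 1))
  expect_gt(ph$disc_diameter_px, 0)
  expect_gte(nrow(ph$bifurcations), 10)
  # disc fully inside the canvas
  r <- ph$disc_diameter_px / 2
  expect_true(ph$disc_center[1] - r >= 0 &&
                ph$disc_center[1] + r <= ncol(ph$canvas) - 1 &&
                ph$disc_center[2] - r >= 0 &&
                ph$disc_center[2] + r <= nrow(ph$canvas) - 1)
  # the disc region is brighter than the image median, vessels darker
  g <- expand.grid(y = 0:(nrow(ph$canvas) - 1), x = 0:(ncol(ph$canvas) - 1))
  inside <- (g$x - ph$disc_center[1])^2 + (g$y - ph$disc_center[2])^2 < r^2 / 4
  expect_gt(mean(ph$canvas[as.logical(inside)]), median(ph$canvas) + 0.1)
})

test_that("undersized or disc-less canvases are rejected", {
  expect_error(generate_vessel_phantom(c(128, 128), seed = 1),
               class = "invalid_parameter")
  expect_error(generate_vessel_phantom(c(320, 320), seed = 1, disc_frac = 0.5),
               class = "invalid_parameter")
  expect_error(branching_params(caliber_ratio = c(1.2, 0.7)),
               class = "invalid_parameter")
})
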