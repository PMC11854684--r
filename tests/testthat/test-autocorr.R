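test_that("autocorrelation recovers a double-image offset within 1 px", {
  img <- ghost_fixture(d = c(24, 0), n = 2)
  e <- estimate_displacement_autocorr(img)
  expect_equal(e$n_images, 2L)
  expect_lt(ghost_offset_distance(e, c(24, 0)), 1)
  expect_gt(e$peak_strength, 0.2)
})

test_that("a single exposure yields no off-center peak", {
  img <- ghost_fixture(n = 1)
  e <- estimate_displacement_autocorr(img)
  expect_equal(e$n_images, 1L)
  expect_equal(c(e$dx_px, e$dy_px), c(0, 0))
})

test_that("an equally spaced triple is recognized with its adjacent offset", {
  img <- ghost_fixture(d = c(12, 12), n = 3)
  e <- estimate_displacement_autocorr(img)
  expect_equal(e$n_images, 3L)
  expect_lt(ghost_offset_distance(e, c(12, 12)), 1)
})

test_that("sign convention: dx nonnegative, deterministic output", {
  img <- ghost_fixture(d = c(0, 20), n = 2)
  e1 <- estimate_displacement_autocorr(img)
  e2 <- estimate_displacement_autocorr(img)
  expect_gte(e1$dx_px, 0)
  expect_identical(c(e1$dx_px, e1$dy_px), c(e2$dx_px, e2$dy_px))
  expect_lt(ghost_offset_distance(e1, c(0, 20)), 1)
})

test_that("translating the whole scene does not create a false ghost", {
  ph <- cached_phantom(seed = 3)
  shifted <- ghostgrade:::warp_rigid(ph$canvas, dx = 15, dy = 7)
  e <- estimate_displacement_autocorr(shifted)
  expect_equal(e$n_images, 1L)
  expect_equal(c(e$dx_px, e$dy_px), c(0, 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(estimate_displacement_autocorr(matrix(0.5, 256, 256)),
               class = "degenerate_input")
  expect_error(estimate_displacement_autocorr(matrix(0.5, 64, 64)),
               class = "invalid_parameter")
})

test_that("estimates survive moderate sensor noise", {
  set.seed(1)
  img <- ghost_fixture(d = c(18, -12), n = 2, noise = 0.05, seed = 4)
  e <- estimate_displacement_autocorr(img)
  expect_equal(e$n_images, 2L)
  expect_lt(ghost_offset_distance(e, c(18, -12)), 1)
})
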