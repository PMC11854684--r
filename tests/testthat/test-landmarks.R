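test_that("landmark consensus recovers a double-image offset within 2 px", {
  img <- ghost_fixture(d = c(0, 20), n = 2, seed = 5, size = c(512, 512))
  e <- match_landmarks(img)
  expect_equal(e$method, "landmark")
  expect_equal(e$n_images, 2L)
  expect_lt(ghost_offset_distance(e, c(0, 20)), 2)
})

test_that("a single exposure produces no off-origin consensus", {
  img <- ghost_fixture(n = 1, seed = 5, size = c(512, 512))
  e <- match_landmarks(img)
  expect_equal(e$n_images, 1L)
  expect_equal(c(e$dx_px, e$dy_px), c(0, 0))
})

test_that("bifurcation detection finds landmarks near the true tree", {
  ph <- cached_phantom(seed = 5, size = c(512, 512))
  bif <- detect_bifurcations(ph$canvas)
  expect_gte(nrow(bif), 10)
  # most detections lie within a vessel caliber of a true bifurcation
  d2 <- apply(bif, 1, function(p)
    min((ph$bifurcations[, 1] - p[1])^2 + (ph$bifurcations[, 2] - p[2])^2))
  expect_gte(mean(sqrt(d2) <= 6), 0.5)
})

test_that("featureless images raise insufficient-landmarks", {
  flat <- matrix(0.5, 384, 384)
  flat[100, 100] <- 0.6   # non-constant but featureless
  expect_error(match_landmarks(flat), class = "insufficient_landmarks")
})

test_that("landmark and autocorrelation estimates agree on doubles", {
  for (s in 6:8) {
    d <- list(c(26, 0), c(14, 18), c(0, 22))[[s - 5]]
    img <- ghost_fixture(d = d, n = 2, seed = s, size = c(512, 512))
    a <- estimate_displacement_autocorr(img)
    l <- match_landmarks(img)
    expect_lt(ghost_offset_distance(a, l), 2)
  }
})
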