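est <- function(dx, dy = 0, rot = 0, n = 2)
  displacement_estimate(dx, dy, rot, n_images = n,
                        peak_strength = if (n > 1) 0.5 else 0,
                        arc_radius_px = 150)

test_that("amplitude grade maps normalized displacement to the 0-3 scale", {
  dd <- 40
  expect_equal(amplitude_grade(est(0, n = 1), dd), 0L)
  expect_equal(amplitude_grade(est(0.10 * dd), dd), 1L)
  expect_equal(amplitude_grade(est(0.25 * dd), dd), 2L)
  expect_equal(amplitude_grade(est(0.50 * dd), dd), 3L)
})

test_that("grade bins are lower-inclusive at the cut-points", {
  dd <- 100   # cut-points land on exact pixel values
  expect_equal(amplitude_grade(est(15), dd), 2L)   # d = 0.15 exactly
  expect_equal(amplitude_grade(est(40), dd), 3L)   # d = 0.40 exactly
  expect_equal(amplitude_grade(est(15 - 1e-9), dd), 1L)
  expect_equal(amplitude_grade(est(40 - 1e-9), dd), 2L)
})

test_that("rotation-only estimates grade by arc length at the annulus radius", {
  dd <- 40
  # arc = rot(rad) * 150 px; rot = 6 deg -> 15.7 px -> 0.39 DD -> grade 2
  expect_equal(amplitude_grade(est(0, rot = 6), dd), 2L)
  expect_equal(amplitude_grade(est(0, rot = 1.0), dd), 0L)  # below floor
  expect_equal(amplitude_grade(est(0, rot = 6.2), dd), 3L)  # 0.406 DD
})

test_that("amplitude grade is monotone in displacement", {
  dd <- 40
  grades <- sapply(seq(0, 0.7, by = 0.01), function(d)
    amplitude_grade(est(d * dd), dd))
  expect_true(all(diff(grades) >= 0))
})

test_that("thresholds must be ordered and positive", {
  expect_error(grade_thresholds(c(0.4, 0.15)), class = "invalid_parameter")
  expect_error(grade_thresholds(c(-0.1, 0.4)), class = "invalid_parameter")
  expect_error(amplitude_grade(est(10), -5), class = "invalid_parameter")
})

test_that("direction classification follows the angle bins and floors", {
  expect_equal(classify_direction(est(24, 0)), "horizontal")
  expect_equal(classify_direction(est(0, 24)), "vertical")
  expect_equal(classify_direction(est(15, 15)), "combined")   # 45 degrees
  expect_equal(classify_direction(est(20, 10)), "horizontal") # 26.6 deg
  expect_equal(classify_direction(est(10, 20)), "vertical")   # 63.4 deg
  expect_equal(classify_direction(est(0, 0, rot = 5, n = 2)), "rotary")
  expect_equal(classify_direction(est(24, 0, rot = 5)), "combined")
  expect_equal(classify_direction(est(1, 0, n = 1)), "undetected")
  expect_error(classify_direction(est(1, 1), angle_bins = c(60, 30)),
               class = "invalid_parameter")
})

test_that("every estimate maps to exactly one grade and one class", {
  set.seed(8)
  for (k in 1:50) {
    e <- est(runif(1, 0, 30), runif(1, 0, 30), runif(1, 0, 8))
    g <- amplitude_grade(e, 40)
    cl <- classify_direction(e)
    expect_true(g %in% 0:3)
    expect_true(cl %in% c("horizontal", "vertical", "rotary", "combined",
                          "undetected"))
    expect_identical(g == 0L, cl == "undetected")
  }
})

test_that("photo_grade enforces the grade-0/undetected equivalence", {
  expect_error(photo_grade("e1", 0, "horizontal"), class = "invalid_parameter")
  expect_error(photo_grade("e1", 2, "undetected"), class = "invalid_parameter")
  g <- photo_grade("e1", 2, "horizontal", normalized_displacement = 0.3)
  expect_s3_class(g, "photo_grade")
})

test_that("both arms agree on saturated and sub-floor images", {
  img_big <- ghost_fixture(d = c(70, 0), n = 2, seed = 9, size = c(512, 512))
  qt <- grade_photo(quantify_ghosts(img_big))
  ql <- qualitative_emulation(img_big)
  expect_equal(qt$amplitude_grade, 3L)
  expect_equal(ql$amplitude_grade, 3L)
  expect_equal(ql$arm, "qualitative")

  img_none <- ghost_fixture(n = 1, seed = 9, size = c(512, 512))
  expect_equal(grade_photo(quantify_ghosts(img_none))$amplitude_grade, 0L)
  expect_equal(qualitative_emulation(img_none)$amplitude_grade, 0L)
})

test_that("near-threshold images can split the arms by one grade", {
  # quantitative cut at 0.15 DD, qualitative at 0.12 DD: a displacement
  # between them grades 1 vs 2 by construction
  e <- est(0.14 * 40)
  q1 <- amplitude_grade(e, 40)
  q2 <- amplitude_grade(e, 40, grade_thresholds(c(0.15, 0.40) * c(0.8, 1.2)))
  expect_equal(q1, 1L)
  expect_equal(q2, 2L)
})
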