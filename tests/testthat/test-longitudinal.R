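series <- function(grades, dates = NULL) {
  if (is.null(dates))
    dates <- as.Date("2022-01-01") + 180 * (seq_along(grades) - 1)
  longitudinal_series("eyeA", data.frame(session_date = dates,
                                         amplitude_grade = grades))
}

test_that("resolution after surgery is flagged with its grade delta", {
  cmp <- compare_sessions(series(c(2, 0)))
  expect_true(cmp$resolved)
  expect_false(cmp$intermittent)
  expect_equal(cmp$intervals$grade_delta, -2)
  expect_true(cmp$intervals$detection_changed)
})

test_that("a stable series reports no change", {
  cmp <- compare_sessions(series(c(2, 2)))
  expect_false(cmp$resolved)
  expect_false(cmp$intermittent)
  expect_equal(cmp$intervals$grade_delta, 0)
  expect_false(cmp$intervals$detection_changed)
})

test_that("paroxysmal detection toggling is flagged as intermittent", {
  cmp <- compare_sessions(series(c(0, 2, 0)))
  expect_true(cmp$intermittent)
  expect_true(cmp$resolved)   # last session 0 after an earlier ghost
  cmp2 <- compare_sessions(series(c(2, 0, 3, 2)))
  expect_true(cmp2$intermittent)
  expect_false(cmp2$resolved)
})

test_that("series preconditions are enforced", {
  expect_error(compare_sessions(series(2)), class = "insufficient_series")
  expect_error(series(c(1, 2), dates = as.Date(c("2022-06-01", "2022-06-01"))),
               class = "invalid_parameter")
  expect_error(series(c(5, 1)), class = "invalid_parameter")
  # sessions are sorted by date on construction
  s <- series(c(1, 3), dates = as.Date(c("2023-01-01", "2022-01-01")))
  expect_equal(s$sessions$amplitude_grade, c(3, 1))
})

test_that("direction changes are reported when recorded", {
  s <- longitudinal_series("eyeB", data.frame(
    session_date = as.Date(c("2022-01-01", "2023-01-01")),
    amplitude_grade = c(2, 2),
    direction_class = c("horizontal", "combined")))
  cmp <- compare_sessions(s)
  expect_true(cmp$intervals$direction_changed)
})
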