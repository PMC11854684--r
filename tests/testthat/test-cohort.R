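test_that("with clinician noise disabled, clinical amplitude equals truth", {
  co <- generate_cohort(50, seed = 3, p_over = 0, p_missrot = 0,
                        render = FALSE)
  expect_identical(co$clinical$clinical_amplitude, co$true_grades)
  expect_true(all(co$clinical$clinical_amplitude %in% 1:3))
})

test_that("amplitude over-grading follows its binomial rate", {
  co <- generate_cohort(1000, seed = 5, p_over = 0.2, p_missrot = 0,
                        render = FALSE)
  # eyes already at grade 3 cannot show the +1; restrict to grades 1-2
  idx <- co$true_grades < 3
  frac <- mean(co$clinical$clinical_amplitude[idx] > co$true_grades[idx])
  expect_gte(frac, 0.16)
  expect_lte(frac, 0.24)
})

test_that("default direction mix reproduces the clinical marginals", {
  co <- generate_cohort(1000, seed = 7, p_missrot = 0, render = FALSE)
  p <- c(horizontal = 23, vertical = 5, rotary = 10, combined = 15) / 53
  counts <- table(factor(co$truth_table$direction_class, levels = names(p)))
  # multinomial 95% bounds, normal approximation per class
  for (cl in names(p)) {
    se <- sqrt(p[cl] * (1 - p[cl]) * 1000)
    expect_lt(abs(counts[cl] - 1000 * p[cl]), 1.96 * se + 1)
  }
})

test_that("rotary miss-recording converts direction to a linear class", {
  co <- generate_cohort(600, seed = 11, p_missrot = 1, render = FALSE)
  rot_true <- co$truth_table$direction_class == "rotary"
  expect_true(all(co$clinical$clinical_direction[rot_true] == "horizontal"))
  co0 <- generate_cohort(600, seed = 11, p_missrot = 0, render = FALSE)
  expect_true(all(co0$clinical$clinical_direction[rot_true] == "rotary"))
})

test_that("cohort generation is a pure function of seed and parameters", {
  a <- generate_cohort(3, seed = 13, size_px = c(320, 320))
  b <- generate_cohort(3, seed = 13, size_px = c(320, 320))
  expect_identical(a$truth_table, b$truth_table)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$images[[2]]$pixels, b$images[[2]]$pixels)
  # and the record stream does not depend on whether images were rendered
  c0 <- generate_cohort(3, seed = 13, size_px = c(320, 320), render = FALSE)
  expect_identical(a$truth_table, c0$truth_table)
  expect_identical(a$clinical, c0$clinical)
})

test_that("latent-style eyes render as single images but keep a clinical record", {
  co <- generate_cohort(40, seed = 17, p_noghost = 1, render = FALSE)
  expect_true(all(co$truth_table$n_images == 1))
  expect_true(all(co$truth_table$direction_class == "none"))
  expect_true(all(co$clinical$clinical_amplitude >= 1))
})

test_that("invalid mixes and probabilities are rejected", {
  expect_error(class_mix(direction = c(horizontal = 1)),
               class = "invalid_parameter")
  expect_error(class_mix(direction = c(horizontal = 0.6, vertical = 0.6,
                                       rotary = 0, combined = 0)),
               class = "invalid_parameter")
  expect_error(generate_cohort(0, seed = 1), class = "invalid_parameter")
  expect_error(generate_cohort(5, seed = 1, p_over = 1.5),
               class = "invalid_parameter")
})

test_that("write_cohort produces the documented sidecar files", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(2, seed = 19, size_px = c(320, 320))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "eye001.png")))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_identical(names(truth),
                   c("eye_id", "direction_class", "dx_px", "dy_px",
                     "rotation_deg", "n_images", "noise_sigma", "seed"))
  clin <- read.csv(file.path(dir, "clinical.csv"))
  expect_identical(names(clin),
                   c("eye_id", "clinical_direction", "clinical_amplitude"))
  # PNG round-trip preserves the 8-bit image
  back <- read_fundus(file.path(dir, "eye001.png"))
  expect_lt(max(abs(back$pixels - co$images[[1]]$pixels)), 1 / 255)
})
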