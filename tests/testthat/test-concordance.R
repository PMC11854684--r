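make_assessments <- function(n, clin_dir, clin_amp, q_dir, q_amp,
                             l_dir = q_dir, l_amp = q_amp) {
  grades <- rbind(
    data.frame(eye_id = sprintf("e%02d", 1:n), arm = "quantitative",
               amplitude_grade = q_amp, direction_class = q_dir),
    data.frame(eye_id = sprintf("e%02d", 1:n), arm = "qualitative",
               amplitude_grade = l_amp, direction_class = l_dir))
  clinical <- data.frame(eye_id = sprintf("e%02d", 1:n),
                         clinical_direction = clin_dir,
                         clinical_amplitude = clin_amp)
  eye_assessments(grades, clinical)
}

test_that("detection rate is the percentage of graded-positive eyes", {
  counts <- reference_cohort_counts()
  qual <- grades_from_counts(unlist(counts$amplitude[3, 2:5]))
  expect_equal(length(qual), 53)
  expect_equal(detection_rate(qual), 100 * 34 / 53)         # 64.15...
  expect_equal(round(detection_rate(qual), 1), 64.2)
  expect_equal(detection_rate(rep(0, 10)), 0)
  expect_error(detection_rate(integer(0)), class = "invalid_input")
  # permutation invariance
  expect_equal(detection_rate(sample(qual)), detection_rate(qual))
})

test_that("percent agreement counts exact matches over the denominator", {
  # 34 detected eyes, 26 matching the clinical direction, 19 undetected
  n <- 53
  clin <- rep("horizontal", n)
  qdir <- c(rep("horizontal", 26), rep("vertical", 8), rep("undetected", 19))
  qamp <- c(rep(2, 34), rep(0, 19))
  a <- make_assessments(n, clin, rep(2, n), qdir, qamp)
  expect_equal(percent_agreement(a, "direction", "quantitative",
                                 "detected_only"), 100 * 26 / 34)
  expect_equal(round(percent_agreement(a, "direction", "quantitative",
                                       "detected_only"), 2), 76.47)
  expect_equal(percent_agreement(a, "direction", "quantitative", "all"),
               100 * 26 / 53)
})

test_that("agreement is 100 for identical labels and 0 for disjoint ones", {
  a <- make_assessments(10, rep("vertical", 10), rep(2, 10),
                        rep("vertical", 10), rep(2, 10))
  expect_equal(percent_agreement(a, "direction", "quantitative"), 100)
  expect_equal(percent_agreement(a, "amplitude", "qualitative"), 100)
  b <- make_assessments(10, rep("vertical", 10), rep(2, 10),
                        rep("rotary", 10), rep(3, 10))
  expect_equal(percent_agreement(b, "direction", "quantitative"), 0)
  expect_equal(percent_agreement(b, "amplitude", "quantitative"), 0)
})

test_that("empty denominators are an error, not a silent zero", {
  a <- make_assessments(4, rep("horizontal", 4), rep(1, 4),
                        rep("undetected", 4), rep(0, 4))
  expect_error(percent_agreement(a, "direction", "quantitative",
                                 "detected_only"),
               class = "undefined_denominator")
  expect_error(cross_arm_agreement(a, "direction"),
               class = "undefined_denominator")
})

test_that("cross-arm agreement spans eyes detected by at least one arm", {
  a <- make_assessments(6, rep("horizontal", 6), rep(2, 6),
                        q_dir = rep("horizontal", 6), q_amp = rep(2, 6),
                        l_dir = c(rep("horizontal", 3), rep("undetected", 3)),
                        l_amp = c(2, 2, 2, 0, 0, 0))
  expect_equal(cross_arm_agreement(a, "direction"), 50)
  expect_equal(cross_arm_agreement(a, "amplitude"), 50)
  b <- make_assessments(6, rep("horizontal", 6), rep(2, 6),
                        rep("combined", 6), rep(3, 6))
  expect_equal(cross_arm_agreement(b, "direction"), 100)
})

test_that("joins fail loudly on unmatched eye ids", {
  grades <- rbind(
    data.frame(eye_id = "a", arm = "quantitative", amplitude_grade = 2,
               direction_class = "horizontal"),
    data.frame(eye_id = "a", arm = "qualitative", amplitude_grade = 2,
               direction_class = "horizontal"))
  clinical <- data.frame(eye_id = c("a", "b"),
                         clinical_direction = "horizontal",
                         clinical_amplitude = 2)
  expect_error(eye_assessments(grades, clinical), "\\bb\\b",
               class = "join_error")
})

test_that("cohort summaries use half-up percentages to one decimal", {
  pt <- data.frame(
    patient_id = sprintf("p%02d", 1:29),
    etiology = rep(c("congenital", "latent_manifest", "neurological",
                     "unknown"), c(15, 3, 2, 9)),
    sex = rep(c("male", "female"), c(13, 16)))
  a <- make_assessments(4, rep("horizontal", 4), rep(2, 4),
                        rep("horizontal", 4), rep(2, 4))
  s <- summarize_cohort(a, pt)
  et <- s$etiology
  expect_equal(et$pct[et$category == "congenital"], 51.7)   # 15/29
  expect_equal(et$pct[et$category == "neurological"], 6.9)  # 2/29
  sx <- s$sex
  expect_equal(sx$pct[sx$category == "female"], 55.2)       # 16/29
  # empty category reports 0.0, and each distribution sums to n
  expect_equal(sum(s$direction_quant$n), 4L)
  expect_equal(s$direction_quant$pct[s$direction_quant$category == "rotary"],
               0)
  expect_equal(sum(s$amplitude_clinical$n), 4L)
})

test_that("a concordance report carries every agreement statistic", {
  a <- make_assessments(8, rep(c("horizontal", "vertical"), 4),
                        rep(2, 8), rep("horizontal", 8),
                        c(rep(2, 6), 0, 0))
  rep <- concordance(a)
  expect_s3_class(rep, "concordance_report")
  expect_equal(rep$n_eyes, 8)
  expect_equal(rep$detection_rate_quant, 75)
  pcts <- unlist(rep[c("detection_rate_quant", "detection_rate_qual",
                       "dir_match_quant", "dir_match_qual",
                       "amp_match_quant", "amp_match_qual",
                       "cross_arm_dir", "cross_arm_amp")])
  expect_true(all(pcts >= 0 & pcts <= 100, na.rm = TRUE))
  expect_true(rep$mw_p > 0 && rep$mw_p <= 1)
})

test_that("half-up rounding follows the clinical-table convention", {
  expect_equal(ghostgrade:::round_half_up(0.05, 1), 0.1)
  expect_equal(ghostgrade:::round_half_up(51.75, 1), 51.8)
  expect_equal(ghostgrade:::round_half_up(-0.05, 1), -0.1)
  expect_equal(ghostgrade:::round_half_up(66.0377, 2), 66.04)
})
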