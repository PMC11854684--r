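#' Published reference cohort counts
#'
#' Summary counts from the published 53-eye (29-patient) pediatric
#' nystagmus cohort whose photographic grading protocol this package
#' implements. Per-eye data and images were not deposited, so only these
#' table-level counts are available; they drive the detection-rate and
#' composition arithmetic and serve as the default class mix of the
#' synthetic cohort generator.
#'
#' Direction counts are per assessment (clinical examination, quantitative
#' photo analysis, qualitative photo appearance) over the classes
#' horizontal / vertical / rotary / combined / undetected; amplitude
#' counts over grades 0-3. The quantitative arm's direction and amplitude
#' blocks disagree on the undetected count (18 vs 19, with the study text
#' reporting 35 detected eyes); both are returned as published.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{n_eyes, n_patients}{cohort sizes.}
#'     \item{direction}{data frame of direction counts per assessment.}
#'     \item{amplitude}{data frame of amplitude-grade counts per
#'       assessment.}
#'     \item{etiology}{per-patient etiology counts.}
#'     \item{sex}{per-patient sex counts.}
#'     \item{latent}{latent-nystagmus eyes: `n_eyes` examined and
#'       `n_no_ghost` showing no ghost image.}
#'   }
#' @examples
#' counts <- reference_cohort_counts()
#' # quantitative photographic detection rate
#' with(counts$direction[counts$direction$assessment == "quantitative", ],
#'      100 * (sum(horizontal, vertical, rotary, combined)) /
#'        (sum(horizontal, vertical, rotary, combined) + undetected))
#' @export
reference_cohort_counts <- function() {
  direction <- data.frame(
    assessment = c("clinical", "quantitative", "qualitative"),
    horizontal = c(23L, 17L, 16L),
    vertical = c(5L, 3L, 9L),
    rotary = c(10L, 4L, 1L),
    combined = c(15L, 11L, 8L),
    undetected = c(0L, 18L, 19L),
    stringsAsFactors = FALSE)
  amplitude <- data.frame(
    assessment = c("clinical", "quantitative", "qualitative"),
    grade0 = c(0L, 19L, 19L),
    grade1 = c(4L, 5L, 4L),
    grade2 = c(24L, 12L, 7L),
    grade3 = c(25L, 17L, 23L),
    stringsAsFactors = FALSE)
  etiology <- data.frame(
    category = c("congenital", "latent_manifest", "neurological", "unknown"),
    n = c(15L, 3L, 2L, 9L), stringsAsFactors = FALSE)
  sex <- data.frame(category = c("male", "female"), n = c(13L, 16L),
                    stringsAsFactors = FALSE)
  list(n_eyes = 53L, n_patients = 29L, direction = direction,
       amplitude = amplitude, etiology = etiology, sex = sex,
       latent = list(n_eyes = 6L, n_no_ghost = 4L))
}

#' Expand per-assessment counts into a grade vector
#'
#' Turns a row of amplitude-grade counts into the corresponding vector of
#' per-eye grades, so count data can be fed to [detection_rate()] and
#' [mann_whitney()].
#'
#' @param counts named counts, e.g. `c(grade0 = 19, grade1 = 5, ...)` or
#'   an unnamed vector ordered grade 0 to 3.
#' @return Integer vector of grades.
#' @export
grades_from_counts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || any(counts < 0))
    stop_ghostgrade("`counts` must be 4 nonnegative counts (grades 0-3)",
                    "invalid_parameter")
  rep(0:3, counts)
}
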