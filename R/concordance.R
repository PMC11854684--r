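# Concordance between photographic arms and clinical examination:
# detection rates, percent agreement, cross-arm consistency and the
# rank-based amplitude comparison.

#' Photographic detection rate
#'
#' Percentage of eyes with a detectable ghost (amplitude grade above 0).
#'
#' @param grades a vector of amplitude grades, a list of [photo_grade()]
#'   objects, or a data frame with an `amplitude_grade` column.
#' @return Percentage in `[0, 100]` (full precision; round at print time).
#' @export
detection_rate <- function(grades) {
  g <- extract_grades(grades)
  if (length(g) == 0)
    stop_ghostgrade("`grades` must be nonempty", "invalid_input")
  100 * mean(g > 0)
}

extract_grades <- function(grades) {
  if (is.data.frame(grades)) return(grades$amplitude_grade)
  if (is.list(grades) && !is.null(grades[[1]]$amplitude_grade))
    return(vapply(grades, function(x) x$amplitude_grade, 0L))
  as.numeric(grades)
}

#' Assemble per-eye assessments
#'
#' Joins the photographic grades of both arms with the clinical record on
#' `eye_id`; eyes missing from either side are an error listing the
#' offenders (silent drops would corrupt the agreement statistics).
#'
#' @param grades data frame with columns `eye_id`, `arm`,
#'   `amplitude_grade`, `direction_class` (long format, one row per
#'   eye-arm), as produced by [grade_photo()] rows.
#' @param clinical data frame with `eye_id`, `clinical_direction`,
#'   `clinical_amplitude`.
#' @return Data frame of class `eye_assessments`, one row per eye:
#'   `eye_id`, `clinical_direction`, `clinical_amplitude`, `quant_grade`,
#'   `quant_direction`, `qual_grade`, `qual_direction`.
#' @export
eye_assessments <- function(grades, clinical) {
  check_columns(grades, c("eye_id", "arm", "amplitude_grade",
                          "direction_class"), "grades")
  check_columns(clinical, c("eye_id", "clinical_direction",
                            "clinical_amplitude"), "clinical")
  validate_clinical(clinical)
  wide <- NULL
  for (a in c("quantitative", "qualitative")) {
    sub <- grades[grades$arm == a,
                  c("eye_id", "amplitude_grade", "direction_class")]
    names(sub)[2:3] <- paste0(arm_prefix(a), c("_grade", "_direction"))
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "eye_id")
  }
  missing_g <- setdiff(clinical$eye_id, wide$eye_id)
  missing_c <- setdiff(wide$eye_id, clinical$eye_id)
  if (length(missing_g) || length(missing_c))
    stop_ghostgrade(paste0(
      "unmatched eye_ids: ",
      paste(c(missing_g, missing_c), collapse = ", ")), "join_error")
  out <- merge(clinical, wide, by = "eye_id")
  out <- out[order(out$eye_id), ]
  rownames(out) <- NULL
  class(out) <- c("eye_assessments", "data.frame")
  out
}

arm_prefix <- function(arm) c(quantitative = "quant", qualitative = "qual")[[arm]]

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df) || nrow(df) == 0)
    stop_ghostgrade(sprintf("`%s` must be a nonempty data frame", name),
                    "invalid_input")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ghostgrade(sprintf("`%s` is missing columns: %s", name,
                            paste(miss, collapse = ", ")), "schema_error")
  invisible(df)
}

validate_clinical <- function(clinical) {
  ok_dir <- c("horizontal", "vertical", "rotary", "combined")
  bad <- setdiff(unique(clinical$clinical_direction), ok_dir)
  if (length(bad))
    stop_ghostgrade(sprintf("unknown clinical_direction label(s): %s",
                            paste(bad, collapse = ", ")), "schema_error")
  if (!all(clinical$clinical_amplitude %in% 1:3))
    stop_ghostgrade("clinical_amplitude must be 1, 2 or 3 (never 0)",
                    "schema_error")
  invisible(clinical)
}

#' Percent agreement between a photographic arm and the clinic
#'
#' Exact-match percentage of the chosen photographic field against the
#' clinical field. The study computes matches among eyes that showed
#' ghost images, so the default denominator is `detected_only` (eyes the
#' chosen arm graded above 0); `all` uses every eye.
#'
#' @param assessments an [eye_assessments()] data frame.
#' @param field `"direction"` or `"amplitude"`.
#' @param arm `"quantitative"` or `"qualitative"`.
#' @param denominator `"detected_only"` or `"all"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_agreement <- function(assessments,
                              field = c("direction", "amplitude"),
                              arm = c("quantitative", "qualitative"),
                              denominator = c("detected_only", "all")) {
  field <- match.arg(field); arm <- match.arg(arm)
  denominator <- match.arg(denominator)
  if (nrow(assessments) == 0)
    stop_ghostgrade("`assessments` must be nonempty", "invalid_input")
  pre <- arm_prefix(arm)
  photo <- assessments[[paste0(pre, "_", if (field == "direction")
    "direction" else "grade")]]
  clin <- assessments[[if (field == "direction") "clinical_direction"
                       else "clinical_amplitude"]]
  keep <- if (denominator == "detected_only")
    assessments[[paste0(pre, "_grade")]] > 0 else rep(TRUE, nrow(assessments))
  if (!any(keep))
    stop_ghostgrade("denominator set is empty", "undefined_denominator")
  100 * mean(photo[keep] == clin[keep])
}

#' Cross-arm consistency of the two photographic assessments
#'
#' Exact-match percentage between the qualitative and quantitative arms
#' over eyes detected by at least one arm.
#'
#' @param assessments an [eye_assessments()] data frame.
#' @param field `"direction"` or `"amplitude"`.
#' @return Percentage in `[0, 100]`.
#' @export
cross_arm_agreement <- function(assessments,
                                field = c("direction", "amplitude")) {
  field <- match.arg(field)
  if (nrow(assessments) == 0)
    stop_ghostgrade("`assessments` must be nonempty", "invalid_input")
  keep <- assessments$quant_grade > 0 | assessments$qual_grade > 0
  if (!any(keep))
    stop_ghostgrade("no eye detected by either arm", "undefined_denominator")
  a <- assessments[keep, ]
  if (field == "direction")
    100 * mean(a$quant_direction == a$qual_direction)
  else
    100 * mean(a$quant_grade == a$qual_grade)
}

#' Cohort-level concordance report
#'
#' Computes every agreement statistic the photographic-versus-clinical
#' comparison reports: per-arm detection rates, direction and amplitude
#' agreement with the clinical examination (among detected eyes),
#' cross-arm consistency, and the Mann-Whitney comparison of the two
#' arms' grade distributions.
#'
#' @param assessments an [eye_assessments()] data frame.
#' @param mw_mode Mann-Whitney mode; `"auto"` enumerates exactly for
#'   small cohorts and falls back to the normal approximation.
#' @return An object of class `concordance_report`.
#' @export
concordance <- function(assessments, mw_mode = "auto") {
  if (!nrow(assessments))
    stop_ghostgrade("`assessments` must be nonempty", "invalid_input")
  n <- nrow(assessments)
  if (mw_mode == "auto")
    mw_mode <- if (choose(2 * n, n) <= 2e5) "exact" else "normal"
  mw <- mann_whitney(assessments$quant_grade, assessments$qual_grade,
                     mode = mw_mode)
  agree <- function(f, a) tryCatch(
    percent_agreement(assessments, f, a, "detected_only"),
    ghostgrade_error = function(e) NA_real_)
  structure(list(
    n_eyes = n,
    detection_rate_quant = detection_rate(assessments$quant_grade),
    detection_rate_qual = detection_rate(assessments$qual_grade),
    dir_match_quant = agree("direction", "quantitative"),
    dir_match_qual = agree("direction", "qualitative"),
    amp_match_quant = agree("amplitude", "quantitative"),
    amp_match_qual = agree("amplitude", "qualitative"),
    cross_arm_dir = cross_arm_agreement(assessments, "direction"),
    cross_arm_amp = cross_arm_agreement(assessments, "amplitude"),
    mw_U = mw$U, mw_p = mw$p), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d eyes\n", x$n_eyes))
  cat(sprintf("  detection: quantitative %.2f%%, qualitative %.2f%%\n",
              x$detection_rate_quant, x$detection_rate_qual))
  cat(sprintf("  direction match vs clinic (detected eyes): quant %.1f%%, qual %.1f%%\n",
              round_half_up(x$dir_match_quant, 1),
              round_half_up(x$dir_match_qual, 1)))
  cat(sprintf("  amplitude match vs clinic (detected eyes): quant %.1f%%, qual %.1f%%\n",
              round_half_up(x$amp_match_quant, 1),
              round_half_up(x$amp_match_qual, 1)))
  cat(sprintf("  cross-arm: direction %.1f%%, amplitude %.1f%%\n",
              round_half_up(x$cross_arm_dir, 1),
              round_half_up(x$cross_arm_amp, 1)))
  cat(sprintf("  Mann-Whitney (quant vs qual grades): U = %g, p = %.4g\n",
              x$mw_U, x$mw_p))
  invisible(x)
}

#' Category counts with clinical-table percentages
#'
#' Tabulates a categorical vector with percentages rounded half-up to one
#' decimal, the convention of clinical summary tables.
#'
#' @param x categorical vector.
#' @param levels optional category order (categories absent from `x` get
#'   zero counts).
#' @return Data frame with `category`, `n`, `pct`.
#' @export
tabulate_percent <- function(x, levels = NULL) {
  if (is.null(levels)) levels <- unique(x)
  n <- vapply(levels, function(l) sum(x == l), 0L)
  data.frame(category = as.character(levels), n = as.integer(n),
             pct = round_half_up(100 * n / length(x), 1),
             stringsAsFactors = FALSE)
}

#' Summarize a cohort the way clinical tables do
#'
#' Produces per-category counts and percentages (half-up, one decimal)
#' for the direction and amplitude distributions of the clinical and both
#' photographic assessments, plus any categorical columns of an optional
#' patient table.
#'
#' @param assessments an [eye_assessments()] data frame.
#' @param patient_table optional data frame of per-patient categorical
#'   variables (all columns except any `patient_id` are tabulated).
#' @return A list of class `cohort_summary` of [tabulate_percent()]
#'   tables; direction tables share the level order
#'   horizontal/vertical/rotary/combined/undetected and amplitude tables
#'   0-3.
#' @export
summarize_cohort <- function(assessments, patient_table = NULL) {
  if (!nrow(assessments))
    stop_ghostgrade("`assessments` must be nonempty", "invalid_input")
  dirs <- c("horizontal", "vertical", "rotary", "combined", "undetected")
  out <- list(
    direction_clinical = tabulate_percent(assessments$clinical_direction,
                                          dirs),
    direction_quant = tabulate_percent(assessments$quant_direction, dirs),
    direction_qual = tabulate_percent(assessments$qual_direction, dirs),
    amplitude_clinical = tabulate_percent(assessments$clinical_amplitude, 0:3),
    amplitude_quant = tabulate_percent(assessments$quant_grade, 0:3),
    amplitude_qual = tabulate_percent(assessments$qual_grade, 0:3))
  if (!is.null(patient_table)) {
    if (!is.data.frame(patient_table) || nrow(patient_table) == 0)
      stop_ghostgrade("`patient_table` must be a nonempty data frame",
                      "invalid_input")
    for (col in setdiff(names(patient_table), "patient_id"))
      out[[col]] <- tabulate_percent(patient_table[[col]])
  }
  structure(out, n_eyes = nrow(assessments), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d eyes\n", attr(x, "n_eyes")))
  for (nm in names(x)) {
    cat("--", nm, "\n")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}
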