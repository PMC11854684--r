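#' Class mix for synthetic cohorts
#'
#' Proportions of the four clinical direction classes and of the three
#' clinical amplitude grades from which synthetic eyes are drawn. The
#' defaults are the clinical-examination marginals of the 53-eye study
#' cohort this package emulates: directions 23/5/10/15 of 53
#' (horizontal / vertical / rotary / combined) and amplitudes 4/24/25 of
#' 53 (grades 1/2/3).
#'
#' @param direction named proportions over
#'   `horizontal`/`vertical`/`rotary`/`combined`; must sum to 1.
#' @param amplitude proportions over grades 1-3; must sum to 1.
#' @return A list of class `class_mix`.
#' @export
class_mix <- function(direction = c(horizontal = 23, vertical = 5,
                                    rotary = 10, combined = 15) / 53,
                      amplitude = c(4, 24, 25) / 53) {
  req <- c("horizontal", "vertical", "rotary", "combined")
  if (is.null(names(direction)) || !all(req %in% names(direction)))
    stop_ghostgrade(
      "`direction` must name all of horizontal, vertical, rotary, combined",
      "invalid_parameter")
  direction <- direction[req]
  if (any(direction < 0) || abs(sum(direction) - 1) > 1e-9)
    stop_ghostgrade("`direction` proportions must be nonnegative and sum to 1",
                    "invalid_parameter")
  if (length(amplitude) != 3L || any(amplitude < 0) ||
      abs(sum(amplitude) - 1) > 1e-9)
    stop_ghostgrade("`amplitude` must be 3 nonnegative proportions summing to 1",
                    "invalid_parameter")
  structure(list(direction = direction, amplitude = amplitude),
            class = "class_mix")
}

#' Generate a synthetic cohort of ghost images with clinical records
#'
#' Draws per-eye direction class and amplitude grade from `mix`, renders
#' each ghost image on its own vessel phantom, and produces a synthetic
#' clinical record that encodes the two clinician-noise effects reported
#' for photographic-versus-clinical comparison: the clinical amplitude
#' exceeds the true grade by 1 with probability `p_over` (capped at 3,
#' clinicians tend to overestimate amplitude), and a true rotary
#' component is clinically recorded as its linear projection with
#' probability `p_missrot` (rotary components are missed on clinical
#' examination in about half of discordant cases). Clinical amplitude is
#' never 0: every eye in the emulated cohort has clinically confirmed
#' nystagmus.
#'
#' True normalized displacement is drawn uniformly inside the grade's
#' cut-point bin; with probability `p_noghost` an eye is rendered as a
#' single image regardless of its clinical record, emulating latent
#' nystagmus that leaves no ghost on binocular photography. The whole
#' cohort is a pure function of `(n_eyes, seed, mix, parameters)`.
#'
#' @param n_eyes number of eyes (>= 1).
#' @param seed integer seed.
#' @param mix a [class_mix()].
#' @param p_over probability the clinical amplitude overestimates by 1.
#' @param p_missrot probability a true rotary component is clinically
#'   recorded as its linear projection.
#' @param p_noghost probability an eye shows no ghost despite clinical
#'   nystagmus (latent-nystagmus emulation).
#' @param size_px image size `(width, height)`.
#' @param noise_sigma render noise s.d.
#' @param thresholds [grade_thresholds()] defining the amplitude bins.
#' @param floors [detect_params()] supplying detectability floors.
#' @param p_triple probability a detected eye shows a triple (vs double)
#'   image.
#' @param disc_frac optic-disc diameter as a fraction of image width,
#'   passed to [generate_vessel_phantom()].
#' @param render render the images (default). With `render = FALSE` only
#'   the ground-truth and clinical record streams are produced (`images`
#'   is `NULL`); they are identical to what a rendered run yields, since
#'   image synthesis consumes a separate part of the random stream.
#' @return A list of class `ghost_cohort` with `images` (list of
#'   [fundus_image()]), `truths` (list of [trajectory_truth()]),
#'   `truth_table` (data frame), `clinical` (data frame with `eye_id`,
#'   `clinical_direction`, `clinical_amplitude`), and `true_grades`.
#' @export
generate_cohort <- function(n_eyes, seed = 1, mix = class_mix(),
                            p_over = 0.2, p_missrot = 0.5, p_noghost = 0,
                            size_px = c(512, 512), noise_sigma = 0.02,
                            thresholds = grade_thresholds(),
                            floors = detect_params(), p_triple = 0.4,
                            disc_frac = 0.08, render = TRUE) {
  if (!is.numeric(n_eyes) || n_eyes < 1)
    stop_ghostgrade("`n_eyes` must be >= 1", "invalid_parameter")
  if (!inherits(mix, "class_mix")) mix <- do.call(class_mix, mix)
  for (p in c(p_over, p_missrot, p_noghost, p_triple))
    if (p < 0 || p > 1)
      stop_ghostgrade("probabilities must be in [0, 1]", "invalid_parameter")
  n_eyes <- as.integer(n_eyes)
  set.seed(as.integer(seed))
  dirs <- sample(names(mix$direction), n_eyes, replace = TRUE,
                 prob = mix$direction)
  grades <- sample(1:3, n_eyes, replace = TRUE, prob = mix$amplitude)
  cuts <- thresholds$cuts
  bins <- rbind(c(0.05, cuts[1]), c(cuts[1], cuts[2]), c(cuts[2], 0.60))
  d_norm <- stats::runif(n_eyes, bins[grades, 1], bins[grades, 2])
  angle_sign <- sample(c(-1, 1), n_eyes, replace = TRUE)
  jitter <- stats::runif(n_eyes, 0, 15)
  comb_angle <- stats::runif(n_eyes, 35, 55)
  comb_rotary <- stats::runif(n_eyes) < 0.5       # combined = oblique or lin+rot
  comb_base_v <- stats::runif(n_eyes) < 0.5
  comb_rot_deg <- stats::runif(n_eyes, 2, 6)
  noghost <- stats::runif(n_eyes) < p_noghost
  triple <- stats::runif(n_eyes) < p_triple
  over <- stats::runif(n_eyes) < p_over
  missrot <- stats::runif(n_eyes) < p_missrot
  phantom_seeds <- sample.int(.Machine$integer.max - 1L, n_eyes)

  r_mid <- mean(floors$annulus) * min(size_px)
  dd <- disc_frac * size_px[1]
  images <- if (render) vector("list", n_eyes)
  truths <- vector("list", n_eyes)
  clin_dir <- character(n_eyes)
  eye_ids <- sprintf("eye%03d", seq_len(n_eyes))

  for (i in seq_len(n_eyes)) {
    disp <- c(0, 0); rot <- 0
    cd <- dirs[i]
    if (cd == "horizontal") {
      a <- deg2rad(angle_sign[i] * jitter[i])
      disp <- d_norm[i] * dd * c(cos(a), sin(a))
    } else if (cd == "vertical") {
      a <- deg2rad(90 - angle_sign[i] * jitter[i])
      disp <- d_norm[i] * dd * c(cos(a), sin(a))
    } else if (cd == "rotary") {
      rot <- d_norm[i] * dd / r_mid * 180 / pi
    } else {                                     # combined
      if (comb_rotary[i]) {
        base <- if (comb_base_v[i]) 90 - angle_sign[i] * jitter[i]
                else angle_sign[i] * jitter[i]
        a <- deg2rad(base)
        disp <- d_norm[i] * dd * c(cos(a), sin(a))
        rot <- comb_rot_deg[i]
      } else {
        a <- deg2rad(angle_sign[i] * comb_angle[i])
        disp <- d_norm[i] * dd * c(cos(a), abs(sin(a)) * angle_sign[i])
      }
    }
    if (disp[1] < 0) disp <- -disp
    if (noghost[i]) {
      tr <- trajectory_truth("none", c(0, 0), 0, n_images = 1,
                             noise_sigma = noise_sigma, floors = floors)
    } else {
      n_img <- if (triple[i]) 3L else 2L
      tr <- trajectory_truth(cd, disp, rot, n_images = n_img,
                             noise_sigma = noise_sigma, floors = floors)
    }
    truths[[i]] <- tr
    if (render) {
      ph <- generate_vessel_phantom(size_px, seed = phantom_seeds[i],
                                    disc_frac = disc_frac)
      images[[i]] <- render_ghost_image(ph, tr, eye_id = eye_ids[i])
    }
    # clinical direction: rotary components are sometimes missed at the slit
    # lamp and read as the linear movement alone
    clin_dir[i] <- cd
    if (missrot[i]) {
      if (cd == "rotary") clin_dir[i] <- "horizontal"
      else if (cd == "combined" && comb_rotary[i])
        clin_dir[i] <- if (comb_base_v[i]) "vertical" else "horizontal"
    }
  }
  clin_amp <- pmin(3L, pmax(1L, grades) + as.integer(over))
  truth_table <- data.frame(
    eye_id = eye_ids,
    direction_class = vapply(truths, function(t) t$direction_class, ""),
    dx_px = vapply(truths, function(t) t$displacement_px[1], 0),
    dy_px = vapply(truths, function(t) t$displacement_px[2], 0),
    rotation_deg = vapply(truths, function(t) t$rotation_deg, 0),
    n_images = vapply(truths, function(t) t$n_images, 0L),
    noise_sigma = noise_sigma, seed = as.integer(seed),
    stringsAsFactors = FALSE)
  clinical <- data.frame(eye_id = eye_ids, clinical_direction = clin_dir,
                         clinical_amplitude = clin_amp,
                         stringsAsFactors = FALSE)
  structure(list(images = images, truths = truths,
                 truth_table = truth_table, clinical = clinical,
                 true_grades = grades, seed = as.integer(seed)),
            class = "ghost_cohort")
}

#' @export
print.ghost_cohort <- function(x, ...) {
  cat(sprintf("<ghost_cohort> %d eyes, seed %d\n", nrow(x$truth_table),
              x$seed))
  print(table(direction = x$truth_table$direction_class))
  print(table(true_grade = x$true_grades))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes each image as an 8-bit grayscale PNG plus the ground-truth and
#' clinical-record CSV sidecars.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (img in cohort$images)
    write_fundus_png(img, file.path(dir, paste0(img$eye_id, ".png")))
  write_csv_atomic(cohort$truth_table, file.path(dir, "truth.csv"))
  write_csv_atomic(cohort$clinical, file.path(dir, "clinical.csv"))
  invisible(dir)
}

write_csv_atomic <- function(df, path) {
  write_atomic(function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE), path)
}
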