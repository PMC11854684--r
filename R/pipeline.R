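#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline (simulate, quantify,
#' grade, concord) so a run is a pure function of its config. Configs
#' round-trip losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed integer master seed.
#' @param n_eyes cohort size for the simulation stage.
#' @param size_px image size `(width, height)`.
#' @param noise_sigma render noise s.d.
#' @param p_over,p_missrot,p_noghost clinician/latent noise probabilities
#'   (see [generate_cohort()]).
#' @param theta_peak,s_min,floor_px,floor_deg detection parameters (see
#'   [detect_params()]).
#' @param cuts amplitude cut-points (see [grade_thresholds()]).
#' @param angle_bins direction sector bounds, degrees.
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_eyes = 50, size_px = c(512, 512),
                       noise_sigma = 0.02, p_over = 0.2, p_missrot = 0.5,
                       p_noghost = 0, theta_peak = 0.2, s_min = 4,
                       floor_px = 3, floor_deg = 1.5, cuts = c(0.15, 0.40),
                       angle_bins = c(30, 60), out_dir = "ghostgrade_run") {
  cfg <- list(seed = as.integer(seed), n_eyes = as.integer(n_eyes),
              size_px = as.integer(size_px), noise_sigma = noise_sigma,
              p_over = p_over, p_missrot = p_missrot, p_noghost = p_noghost,
              theta_peak = theta_peak, s_min = s_min, floor_px = floor_px,
              floor_deg = floor_deg, cuts = as.numeric(cuts),
              angle_bins = as.numeric(angle_bins),
              out_dir = as.character(out_dir))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$n_eyes < 1)
    stop_ghostgrade("`n_eyes` must be >= 1", "invalid_parameter")
  detect_params(theta_peak = cfg$theta_peak, s_min = cfg$s_min,
                floor_px = cfg$floor_px, floor_deg = cfg$floor_deg)
  grade_thresholds(cfg$cuts)
  if (length(cfg$size_px) != 2L || any(cfg$size_px < 256))
    stop_ghostgrade("`size_px` must be a pair >= 256", "invalid_parameter")
  invisible(cfg)
}

config_params <- function(cfg)
  detect_params(theta_peak = cfg$theta_peak, s_min = cfg$s_min,
                floor_px = cfg$floor_px, floor_deg = cfg$floor_deg)

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  write_atomic(function(tmp) yaml::write_yaml(unclass(cfg), tmp), path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_ghostgrade(sprintf("config file not found: '%s'", path), "io_error")
  do.call(run_config, yaml::read_yaml(path))
}

#' Read a clinical-record CSV
#'
#' Strict reader for the `eye_id, clinical_direction, clinical_amplitude`
#' schema: unknown columns and unknown direction labels are hard errors,
#' never coerced (silent coercion would corrupt the agreement
#' statistics).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df),
                   c("eye_id", "clinical_direction", "clinical_amplitude"))
  if (length(extra))
    stop_ghostgrade(sprintf("unknown column(s) in clinical CSV: %s",
                            paste(extra, collapse = ", ")), "schema_error")
  check_columns(df, c("eye_id", "clinical_direction", "clinical_amplitude"),
                "clinical")
  validate_clinical(df)
  df
}

#' Quantify every image in a directory
#'
#' Runs [quantify_ghosts()] over all PNG/TIFF/JPEG files in `dir` and
#' returns the per-image measurement table.
#'
#' @param dir directory of fundus photographs.
#' @param method estimator, as in [quantify_ghosts()].
#' @param params a [detect_params()].
#' @return Data frame, one row per image (columns as in
#'   [as.data.frame.ghost_fit()]).
#' @export
quantify_directory <- function(dir, method = "autocorr",
                               params = detect_params()) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0)
    stop_ghostgrade(sprintf("no images found in '%s'", dir), "io_error")
  do.call(rbind, lapply(sort(files), function(f)
    as.data.frame(quantify_ghosts(read_fundus(f), method = method,
                                  params = params))))
}

#' Run the full simulate-quantify-grade-concord pipeline
#'
#' Executes every stage in order under the config's seed, writing all
#' artifacts (images, truth and clinical CSVs, per-image measurements,
#' per-eye grades, the per-eye match table, and `report.json`)
#' atomically into `cfg$out_dir`. Identical configs give bit-identical
#' outputs. Any stage failure aborts with a stage-named error.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return The [concordance()] report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  validate_run_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop_ghostgrade(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      "pipeline_error"))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  thresholds <- grade_thresholds(cfg$cuts)

  say("simulate: %d eyes (seed %d)", cfg$n_eyes, cfg$seed)
  cohort <- stage("simulate", {
    co <- generate_cohort(cfg$n_eyes, seed = cfg$seed,
                          p_over = cfg$p_over, p_missrot = cfg$p_missrot,
                          p_noghost = cfg$p_noghost, size_px = cfg$size_px,
                          noise_sigma = cfg$noise_sigma,
                          thresholds = thresholds, floors = params)
    write_cohort(co, file.path(cfg$out_dir, "images"))
    co
  })

  say("quantify: %d images", length(cohort$images))
  fits <- stage("quantify", {
    fl <- lapply(cohort$images, quantify_ghosts, method = "autocorr",
                 params = params)
    write_csv_atomic(do.call(rbind, lapply(fl, as.data.frame)),
                     file.path(cfg$out_dir, "results.csv"))
    fl
  })

  say("grade: both arms")
  grades <- stage("grade", {
    g <- do.call(rbind, Map(function(fit, img) {
      rbind(as.data.frame(grade_photo(fit, thresholds = thresholds,
                                      floors = params,
                                      angle_bins = cfg$angle_bins)),
            as.data.frame(qualitative_emulation(img, params = params,
                                                thresholds = thresholds,
                                                angle_bins = cfg$angle_bins)))
    }, fits, cohort$images))
    write_csv_atomic(g, file.path(cfg$out_dir, "grades.csv"))
    g
  })

  say("concord")
  report <- stage("concord", {
    ass <- eye_assessments(grades, cohort$clinical)
    write_csv_atomic(as.data.frame(ass),
                     file.path(cfg$out_dir, "match_table.csv"))
    rep <- concordance(ass)
    write_atomic(function(tmp) jsonlite::write_json(
      unclass(rep), tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(cfg$out_dir, "report.json"))
    rep
  })

  log <- c(sprintf("ghostgrade %s", as.character(utils::packageVersion("ghostgrade"))),
           sprintf("R %s", getRversion()),
           utils::capture.output(utils::str(unclass(cfg))))
  write_atomic(function(tmp) writeLines(log, tmp),
               file.path(cfg$out_dir, "run.log"))
  invisible(report)
}
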