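#' Configuration of an end-to-end synthetic-study run
#'
#' A single object holding every knob of the pipeline: cohort size,
#' kinematic constants, permutation count, seed and output directory.  All
#' randomness flows from the one root seed through fixed per-stage
#' sub-seeds, so a rerun with the same config is byte-identical.
#'
#' @param output_dir directory for the result bundle (created if absent).
#' @param n_subjects cohort size (default 16).
#' @param n_perm permutations for correlation and regression p-values.
#' @param seed root seed.
#' @param alternative alternative for the pairwise correlations
#'   (`"greater"` by default: positive association).
#' @param kin_config a [kinematic_config()].
#' @param response response variable for the regression (default `mmse`).
#' @param predictors regression predictors (default: elevation, velocity,
#'   sex, age, grip).
#' @param correlation_vars variables entering the pairwise correlation
#'   table; default the 11 jointly tabulated pilot measures.
#' @param ladder_candidates list of predictor sets ranked by AIC.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir, n_subjects = 16, n_perm = 19999,
                       seed = 20230525, alternative = "greater",
                       kin_config = kinematic_config(),
                       response = "mmse",
                       predictors = c("avg_elevation_deg", "avg_velocity_ms",
                                      "sex", "age", "grip_kg"),
                       correlation_vars = rownames(pilot_target_rho()),
                       ladder_candidates = list(
                         c("age", "sex", "grip_kg", "avg_velocity_ms",
                           "avg_elevation_deg"),
                         c("age", "sex", "grip_kg", "avg_elevation_deg"),
                         c("age", "grip_kg", "avg_elevation_deg"),
                         c("grip_kg", "avg_elevation_deg"))) {
  stopifnot(inherits(kin_config, "kinematic_config"),
            n_subjects >= 3, n_perm >= 999)
  structure(list(output_dir = output_dir, n_subjects = n_subjects,
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 kin_config = kin_config, response = response,
                 predictors = predictors,
                 correlation_vars = correlation_vars,
                 ladder_candidates = ladder_candidates),
            class = "run_config")
}

# Map a subject's nominal (elevation, velocity) biomarkers to swing-model
# parameters.  With at least one full cycle per 1 s window the window-max
# elevation is phi0 + A, and the mean absolute angular speed of a sinusoid
# gives v = 4 A f r, so f = v / (4 A r) once A is chosen.
motion_params_for_subject <- function(elev_deg, vel_ms, seed,
                                      radius_m = 0.223, duration_s = 60,
                                      rate_hz = 20, f_base = 1.5,
                                      amp_cap_deg = 25) {
  vel_ms <- max(vel_ms, 1e-4)
  A_rad <- vel_ms / (4 * f_base * radius_m)
  f <- f_base
  cap <- amp_cap_deg * pi / 180
  if (A_rad > cap) {
    A_rad <- cap
    f <- vel_ms / (4 * A_rad * radius_m)
  }
  A_deg <- A_rad * 180 / pi
  phi0 <- elev_deg - A_deg
  phi0 <- max(min(phi0, 90 - A_deg - 1e-6), -90 + A_deg + 1e-6)
  motion_params(elevation_offset_deg = phi0, swing_amplitude_deg = A_deg,
                swing_freq_hz = f, duration_s = duration_s,
                rate_hz = rate_hz, seed = seed)
}

write_csv_stable <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a cohort with the published correlation structure, generates
#' one wrist-IMU drumming stream per subject whose ground-truth biomarkers
#' equal the cohort's nominal values, recomputes the biomarkers from the
#' streams through the kinematic pipeline, and feeds the measured values
#' into the descriptive report, the pairwise permutation-Spearman table,
#' the permutation regression predicting MMSE, and the AIC model ladder.
#' Writes `cohort.csv`, `kinematics.csv`, `table1_report.csv`,
#' `correlations.csv`, `regression.csv`, `ladder.csv` and `manifest.json`
#' into the output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate-cohort", {
    simulate_cohort(cohort_params(n = config$n_subjects,
                                  seed = config$seed + 1))
  })

  kin <- stage("kinematics", {
    rows <- lapply(seq_len(config$n_subjects), function(i) {
      mp <- motion_params_for_subject(cohort$avg_elevation_deg[i],
                                      cohort$avg_velocity_ms[i],
                                      seed = config$seed + 100 + i,
                                      radius_m = config$kin_config$radius_m)
      sim <- simulate_drumming_motion(
        mp, radius_m = config$kin_config$radius_m,
        gravity_ms2 = config$kin_config$gravity_ms2,
        rest_threshold_ms2 = config$kin_config$rest_threshold_ms2)
      s <- sim$stream
      s$subject_id <- cohort$id[i]
      summarize_kinematics(s, config$kin_config)
    })
    do.call(rbind, rows)
  })
  cohort$avg_velocity_ms <- kin$avg_velocity_ms
  cohort$avg_elevation_deg <- kin$avg_elevation_deg

  table1 <- stage("cohort-report", summarize_cohort(cohort))
  correlations <- stage("correlations", {
    correlation_matrix(cohort, config$correlation_vars,
                       n_perm = config$n_perm, seed = config$seed + 3,
                       alternative = config$alternative)
  })
  regression <- stage("regression", {
    fit_perm_regression(cohort[[config$response]],
                        cohort[, config$predictors, drop = FALSE],
                        n_perm = config$n_perm, seed = config$seed + 4)
  })
  ladder <- stage("aic-ladder", {
    dat <- cohort
    dat$sex <- as.numeric(dat$sex == "woman")
    aic_ladder(dat, config$response, config$ladder_candidates)
  })

  manifest <- list(
    package = "drumkin",
    version = as.character(utils::packageVersion("drumkin")),
    seed = config$seed,
    stage_seeds = list(cohort = config$seed + 1,
                       motion = paste0(config$seed + 101, "..",
                                       config$seed + 100 + config$n_subjects),
                       correlations = config$seed + 3,
                       regression = config$seed + 4),
    n_subjects = config$n_subjects,
    n_perm = config$n_perm,
    alternative = config$alternative,
    kinematic_config = unclass(config$kin_config),
    response = config$response,
    predictors = config$predictors,
    correlation_vars = config$correlation_vars)

  out <- config$output_dir
  write_csv_stable(cohort, file.path(out, "cohort.csv"))
  write_csv_stable(kin, file.path(out, "kinematics.csv"))
  write_csv_stable(table1, file.path(out, "table1_report.csv"))
  write_csv_stable(correlations, file.path(out, "correlations.csv"))
  reg_tab <- data.frame(term = regression$terms,
                        beta_std = regression$beta_std,
                        t = regression$t_stats,
                        p_perm = regression$p_perm,
                        vif = regression$vif[regression$terms],
                        r2 = regression$r2, adj_r2 = regression$adj_r2,
                        aic = regression$aic,
                        p_perm_model = regression$p_perm_model,
                        stringsAsFactors = FALSE)
  write_csv_stable(reg_tab, file.path(out, "regression.csv"))
  write_csv_stable(as.data.frame(ladder), file.path(out, "ladder.csv"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, kinematics = kin, table1 = table1,
                 correlations = correlations, regression = regression,
                 ladder = ladder, manifest = manifest, output_dir = out))
}
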