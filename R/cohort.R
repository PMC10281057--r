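#' Published summary statistics of the pilot drumming cohort
#'
#' The per-variable summary table of the 16-resident nursing-home pilot
#' cohort (12 women, 4 men) that motivates this package: overall and
#' per-sex means and SDs, observed ranges, and the printed sex-difference
#' p-values.  These printed summaries are the reference inputs for
#' [pooled_t_from_summary()] validation and supply the default marginals of
#' [cohort_params()].  The `sd_decimals` column records the coarsest
#' printed precision among each row's inputs (two rows have an SD printed
#' to a single decimal, which limits how precisely their p-value can be
#' recomputed from the rounded summaries).
#'
#' @return data.frame with one row per cohort variable.
#' @export
pilot_cohort_summary <- function() {
  path <- system.file("extdata", "pilot_cohort_summary.csv",
                      package = "drumkin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's pooled-variance two-sample t-test computed from printed group
#' summary statistics (means, SDs, group sizes) rather than raw data, with
#' \eqn{df = n_a + n_b - 2} and a two-sided p-value.  This is the form that
#' reproduces the published sex-difference column of the pilot cohort
#' table; Welch's unequal-variance form does not.
#'
#' @param mean_a,sd_a,n_a summary statistics of group A.
#' @param mean_b,sd_b,n_b summary statistics of group B.
#' @return a `group_comparison` list with fields `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `t_stat`, `df`, `p_two_sided`.
#' @examples
#' # handgrip strength, women vs men
#' pooled_t_from_summary(8.82, 3.72, 12, 19.30, 6.66, 4)$p_two_sided
#' @export
pooled_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("both groups need at least 2 observations")
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be non-negative")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  if (se == 0) {
    t_stat <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
  } else {
    t_stat <- (mean_a - mean_b) / se
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df)
  structure(list(mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                 mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                 t_stat = t_stat, df = df, p_two_sided = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("pooled t = %.4f, df = %d, two-sided p = %.4f\n",
              x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Classify an MMSE score into a dementia-severity band
#'
#' Mini-Mental State Examination severity bands: severe 0-10, moderate
#' 11-20, mild 21-26, none 27-30.
#'
#' @param score integer MMSE score(s) in \eqn{[0, 30]}.
#' @return factor with levels `severe`, `moderate`, `mild`, `none`.
#' @export
classify_mmse <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 30))
    stop("MMSE scores must lie in [0, 30]")
  cut(score, breaks = c(-0.5, 10.5, 20.5, 26.5, 30.5),
      labels = c("severe", "moderate", "mild", "none"))
}

cohort_numeric_vars <- c(
  "id_adl", "age", "length_of_stay", "height_cm", "weight_kg", "bmi",
  "smi", "arm_muscle_kg", "mmse", "avg_velocity_ms", "avg_elevation_deg",
  "grip_kg", "active_flexion_deg", "passive_flexion_deg")

#' Validate a cohort table
#'
#' Checks the per-participant schema: a `sex` column with values `woman` /
#' `man`, MMSE in \eqn{[0, 30]}, angles in \eqn{[0, 180]} and non-negative
#' masses, days and velocities.  Missing values (e.g. a handgrip
#' measurement a participant could not perform) are legal and are excluded
#' pairwise by downstream statistics.
#'
#' @param table data.frame, one row per participant.
#' @return the table, invisibly, or an error.
#' @export
validate_cohort <- function(table) {
  if (!is.data.frame(table) || nrow(table) < 1L)
    stop("cohort table must be a data.frame with at least one row")
  if (!"sex" %in% names(table) || !all(table$sex %in% c("woman", "man")))
    stop("cohort table needs a sex column with values 'woman'/'man'")
  chk <- function(col, lo, hi) {
    if (col %in% names(table)) {
      v <- table[[col]]
      if (any(v < lo | v > hi, na.rm = TRUE))
        stop("column ", col, " outside [", lo, ", ", hi, "]")
    }
  }
  chk("mmse", 0, 30)
  chk("active_flexion_deg", 0, 180)
  chk("passive_flexion_deg", 0, 180)
  for (col in c("length_of_stay", "weight_kg", "smi", "arm_muscle_kg",
                "grip_kg", "avg_velocity_ms"))
    chk(col, 0, Inf)
  invisible(table)
}

#' Descriptive summary of a cohort with sex comparisons
#'
#' Reproduces the structure of the published cohort table from raw rows:
#' per variable, the overall mean (SD) and range, per-sex means (SDs), and
#' the pooled two-sample t-test p-value for the sex difference (two-sided;
#' see [pooled_t_from_summary()]).  Missing values are excluded per
#' variable, with the number used reported.  With fewer than two
#' observations in either sex the comparison columns are `NA`.
#'
#' @param table a validated cohort data.frame (see [validate_cohort()]).
#' @return data.frame with one row per available cohort variable.
#' @export
summarize_cohort <- function(table) {
  validate_cohort(table)
  vars <- intersect(cohort_numeric_vars, names(table))
  if (length(vars) == 0L) stop("no recognized cohort variables present")
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    ok <- is.finite(x)
    xw <- x[ok & table$sex == "woman"]
    xm <- x[ok & table$sex == "man"]
    cmp <- if (length(xw) >= 2 && length(xm) >= 2) {
      pooled_t_from_summary(mean(xw), stats::sd(xw), length(xw),
                            mean(xm), stats::sd(xm), length(xm))
    } else {
      list(t_stat = NA_real_, p_two_sided = NA_real_)
    }
    data.frame(variable = v, n = sum(ok), n_missing = sum(!ok),
               mean = mean(x[ok]), sd = stats::sd(x[ok]),
               min = if (any(ok)) min(x[ok]) else NA_real_,
               max = if (any(ok)) max(x[ok]) else NA_real_,
               mean_women = if (length(xw)) mean(xw) else NA_real_,
               sd_women = if (length(xw) > 1) stats::sd(xw) else NA_real_,
               n_women = length(xw),
               mean_men = if (length(xm)) mean(xm) else NA_real_,
               sd_men = if (length(xm) > 1) stats::sd(xm) else NA_real_,
               n_men = length(xm),
               t_stat = cmp$t_stat, p_sex = cmp$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
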