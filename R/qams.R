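#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of peak area (Y) on concentration (X). The LOD
#' and LOQ are the concentrations at which the predicted peak *height*
#' equals 3 and 10 times the noise SD respectively (the 3:1 / 10:1
#' signal-to-noise criterion); height is derived from predicted area via
#' `height_per_area`, the peak shape factor (`1 / (sigma sqrt(2 pi))` for
#' a Gaussian of width sigma in minutes).
#'
#' @param concentrations Concentrations in ug/mL (at least 3 distinct
#'   levels).
#' @param areas Corresponding peak areas.
#' @param noise_sd Detector noise SD (intensity units); `NA` to skip
#'   LOD/LOQ.
#' @param height_per_area Peak height per unit area (1/minutes).
#' @param compound Compound name carried in the result.
#' @return Object of class `calibration_curve`: `compound`, `slope`,
#'   `intercept`, `r_squared`, `linear_range`, `lod`, `loq`, `model` (the
#'   underlying `lm`).
#' @examples
#' conc <- c(2, 5, 10, 20, 40, 80)
#' fit_calibration(conc, 2e7 * conc, noise_sd = 5e6,
#'                 height_per_area = 1 / (0.05 * sqrt(2 * pi)))
#' @export
fit_calibration <- function(concentrations, areas, noise_sd = NA,
                            height_per_area = NA, compound = "") {
  if (length(unique(concentrations)) < 3L)
    stop("need at least 3 distinct concentration levels")
  if (stats::var(concentrations) == 0) stop("zero variance in concentrations")
  fit <- stats::lm(areas ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # computed directly: summary.lm warns on the exact fits that synthetic
  # noiseless calibrations legitimately produce
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((areas - mean(areas))^2)
  lod <- loq <- NA_real_
  if (is.finite(noise_sd) && is.finite(height_per_area) && slope > 0) {
    lod <- (3 * noise_sd / height_per_area - intercept) / slope
    loq <- (10 * noise_sd / height_per_area - intercept) / slope
  }
  structure(list(compound = compound, slope = slope, intercept = intercept,
                 r_squared = r2,
                 linear_range = range(concentrations),
                 lod = lod, loq = loq, model = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<calibration_curve>%s Y = %.6g X %+.6g  (R2 = %.4f)\n",
    if (nzchar(x$compound)) paste0(" ", x$compound, ":") else "",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear range %.4g-%.4g ug/mL; LOD %.4g, LOQ %.4g ug/mL\n",
              x$linear_range[1L], x$linear_range[2L], x$lod, x$loq))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.calibration_curve <- function(object, concentrations, ...) {
  if (missing(concentrations)) return(stats::fitted(object$model))
  object$intercept + object$slope * concentrations
}

#' @export
residuals.calibration_curve <- function(object, ...)
  stats::residuals(object$model)

#' @export
plot.calibration_curve <- function(x, ...) {
  d <- x$model$model
  graphics::plot(d$concentrations, d$areas, xlab = "concentration (ug/mL)",
                 ylab = "peak area", main = x$compound, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' External-standard content
#'
#' Inverts a calibration curve: `((area - intercept) / slope) x
#' dilution_factor`. A warning (class `qamsfp_extrapolation`) is issued
#' when the back-calculated injected concentration falls outside the
#' curve's linear range.
#'
#' @param curve A [fit_calibration()] result.
#' @param area Observed peak area(s).
#' @param dilution_factor Sample dilution applied before injection.
#' @param warn Set `FALSE` to silence the extrapolation guard.
#' @return Content in ug/mL (vectorised over `area`).
#' @export
esm_content <- function(curve, area, dilution_factor = 1, warn = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  conc <- (area - curve$intercept) / curve$slope
  if (warn && any(conc < curve$linear_range[1L] |
                  conc > curve$linear_range[2L]))
    warning(warningCondition(
      sprintf("%s: back-calculated concentration outside linear range",
              curve$compound),
      class = "qamsfp_extrapolation"))
  conc * dilution_factor
}

#' Relative correction factor
#'
#' `f_x = (C_x x A_ref) / (C_ref x A_x)`: the ratio of the marker's
#' response per concentration to the compound's, measured from one run in
#' which both concentrations are known. Invariant to any rescaling that
#' affects both areas equally (injection volume, detector gain).
#'
#' @param c_x,a_x Concentration and peak area of the compound.
#' @param c_ref,a_ref Concentration and peak area of the marker.
#' @return The relative correction factor (vectorised).
#' @export
compute_rcf <- function(c_x, a_x, c_ref, a_ref) {
  if (any(c(c_x, a_x, c_ref, a_ref) <= 0))
    stop("all concentrations and areas must be positive")
  (c_x * a_ref) / (c_ref * a_x)
}

#' Single-marker (QAMS) content
#'
#' Inverts the relative-correction-factor relation: `C_x = f_x x C_ref x
#' A_x / A_ref`, scaled by the sample dilution. `C_ref` is the marker
#' content of the same run (typically obtained by ESM from the marker's
#' own curve); only the marker needs a calibration standard.
#'
#' @param f_x Relative correction factor of the compound.
#' @param c_ref Marker concentration in the run (ug/mL, injected scale).
#' @param a_x,a_ref Peak areas of the compound and the marker.
#' @param dilution_factor Sample dilution applied before injection.
#' @return Content in ug/mL.
#' @export
qams_content <- function(f_x, c_ref, a_x, a_ref, dilution_factor = 1) {
  if (any(c(f_x, c_ref, a_x, a_ref, dilution_factor) <= 0))
    stop("all inputs must be positive")
  f_x * c_ref * a_x / a_ref * dilution_factor
}

#' Relative retention time
#'
#' A peak's apex time divided by the marker peak's apex time; used for
#' peak location across instruments and columns.
#'
#' @param rt_x Retention time(s) in minutes.
#' @param rt_ref Marker retention time (> 0).
#' @return Ratio(s).
#' @export
relative_retention_time <- function(rt_x, rt_ref) {
  if (any(rt_ref <= 0)) stop("reference retention time must be positive")
  rt_x / rt_ref
}

#' Locate a peak by relative retention time
#'
#' Returns the peak whose relative RT (vs the marker apex) is nearest to
#' `expected_t` and within `tolerance`; equidistant candidates resolve to
#' the larger area. No candidate within tolerance raises an error of
#' class `qamsfp_peak_not_found`.
#'
#' @param t A [peak_table].
#' @param marker_apex Marker apex time in minutes.
#' @param expected_t Expected relative retention time.
#' @param tolerance Half-width of the acceptance window on the
#'   relative-RT axis.
#' @return One-row data.frame (the matched peak) with a `rel_rt` column.
#' @export
locate_peak_by_relative_rt <- function(t, marker_apex, expected_t,
                                       tolerance = 0.02) {
  stopifnot(marker_apex > 0, tolerance > 0)
  rel <- t$apex_time / marker_apex
  d <- abs(rel - expected_t)
  cand <- which(d <= tolerance)
  if (length(cand) == 0L)
    stop(errorCondition(
      sprintf("no peak within %.3g of relative RT %.4g in sample '%s'",
              tolerance, expected_t, attr(t, "sample_id")),
      class = c("qamsfp_peak_not_found", "error")))
  best <- cand[order(d[cand], -t$area[cand])][1L]
  out <- as.data.frame(t)[best, , drop = FALSE]
  out$rel_rt <- rel[best]
  rownames(out) <- NULL
  out
}

#' Relative error between QAMS and ESM contents
#'
#' `(QAMS - ESM) / ESM x 100`, the agreement statistic between the
#' single-marker and external-standard determinations of the same
#' analyte in the same sample.
#'
#' @param qams,esm Contents (same units); `esm` must be positive.
#' @return Signed percentage (vectorised).
#' @export
relative_error <- function(qams, esm) {
  if (any(esm <= 0)) stop("ESM content must be positive")
  (qams - esm) / esm * 100
}

#' Spike-recovery rate
#'
#' `(found - known) x 100 / added`: percentage of a spiked amount
#' recovered on re-analysis.
#'
#' @param found Total amount found after spiking.
#' @param known Amount present before spiking.
#' @param added Spiked amount (> 0); all in consistent units (e.g. ug).
#' @return Percentage (vectorised).
#' @export
recovery_rate <- function(found, known, added) {
  if (any(added <= 0)) stop("added amount must be positive")
  (found - known) * 100 / added
}

#' Summarize a robustness condition table
#'
#' Per-compound arithmetic mean and relative standard deviation (sample
#' SD, n-1 denominator) of a quantity measured under several conditions -
#' the summary rows of an RCF or relative-RT robustness table. Report
#' rounding convention: means to 4 decimals, RSD to 2 (applied by the
#' print method only; stored values keep full precision).
#'
#' @param values data.frame: one row per condition, one numeric column per
#'   compound, with the condition labels in column `condition_col`.
#' @param condition_col Index/name of the condition-label column (dropped
#'   before summarizing); `NULL` if every column is a compound.
#' @param grouping Label describing the varied condition.
#' @return Object of class `condition_summary`: data.frame `compound`,
#'   `n`, `mean`, `rsd_pct` with attribute `grouping`.
#' @examples
#' summarize_condition_table(data.frame(
#'   run = 1:3, a = c(1, 2, 3)))  # mean 2, RSD 50%
#' @export
summarize_condition_table <- function(values, condition_col = 1L,
                                      grouping = "") {
  df <- as.data.frame(values)
  if (!is.null(condition_col) && ncol(df) > 1L) df[condition_col] <- NULL
  num <- vapply(df, is.numeric, logical(1))
  dat <- df[, num, drop = FALSE]
  if (ncol(dat) == 0L) stop("no numeric compound columns")
  if (nrow(dat) < 2L) stop("need at least two conditions (n >= 2)")
  m <- vapply(dat, mean, numeric(1))
  s <- vapply(dat, stats::sd, numeric(1))
  structure(data.frame(compound = names(dat), n = nrow(dat),
                       mean = unname(m), rsd_pct = unname(100 * s / m),
                       row.names = NULL),
            class = c("condition_summary", "data.frame"),
            grouping = grouping)
}

#' @export
print.condition_summary <- function(x, ...) {
  g <- attr(x, "grouping")
  if (nzchar(g)) cat("Condition:", g, "\n")
  out <- data.frame(compound = x$compound, n = x$n,
                    mean = sprintf("%.4f", x$mean),
                    `RSD (%)` = sprintf("%.2f", x$rsd_pct),
                    check.names = FALSE)
  print(out, row.names = FALSE, ...)
  invisible(x)
}
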