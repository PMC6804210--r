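#' Fit a QAMS quantitation model
#'
#' The single fitting entry point for quantitative analysis of
#' multi-components by a single marker. From a mixed-standard calibration
#' data set (every compound at several known concentrations, with
#' measured peak areas) it fits one external-standard curve per compound
#' and estimates the relative correction factor (RCF) of each compound
#' against the marker as the mean of the per-level ratios
#' `(C_x A_ref) / (C_ref A_x)`. For zero-intercept linear responses the
#' RCF equals `slope_ref / slope_x`.
#'
#' Once fitted, only the marker's standard is needed to quantify new
#' samples: [predict.qams_model()] locates each compound by relative
#' retention time, determines the marker content by ESM, and every other
#' content both by ESM (for comparison) and by the single-marker route.
#'
#' @param calibration data.frame with columns `compound`, `level`,
#'   `concentration_ug_ml`, `area` (as written by the calibration-series
#'   generator or an instrument export).
#' @param marker Name of the single-marker reference compound.
#' @param expected_rel_rt Optional named vector of expected relative
#'   retention times per compound (marker = 1); if omitted it must be
#'   supplied to `predict`.
#' @param noise_sd,height_per_area Optional noise figure and peak shape
#'   factor used for LOD/LOQ on each curve (see [fit_calibration()]);
#'   `height_per_area` may be a named vector per compound.
#' @return Object of class `qams_model`: list with `curves` (named list
#'   of [fit_calibration()] curves), `rcf` (named vector, marker = 1),
#'   `rcf_by_level` (matrix), `marker`, `compounds`, `expected_rel_rt`.
#' @seealso [compute_rcf()], [qams_content()], [esm_content()]
#' @export
qams <- function(calibration, marker = "forsythoside_A",
                 expected_rel_rt = NULL, noise_sd = NA,
                 height_per_area = NA) {
  need <- c("compound", "concentration_ug_ml", "area")
  stopifnot(all(need %in% names(calibration)))
  compounds <- unique(calibration$compound)
  if (!marker %in% compounds)
    stop("marker '", marker, "' not present in the calibration data")
  hpa <- if (length(height_per_area) > 1L)
    height_per_area[compounds] else rep(height_per_area, length(compounds))
  names(hpa) <- compounds
  curves <- lapply(compounds, function(cp) {
    d <- calibration[calibration$compound == cp, ]
    fit_calibration(d$concentration_ug_ml, d$area, noise_sd = noise_sd,
                    height_per_area = hpa[[cp]], compound = cp)
  })
  names(curves) <- compounds

  # per-level RCFs against the marker (levels paired by the 'level'
  # column when present, else by row order within compound)
  cal <- calibration
  if (!"level" %in% names(cal))
    cal$level <- stats::ave(seq_len(nrow(cal)), cal$compound,
                            FUN = seq_along)
  ref <- cal[cal$compound == marker, ]
  rcf_by_level <- sapply(setdiff(compounds, marker), function(cp) {
    d <- cal[cal$compound == cp, ]
    i <- match(d$level, ref$level)
    compute_rcf(d$concentration_ug_ml, d$area,
                ref$concentration_ug_ml[i], ref$area[i])
  })
  rcf_by_level <- cbind(rcf_by_level,
                        matrix(1, nrow(ref), 1,
                               dimnames = list(NULL, marker)))
  rcf <- colMeans(rcf_by_level)[compounds]
  structure(list(curves = curves, rcf = rcf, rcf_by_level = rcf_by_level,
                 marker = marker, compounds = compounds,
                 expected_rel_rt = expected_rel_rt),
            class = "qams_model")
}

#' Measure calibration areas from standard-run chromatograms
#'
#' Runs peak detection on each mixed-standard chromatogram and locates
#' every compound by relative retention time against the marker peak,
#' producing the `compound`/`level`/`concentration_ug_ml`/`area` table
#' that [qams()] fits.
#'
#' @param chromatograms List of standard-run [chromatogram]s, one per
#'   level.
#' @param concentration_table data.frame with `level`, `compound`,
#'   `concentration_ug_ml` (as produced by
#'   [generate_calibration_series()]).
#' @param marker_rt Expected marker apex time (minutes).
#' @param expected_rel_rt Named vector of expected relative retention
#'   times per compound.
#' @param tolerance Relative-RT acceptance window.
#' @param ... Passed to [detect_and_integrate_peaks()].
#' @return data.frame ready for [qams()].
#' @export
measure_calibration_areas <- function(chromatograms, concentration_table,
                                      marker_rt, expected_rel_rt,
                                      tolerance = 0.02, ...) {
  out <- list()
  for (k in seq_along(chromatograms)) {
    tab <- detect_and_integrate_peaks(chromatograms[[k]], ...)
    mk <- locate_marker_peak(tab, marker_rt)
    lev <- concentration_table[concentration_table$level == k, ]
    for (cp in names(expected_rel_rt)) {
      pk <- locate_peak_by_relative_rt(tab, mk$apex_time,
                                       expected_rel_rt[[cp]],
                                       tolerance = tolerance)
      out[[length(out) + 1L]] <- data.frame(
        compound = cp, level = k,
        concentration_ug_ml =
          lev$concentration_ug_ml[lev$compound == cp],
        area = pk$area)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.qams_model <- function(x, ...) {
  cat(sprintf("<qams_model> marker: %s; %d compounds\n", x$marker,
              length(x$compounds)))
  cat("RCFs:\n")
  print(round(x$rcf, 4))
  invisible(x)
}

#' @export
coef.qams_model <- function(object, ...) object$rcf

#' @export
summary.qams_model <- function(object, ...) {
  cs <- data.frame(
    compound = object$compounds,
    slope = vapply(object$curves, `[[`, numeric(1), "slope"),
    intercept = vapply(object$curves, `[[`, numeric(1), "intercept"),
    r_squared = vapply(object$curves, `[[`, numeric(1), "r_squared"),
    lod = vapply(object$curves, `[[`, numeric(1), "lod"),
    loq = vapply(object$curves, `[[`, numeric(1), "loq"),
    rcf = unname(object$rcf[object$compounds]),
    rcf_rsd_pct = vapply(object$compounds, function(cp) {
      v <- object$rcf_by_level[, cp]
      100 * stats::sd(v) / mean(v)
    }, numeric(1)),
    row.names = NULL)
  structure(list(marker = object$marker, table = cs),
            class = "summary.qams_model")
}

#' @export
print.summary.qams_model <- function(x, ...) {
  cat("QAMS model (marker:", x$marker, ")\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.qams_model <- function(x, ...) {
  n <- length(x$curves)
  op <- graphics::par(mfrow = grDevices::n2mfrow(n),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cv in x$curves) plot(cv, ...)
  invisible(x)
}

#' Quantify samples with a fitted QAMS model
#'
#' For each sample peak table: locate the marker (largest peak near its
#' expected time), locate every modelled compound by relative retention
#' time, compute the ESM content from the compound's own curve and the
#' QAMS content from the marker content and the fitted RCF, and report
#' both with their relative error. The marker's content is by definition
#' identical on both routes.
#'
#' @param object A [qams()] fit.
#' @param peak_tables List of [peak_table]s.
#' @param marker_rt Expected marker apex time in minutes.
#' @param expected_rel_rt Named vector of expected relative retention
#'   times (defaults to the one stored in the model).
#' @param dilution_factor Sample dilution before injection (applied
#'   symmetrically to ESM and QAMS, so the relative error is
#'   dilution-invariant).
#' @param tolerance Relative-RT acceptance window for peak location.
#' @param warn Passed to [esm_content()]'s extrapolation guard.
#' @param ... Unused.
#' @return data.frame: `sample`, `compound`, `esm_content`,
#'   `qams_content`, `re_pct`.
#' @export
predict.qams_model <- function(object, peak_tables, marker_rt,
                               expected_rel_rt = NULL,
                               dilution_factor = 2, tolerance = 0.02,
                               warn = FALSE, ...) {
  rel <- expected_rel_rt %||% object$expected_rel_rt
  if (is.null(rel))
    stop("expected relative retention times are required")
  if (!object$marker %in% names(rel)) rel[object$marker] <- 1
  out <- list()
  for (tab in peak_tables) {
    sid <- attr(tab, "sample_id")
    mk <- locate_marker_peak(tab, marker_rt)
    c_ref_inj <- esm_content(object$curves[[object$marker]], mk$area,
                             dilution_factor = 1, warn = warn)
    for (cp in object$compounds) {
      pk <- if (cp == object$marker) {
        data.frame(area = mk$area)
      } else {
        locate_peak_by_relative_rt(tab, mk$apex_time, rel[[cp]],
                                   tolerance = tolerance)
      }
      esm <- esm_content(object$curves[[cp]], pk$area,
                         dilution_factor = dilution_factor, warn = warn)
      qam <- qams_content(object$rcf[[cp]], c_ref_inj, pk$area, mk$area,
                          dilution_factor = dilution_factor)
      out[[length(out) + 1L]] <- data.frame(
        sample = sid, compound = cp, esm_content = esm,
        qams_content = qam, re_pct = relative_error(qam, esm))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
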