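#' Peak tables
#'
#' A peak table holds the detected peaks of one run, ordered by apex time:
#' apex, integration bounds (minutes), baseline-subtracted height,
#' trapezoidal area (intensity x minutes) and signal-to-noise ratio,
#' together with the run's estimated noise SD.
#'
#' @param peaks data.frame with columns `apex_time`, `left`, `right`,
#'   `height`, `area`, `snr`.
#' @param sample_id Sample identifier.
#' @param noise_sd Noise SD the S/N values refer to.
#' @return Object of class `peak_table` (a data.frame with attributes
#'   `sample_id` and `noise_sd`).
#' @export
peak_table <- function(peaks, sample_id = "", noise_sd = NA_real_) {
  need <- c("apex_time", "left", "right", "height", "area", "snr")
  stopifnot(all(need %in% names(peaks)))
  peaks <- peaks[order(peaks$apex_time), need, drop = FALSE]
  peaks <- peaks[!duplicated(peaks$apex_time), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_table", "data.frame"),
            sample_id = as.character(sample_id)[1L],
            noise_sd = as.numeric(noise_sd)[1L])
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %s: %d peaks (noise_sd = %.4g)\n",
              attr(x, "sample_id"), nrow(x), attr(x, "noise_sd")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read/write a peak table as CSV
#'
#' Columns: `sample_id, apex_time_min, left_min, right_min, height, area,
#' snr`; the run's noise SD travels in a `noise_sd` column (constant).
#'
#' @param x A [peak_table]; `path` a file path.
#' @return `read_peak_table` returns a [peak_table].
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  df <- data.frame(sample_id = attr(x, "sample_id"),
                   apex_time_min = x$apex_time, left_min = x$left,
                   right_min = x$right, height = x$height, area = x$area,
                   snr = x$snr, noise_sd = attr(x, "noise_sd"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @param path Path to a peak-table CSV.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path)
  peak_table(data.frame(apex_time = df$apex_time_min, left = df$left_min,
                        right = df$right_min, height = df$height,
                        area = df$area, snr = df$snr),
             sample_id = df$sample_id[1L],
             noise_sd = if ("noise_sd" %in% names(df)) df$noise_sd[1L]
                        else NA_real_)
}

# Rolling extremes by iterated shifted pmin/pmax: O(n k) vectorised ops,
# edges padded by extension. k is the full (odd) window length.
roll_extreme <- function(x, k, op = pmin) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (s in seq_len(h)) {
    out <- op(out,
              c(x[(s + 1L):n], rep(x[n], s)),
              c(rep(x[1L], s), x[1L:(n - s)]))
  }
  out
}

roll_mean <- function(x, k) {
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

#' Baseline and noise estimation
#'
#' The baseline is a smooth lower envelope obtained by morphological
#' opening (rolling minimum then rolling maximum over `window`) followed
#' by a rolling-mean smoothing of the same width; it tracks slow drift
#' while passing under peaks narrower than the window; it is re-centred so
#' the detrended noise has zero median over the peak-free part of the run.
#' The noise SD comes from first differences of the raw signal (slow drift
#' cancels, white noise keeps `sqrt(2)` times its SD): a robust MAD scale
#' flags the quiet, peak-free differences and their standard deviation is
#' rescaled to the per-point noise SD.
#'
#' @param x A [chromatogram].
#' @param window Envelope window in minutes; must cover at least 5
#'   sampling intervals and must be wider than the peaks.
#' @return List with `baseline` (numeric, same grid as `x`) and `noise_sd`.
#' @export
estimate_baseline_and_noise <- function(x, window = 2) {
  stopifnot(inherits(x, "chromatogram"))
  dt <- sampling_interval(x)
  if (window > diff(range(x$time)))
    stop("'window' is larger than the run")
  k <- max(5L, as.integer(round(window / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  y <- x$intensity
  baseline <- roll_mean(roll_extreme(roll_extreme(y, k, pmin), k, pmax), k)
  resid <- y - baseline
  d <- diff(y)
  s0 <- stats::mad(d, center = stats::median(d)) / sqrt(2)
  if (s0 == 0) {
    noise_sd <- 0
    quiet <- rep(TRUE, length(y))
  } else {
    # mask peak regions (tall detrended signal, dilated outwards) and
    # estimate from differences of adjacent peak-free points
    dil <- max(7L, as.integer(round(0.3 / dt)))
    if (dil %% 2L == 0L) dil <- dil + 1L
    mask <- roll_extreme(as.numeric(resid > 3 * s0), dil, pmax) > 0
    quiet <- !mask
    pair <- quiet[-length(quiet)] & quiet[-1L]
    if (sum(pair) < 50L) {
      noise_sd <- s0
    } else {
      dq <- d[pair]
      keep <- abs(dq - stats::median(dq)) < 5 * stats::mad(dq)
      noise_sd <- stats::sd(dq[keep]) / sqrt(2)
    }
  }
  # rolling-minimum envelopes of a noisy trace sit a few noise SDs low;
  # re-centre on the quiet part so detrended noise has median zero
  baseline <- baseline + stats::median((y - baseline)[quiet])
  list(baseline = baseline, noise_sd = noise_sd)
}

#' Detect and integrate peaks
#'
#' Works on the baseline-subtracted signal. Candidate regions are
#' contiguous runs where a lightly smoothed signal exceeds a floor (twice
#' the smoothed-noise SD, or a small fraction of the maximum for noiseless
#' traces). Within a region, local maxima whose raw height passes both the
#' S/N threshold and `min_height_frac` of the global maximum are kept;
#' adjacent maxima are split at the deepest intervening valley
#' (valley-to-valley bounds, no curve fitting). Areas are trapezoidal
#' integrals of the raw baseline-subtracted signal between the bounds;
#' heights are raw apex values; `snr = height / noise_sd`.
#'
#' When `noise_sd` is zero but `min_snr` is positive, the S/N threshold is
#' taken as an absolute minimum height instead (so noiseless traces do not
#' pass everything or error).
#'
#' @param x A [chromatogram].
#' @param baseline Baseline trace aligned to `x`; `NULL` to estimate via
#'   [estimate_baseline_and_noise()].
#' @param noise_sd Noise SD; `NULL` to estimate.
#' @param min_snr Minimum apex S/N (default 3, the LOD criterion reused as
#'   the detection floor).
#' @param min_height_frac Minimum apex height as a fraction of the tallest
#'   peak.
#' @param smooth_points Odd width (in samples) of the boxcar used only for
#'   region/valley finding; heights and areas always come from the raw
#'   signal.
#' @return A [peak_table].
#' @export
detect_and_integrate_peaks <- function(x, baseline = NULL, noise_sd = NULL,
                                       min_snr = 3, min_height_frac = 0.001,
                                       smooth_points = 5L) {
  stopifnot(inherits(x, "chromatogram"))
  if (is.null(baseline) || is.null(noise_sd)) {
    bn <- estimate_baseline_and_noise(x)
    if (is.null(baseline)) baseline <- bn$baseline
    if (is.null(noise_sd)) noise_sd <- bn$noise_sd
  }
  if (length(baseline) != length(x$time))
    stop("'baseline' must be aligned to the chromatogram grid")
  y <- x$intensity - baseline
  ys <- if (smooth_points > 1L) roll_mean(y, as.integer(smooth_points)) else y
  noise_s <- noise_sd / sqrt(max(1L, smooth_points))

  height_floor <- if (noise_sd > 0) min_snr * noise_sd else min_snr
  region_floor <- if (noise_sd > 0) 2 * noise_s else 1e-4 * max(ys, 1e-300)

  above <- ys > region_floor
  if (!any(above))
    return(peak_table(empty_peaks(), attr(x, "sample_id") %||% x$sample_id,
                      noise_sd))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])

  out <- list()
  gmax <- max(y)
  for (i in seq_len(nrow(regions))) {
    a <- regions[i, 1L]; b <- regions[i, 2L]
    if (b - a < 2L) next
    out[[length(out) + 1L]] <-
      split_region(x, y, ys, a, b, noise_s, height_floor,
                   min_height_frac * gmax)
  }
  pk <- do.call(rbind, out)
  if (is.null(pk) || nrow(pk) == 0L) pk <- empty_peaks()
  pk$snr <- if (noise_sd > 0) pk$height / noise_sd else Inf
  peak_table(pk, x$sample_id, noise_sd)
}

empty_peaks <- function()
  data.frame(apex_time = numeric(0), left = numeric(0), right = numeric(0),
             height = numeric(0), area = numeric(0), snr = numeric(0))

# Split one above-floor region into peaks at the deepest valleys between
# qualifying smoothed local maxima; integrate raw signal per sub-region.
split_region <- function(x, y, ys, a, b, noise_s, height_floor, frac_floor) {
  seg <- ys[a:b]
  n <- length(seg)
  is_max <- c(FALSE, seg[2:(n - 1)] > seg[1:(n - 2)] &
                     seg[2:(n - 1)] >= seg[3:n], FALSE)
  cand <- which(is_max)
  # suppress noise ripples: a maximum must top its neighbourhood by margin
  if (length(cand) > 1L && noise_s > 0) {
    ord <- order(seg[cand], decreasing = TRUE)
    sel <- integer(0)
    for (j in ord) {
      cj <- cand[j]
      ok <- TRUE
      for (s in sel) {
        vall <- min(seg[min(s, cj):max(s, cj)])
        # merge into the taller maximum unless a real valley separates them
        if (min(seg[s], seg[cj]) - vall < 3 * noise_s) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, cj)
    }
    cand <- sort(sel)
  }
  if (length(cand) == 0L) cand <- which.max(seg)
  heights <- vapply(cand, function(ci) {
    w <- max(1L, ci - 3L):min(n, ci + 3L)
    max(y[a - 1L + w])
  }, numeric(1))
  qual <- heights >= max(height_floor, frac_floor)
  cand <- cand[qual]
  if (length(cand) == 0L) return(empty_peaks())
  cand <- sort(cand)
  # bounds: region edges and deepest valley between adjacent maxima
  cuts <- integer(0)
  if (length(cand) > 1L)
    cuts <- vapply(seq_len(length(cand) - 1L), function(j) {
      lo <- cand[j]; hi <- cand[j + 1L]
      lo + which.min(seg[lo:hi]) - 1L
    }, integer(1))
  lefts <- c(1L, cuts)
  rights <- c(cuts, n)
  dt <- sampling_interval(x)
  res <- lapply(seq_along(cand), function(j) {
    li <- a - 1L + lefts[j]; ri <- a - 1L + rights[j]
    ai <- li - 1L + which.max(y[li:ri])
    seg_y <- y[li:ri]
    data.frame(apex_time = x$time[ai], left = x$time[li],
               right = x$time[ri], height = y[ai],
               area = sum((seg_y[-1] + seg_y[-length(seg_y)]) / 2) * dt,
               snr = NA_real_)
  })
  do.call(rbind, res)
}
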