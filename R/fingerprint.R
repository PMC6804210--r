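#' Align common peaks across batches
#'
#' Peaks are mapped to relative retention time (apex time over the marker
#' peak's apex time) and matched to the reference sample's peaks by greedy
#' nearest-neighbour assignment within `rel_rt_tolerance`; ties are broken
#' by smaller relative-RT distance, then larger area. Reference peaks
#' matched in at least `min_fraction` of the samples become the common
#' peaks; everything else is recorded per sample as non-common.
#'
#' The marker peak of each sample is the largest-area peak whose apex lies
#' within `marker_window` (relative) of `marker_rt`; a sample without one
#' is rejected with an error of class `qamsfp_marker_error`.
#'
#' @param tables List of [peak_table]s (named by sample, or carrying
#'   `sample_id` attributes).
#' @param reference_sample Sample id of the alignment template (default:
#'   the first table).
#' @param marker_rt Expected marker apex time in minutes (reference run).
#' @param rel_rt_tolerance Matching tolerance on the relative-RT axis.
#' @param min_fraction Minimum fraction of samples a reference peak must
#'   match in to count as common (default 1: present in every batch).
#' @param marker_window Relative half-width of the marker search window.
#' @param template_min_snr Template floor: reference peaks below this S/N
#'   do not become alignment slots (default 10, the quantifiability
#'   criterion - a common peak must at least be quantifiable in the
#'   reference run). Keeps low-S/N noise excursions in the reference from
#'   capturing genuine peaks of other samples. Sample peaks of any S/N
#'   may still match; `NA` S/N values pass.
#' @return Object of class `aligned_peaks`: list with `areas` (common
#'   peaks x samples matrix, `NA` where missing), `rel_rt` (consensus
#'   relative RT per common peak), `peak_ids`, `samples`, `marker`
#'   (per-sample marker apex/area), `matched_area` and `total_area` per
#'   sample, `noncommon` (list of per-sample unmatched peak tables),
#'   `reference_sample`, `tolerance`.
#' @export
align_common_peaks <- function(tables, reference_sample = NULL,
                               marker_rt, rel_rt_tolerance = 0.02,
                               min_fraction = 1, marker_window = 0.05,
                               template_min_snr = 10) {
  stopifnot(length(tables) >= 1, rel_rt_tolerance > 0)
  ids <- vapply(seq_along(tables), function(i)
    attr(tables[[i]], "sample_id") %||% names(tables)[i] %||%
      paste0("sample", i), character(1))
  names(tables) <- ids
  reference_sample <- reference_sample %||% ids[1L]
  if (!reference_sample %in% ids)
    stop("reference sample '", reference_sample, "' not among the tables")

  marker <- lapply(tables, locate_marker_peak, marker_rt = marker_rt,
                   window = marker_window)
  rel <- lapply(ids, function(s)
    tables[[s]]$apex_time / marker[[s]]$apex_time)
  names(rel) <- ids

  ref_snr <- tables[[reference_sample]]$snr
  slots <- which(is.na(ref_snr) | ref_snr >= template_min_snr)
  ref_rel <- rel[[reference_sample]][slots]
  n_ref <- length(ref_rel)
  assign_mat <- matrix(NA_integer_, n_ref, length(ids),
                       dimnames = list(NULL, ids))
  for (s in ids) {
    assign_mat[, s] <- greedy_match(ref_rel, rel[[s]], tables[[s]]$area,
                                    rel_rt_tolerance)
  }
  frac <- rowMeans(!is.na(assign_mat))
  common <- which(frac >= min_fraction)
  if (length(common) == 0L) stop("no common peaks at this tolerance")
  areas <- matrix(NA_real_, length(common), length(ids),
                  dimnames = list(sprintf("peak_%02d", seq_along(common)),
                                  ids))
  rel_sum <- rel_n <- numeric(length(common))
  matched_area <- total_area <- stats::setNames(numeric(length(ids)), ids)
  noncommon <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) {
    tab <- tables[[s]]
    total_area[s] <- sum(tab$area)
    idx <- assign_mat[common, s]
    got <- !is.na(idx)
    areas[got, s] <- tab$area[idx[got]]
    rel_sum[got] <- rel_sum[got] + rel[[s]][idx[got]]
    rel_n[got] <- rel_n[got] + 1
    matched_area[s] <- sum(tab$area[idx[got]])
    unmatched <- setdiff(seq_len(nrow(tab)), idx[got])
    noncommon[[s]] <- as.data.frame(tab)[unmatched, , drop = FALSE]
  }
  structure(list(areas = areas, rel_rt = rel_sum / rel_n,
                 peak_ids = rownames(areas), samples = ids,
                 marker = do.call(rbind, lapply(ids, function(s)
                   data.frame(sample = s, apex_time = marker[[s]]$apex_time,
                              area = marker[[s]]$area))),
                 matched_area = matched_area, total_area = total_area,
                 noncommon = noncommon,
                 reference_sample = reference_sample,
                 tolerance = rel_rt_tolerance),
            class = "aligned_peaks")
}

locate_marker_peak <- function(tab, marker_rt, window = 0.05) {
  cand <- which(abs(tab$apex_time - marker_rt) <= window * marker_rt)
  if (length(cand) == 0L)
    stop(errorCondition(
      paste0("marker peak not found near ", marker_rt, " min in sample '",
             attr(tab, "sample_id"), "'"),
      class = c("qamsfp_marker_error", "error")))
  best <- cand[which.max(tab$area[cand])]
  list(apex_time = tab$apex_time[best], area = tab$area[best], index = best)
}

# One-to-one greedy assignment of sample peaks to reference slots, closest
# relative-RT pairs first (ties: larger area). Returns, per reference
# slot, the index of the matched sample peak or NA.
greedy_match <- function(ref_rel, sam_rel, sam_area, tol) {
  d <- abs(outer(ref_rel, sam_rel, "-"))
  ok <- which(d <= tol, arr.ind = TRUE)
  out <- rep(NA_integer_, length(ref_rel))
  if (nrow(ok) == 0L) return(out)
  ord <- order(d[ok], -sam_area[ok[, 2L]])
  used_ref <- logical(length(ref_rel))
  used_sam <- logical(length(sam_rel))
  for (k in ord) {
    i <- ok[k, 1L]; j <- ok[k, 2L]
    if (used_ref[i] || used_sam[j]) next
    out[i] <- j
    used_ref[i] <- TRUE
    used_sam[j] <- TRUE
  }
  out
}

#' @export
print.aligned_peaks <- function(x, ...) {
  cat(sprintf(
    "<aligned_peaks> %d common peaks x %d samples (ref %s, tol %.3g)\n",
    nrow(x$areas), length(x$samples), x$reference_sample, x$tolerance))
  cat(sprintf("  missing entries: %d; non-common peaks: %s\n",
              sum(is.na(x$areas)),
              paste(vapply(x$noncommon, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

#' Reference fingerprint (common pattern)
#'
#' Element-wise mean (default) or median of the per-sample common-peak
#' areas, skipping missing entries. This is the common pattern against
#' which batch similarities are computed; it is distinct from the
#' alignment template sample.
#'
#' @param m An [align_common_peaks()] result.
#' @param method `"mean"` or `"median"`.
#' @return Named numeric vector, one entry per common peak.
#' @export
build_reference_fingerprint <- function(m, method = c("mean", "median")) {
  stopifnot(inherits(m, "aligned_peaks"))
  method <- match.arg(method)
  if (any(rowSums(!is.na(m$areas)) == 0L))
    stop("some common peaks have no observed areas")
  apply(m$areas, 1L, if (method == "mean") function(v) mean(v, na.rm = TRUE)
                     else function(v) stats::median(v, na.rm = TRUE))
}

#' Vector-cosine similarity
#'
#' `dot(v1, v2) / (||v1|| ||v2||)`; for non-negative area vectors this
#' lies in `[0, 1]` and is invariant to rescaling either vector.
#'
#' @param v1,v2 Numeric vectors of equal length with non-zero norms.
#' @return The cosine, a scalar.
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have the same length")
  if (anyNA(v1) || anyNA(v2)) stop("missing values in area vectors")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no cosine similarity")
  sum(v1 * v2) / (n1 * n2)
}

#' Whole-curve cosine similarity of two chromatograms
#'
#' Alternative similarity mode: both traces are resampled onto their
#' common time range and compared point-wise by cosine.
#'
#' @param c1,c2 [chromatogram]s.
#' @param n Number of resampling points.
#' @return The cosine of the resampled intensity vectors.
#' @export
trace_cosine <- function(c1, c2, n = 2000L) {
  stopifnot(inherits(c1, "chromatogram"), inherits(c2, "chromatogram"))
  lo <- max(c1$time[1L], c2$time[1L])
  hi <- min(c1$time[length(c1$time)], c2$time[length(c2$time)])
  if (hi <= lo) stop("chromatograms do not overlap in time")
  grid <- seq(lo, hi, length.out = n)
  cosine_similarity(stats::approx(c1$time, c1$intensity, grid)$y,
                    stats::approx(c2$time, c2$intensity, grid)$y)
}

#' Percentage of non-common peak area
#'
#' `100 x` (area of peaks not matched to a common peak) `/` (total peak
#' area) for one sample.
#'
#' @param t A [peak_table].
#' @param matched_idx Integer indices (rows of `t`) of the matched peaks.
#' @return Percentage in `[0, 100]`.
#' @export
noncommon_area_percentage <- function(t, matched_idx) {
  if (nrow(t) == 0L) stop("empty peak table")
  if (length(matched_idx) && (any(matched_idx < 1) ||
                              any(matched_idx > nrow(t))))
    stop("matched indices outside the table")
  100 * (1 - sum(t$area[matched_idx]) / sum(t$area))
}

#' Batch similarity report
#'
#' Per-sample vector-cosine similarity of the common-peak area vector
#' against the reference fingerprint, plus the percentage of non-common
#' peak area.
#'
#' @param m An [align_common_peaks()] result.
#' @param reference Reference fingerprint vector; default the mean pattern
#'   from [build_reference_fingerprint()].
#' @return data.frame `sample`, `similarity`, `non_common_area_pct`.
#' @export
similarity_report <- function(m, reference = NULL) {
  stopifnot(inherits(m, "aligned_peaks"))
  reference <- reference %||% build_reference_fingerprint(m)
  sim <- vapply(m$samples, function(s) {
    v <- m$areas[, s]
    ok <- !is.na(v)
    cosine_similarity(v[ok], reference[ok])
  }, numeric(1))
  data.frame(sample = m$samples, similarity = unname(sim),
             non_common_area_pct =
               unname(100 * (1 - m$matched_area / m$total_area)),
             row.names = NULL)
}

#' Hierarchical clustering heatmap of log2 peak areas
#'
#' Entries are `log2(area + offset)`; samples are clustered
#' agglomeratively (`stats::hclust`) on the chosen metric and the tree is
#' cut into `k` groups. Pass an [align_common_peaks()] result (optionally
#' restricted to a subset of peaks) or a plain peaks x samples matrix.
#'
#' @param m `aligned_peaks` object or numeric matrix (peaks x samples).
#' @param peaks Optional peak ids/indices to restrict to (e.g. the
#'   quantified targets).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @param k Number of groups for the dendrogram cut.
#' @param offset Offset guarding `log2(0)` (area units).
#' @return Object of class `fingerprint_clustering`: list with `hclust`,
#'   `labels` (k-cut group per sample), `matrix` (log2 areas), `k`.
#' @export
cluster_heatmap <- function(m, peaks = NULL, linkage = "average",
                            metric = "euclidean", k = 2L, offset = 1) {
  mat <- if (inherits(m, "aligned_peaks")) m$areas else as.matrix(m)
  if (!is.null(peaks)) mat <- mat[peaks, , drop = FALSE]
  if (nrow(mat) == 0L) stop("empty peak subset")
  if (ncol(mat) < 2L) stop("need at least two samples to cluster")
  lm2 <- log2(mat + offset)
  hc <- stats::hclust(stats::dist(t(lm2), method = metric),
                      method = linkage)
  structure(list(hclust = hc, labels = stats::cutree(hc, k = k),
                 matrix = lm2, k = k),
            class = "fingerprint_clustering")
}

#' @export
print.fingerprint_clustering <- function(x, ...) {
  cat(sprintf("<fingerprint_clustering> %d samples, k = %d cut: ",
              ncol(x$matrix), x$k))
  cat(paste(names(x$labels), x$labels, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.fingerprint_clustering <- function(x, ...,
                                        col = grDevices::hcl.colors(64)) {
  ord <- x$hclust$order
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$hclust, main = "sample clustering", xlab = "", sub = "")
  graphics::image(seq_len(nrow(x$matrix)), seq_len(ncol(x$matrix)),
                  x$matrix[, ord, drop = FALSE], col = col,
                  xlab = "peak", ylab = "sample", axes = FALSE,
                  main = "log2 peak area")
  graphics::axis(2, at = seq_len(ncol(x$matrix)),
                 labels = colnames(x$matrix)[ord], las = 2, cex.axis = 0.7)
  invisible(x)
}
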