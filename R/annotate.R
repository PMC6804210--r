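#' Parts-per-million mass error
#'
#' Signed accurate-mass error `(observed - theoretical) / theoretical x
#' 1e6`; matching criteria use its absolute value.
#'
#' @param observed_mz,theoretical_mz Masses in Da (`theoretical_mz > 0`).
#' @return Signed ppm error (vectorised).
#' @examples
#' ppm_error(500.0025, 500)  # +5 ppm
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical mass must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Annotate MS features against a compound library
#'
#' A feature matches a library entry when `|ppm error| < ppm_tol` and the
#' relative isotope-ratio difference `|iso_obs - iso_theo| / iso_theo x
#' 100 < iso_tol_pct`. When either side lacks an isotope ratio (`NA`) the
#' isotope criterion is skipped for that pair and matching rests on mass
#' alone. If both tables carry a `polarity` column, only same-polarity
#' pairs are considered. Multiple candidates per feature are ranked by
#' `|ppm error|` (rank 1 = best) and all are reported.
#'
#' @param features data.frame with `observed_mz` and optionally
#'   `feature_id`, `isotope_ratio`, `retention_time`, `polarity`,
#'   `intensity`.
#' @param library data.frame with `name`, `theoretical_mz` and optionally
#'   `isotope_ratio`, `polarity`, `class`.
#' @param ppm_tol Mass tolerance in ppm (strict `<`).
#' @param iso_tol_pct Isotope-ratio tolerance in percent (strict `<`).
#' @return data.frame: `feature_id`, `observed_mz`, `name`,
#'   `theoretical_mz`, `ppm_error`, `iso_diff_pct`, `rank` (empty but
#'   well-formed when nothing matches or the library is empty).
#' @export
annotate_features <- function(features, library, ppm_tol = 5,
                              iso_tol_pct = 10) {
  stopifnot(ppm_tol > 0, iso_tol_pct > 0)
  features <- as.data.frame(features)
  library <- as.data.frame(library)
  if (!"feature_id" %in% names(features))
    features$feature_id <- sprintf("F%03d", seq_len(nrow(features)))
  empty <- data.frame(feature_id = character(0), observed_mz = numeric(0),
                      name = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), iso_diff_pct = numeric(0),
                      rank = integer(0))
  if (nrow(library) == 0L || nrow(features) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(features))) {
    lib <- library
    if ("polarity" %in% names(features) && "polarity" %in% names(lib))
      lib <- lib[lib$polarity == features$polarity[i], , drop = FALSE]
    if (nrow(lib) == 0L) next
    ppm <- ppm_error(features$observed_mz[i], lib$theoretical_mz)
    iso_obs <- if ("isotope_ratio" %in% names(features))
      features$isotope_ratio[i] else NA_real_
    iso_theo <- if ("isotope_ratio" %in% names(lib))
      lib$isotope_ratio else rep(NA_real_, nrow(lib))
    iso_diff <- abs(iso_obs - iso_theo) / iso_theo * 100
    iso_ok <- is.na(iso_diff) | iso_diff < iso_tol_pct
    hit <- which(abs(ppm) < ppm_tol & iso_ok)
    if (length(hit) == 0L) next
    hit <- hit[order(abs(ppm[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      feature_id = features$feature_id[i],
      observed_mz = features$observed_mz[i],
      name = lib$name[hit], theoretical_mz = lib$theoretical_mz[hit],
      ppm_error = ppm[hit], iso_diff_pct = iso_diff[hit],
      rank = seq_along(hit))
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Approximate M+1/M isotope ratio from element counts
#'
#' First-isotopologue intensity ratio from natural 13C, 2H, 17O and 15N
#' abundances: `sum(n_element x abundance_ratio)`. Adequate for the
#' <10% isotope-ratio screening criterion; not a full isotope-pattern
#' calculator.
#'
#' @param c,h,o,n Element counts of the (de)protonated formula.
#' @return Expected M+1/M intensity ratio.
#' @export
isotope_ratio_from_counts <- function(c, h, o = 0, n = 0) {
  c * 0.0107 / 0.9893 + h * 0.000115 / 0.999885 +
    o * 0.00038 / 0.99757 + n * 0.003663 / 0.996337
}
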