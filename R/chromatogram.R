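#' Chromatogram objects
#'
#' A chromatogram is a uniformly sampled single-wavelength detector trace:
#' a strictly increasing time grid (minutes) with one finite intensity per
#' time point, plus sample metadata.
#'
#' @param time Numeric vector of acquisition times in minutes. Must be
#'   strictly increasing and uniformly spaced (relative spacing deviation
#'   below 1e-9).
#' @param intensity Numeric vector of detector intensities (arbitrary
#'   units), same length as `time`, all finite.
#' @param sample_id Character scalar identifying the sample/run.
#' @param wavelength Detection wavelength in nm (metadata only).
#' @return An object of class `chromatogram`: a list with elements `time`,
#'   `intensity`, `sample_id` and `wavelength`.
#' @examples
#' ch <- chromatogram(seq(0, 1, by = 0.01), rnorm(101), "blank")
#' print(ch)
#' @export
chromatogram <- function(time, intensity, sample_id = "", wavelength = 254) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) < 2L)
    stop("a chromatogram needs at least two time points")
  if (length(time) != length(intensity))
    stop("'time' and 'intensity' must have the same length")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  dt <- diff(time)
  if (any(dt <= 0))
    stop("'time' must be strictly increasing")
  if ((max(dt) - min(dt)) > 1e-9 * mean(dt))
    stop("'time' must be uniformly spaced")
  structure(
    list(time = time, intensity = intensity,
         sample_id = as.character(sample_id)[1L],
         wavelength = as.numeric(wavelength)[1L]),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %s: %d points, %.4g-%.4g min (dt = %.4g), %g nm\n",
    if (nzchar(x$sample_id)) x$sample_id else "(unnamed)",
    length(x$time), x$time[1L], x$time[length(x$time)],
    x$time[2L] - x$time[1L], x$wavelength))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ..., xlab = "time (min)",
                              ylab = "intensity", type = "l") {
  graphics::plot(x$time, x$intensity, type = type, xlab = xlab, ylab = ylab,
                 main = x$sample_id, ...)
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$time)

#' Sampling interval of a chromatogram, in minutes
#' @param x A [chromatogram].
#' @return The (uniform) grid spacing.
#' @export
sampling_interval <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  (x$time[length(x$time)] - x$time[1L]) / (length(x$time) - 1L)
}

#' Read and write chromatograms
#'
#' CSV is the native dialect: two columns `time_min,intensity` with a
#' header row. mzML chromatogram lists (as written by common proteomics
#' converters) can be read but not written; the first chromatogram entry in
#' the file is returned, with second-based time axes converted to minutes.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"mzml"`; the default guesses from the file
#'   extension.
#' @param sample_id Optional sample id; defaults to the file's base name
#'   (CSV) or the chromatogram `id` attribute (mzML).
#' @return A [chromatogram].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_chromatogram(chromatogram(0:9 / 10, 1:10, "a"), p)
#' read_chromatogram(p)
#' @export
read_chromatogram <- function(path, format = c("auto", "csv", "mzml"),
                              sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  if (format == "mzml") return(read_mzml_chromatogram(path, sample_id))
  df <- utils::read.table(path, header = TRUE, sep = ",", fill = FALSE,
                          colClasses = "numeric")
  if (nrow(df) < 2L) stop("chromatogram file must have at least two rows")
  chromatogram(df[[1L]], df[[2L]],
               sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @param x A [chromatogram] to write.
#' @rdname read_chromatogram
#' @export
write_chromatogram <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  df <- data.frame(time_min = format(x$time, digits = 17, trim = TRUE,
                                     scientific = FALSE),
                   intensity = format(x$intensity, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- mzML chromatogram reading (read-only; uncompressed or zlib binary) ------

read_mzml_chromatogram <- function(path, sample_id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(m = xml2::xml_ns(doc)[["d1"]] %||% "http://psi.hupo.org/ms/mzml")
  chrom <- xml2::xml_find_first(doc, ".//m:chromatogram", ns)
  if (inherits(chrom, "xml_missing"))
    stop("no <chromatogram> element found in ", path)
  arrays <- xml2::xml_find_all(chrom, ".//m:binaryDataArray", ns)
  time <- intensity <- NULL
  for (arr in arrays) {
    cv <- xml2::xml_find_all(arr, ".//m:cvParam", ns)
    acc <- stats::na.omit(c(xml2::xml_attr(cv, "accession"),
                            xml2::xml_attr(cv, "unitAccession")))
    vals <- decode_mzml_binary(
      xml2::xml_text(xml2::xml_find_first(arr, ".//m:binary", ns)), acc)
    if ("MS:1000595" %in% acc) {           # time array
      if ("UO:0000010" %in% acc) vals <- vals / 60  # seconds -> minutes
      time <- vals
    } else if ("MS:1000515" %in% acc) {    # intensity array
      intensity <- vals
    }
  }
  if (is.null(time) || is.null(intensity))
    stop("mzML chromatogram lacks time or intensity array")
  chromatogram(time, intensity,
               sample_id = sample_id %||% xml2::xml_attr(chrom, "id") %||% "")
}

decode_mzml_binary <- function(b64, accessions) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if ("MS:1000574" %in% accessions) {      # zlib compression
    raw <- memDecompress(raw, type = "gzip")
  } else if (!("MS:1000576" %in% accessions) &&
             any(grepl("^MS:10005(74|6[02])$", accessions))) {
    stop("unsupported mzML binary compression")
  }
  size <- if ("MS:1000521" %in% accessions) 4L else 8L  # 32- vs 64-bit float
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}
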