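# Shared fixture builders; everything is generated in code at test time.

# deterministic generator settings with all stochastic parts switched off
quiet_config <- function(...) {
  sim_config(noise_sd = 0, conc_cv = 0, batch_scale_cv = 0,
             rt_jitter_sd = 0, baseline_drift_amplitude = 0,
             cluster_batches = integer(0), ...)
}

# sum-of-Gaussians trace on a fine grid (no generator involved)
gauss_chrom <- function(h, sigma, t0, dt = 0.001, span = 20, baseline = 0,
                        sample_id = "g") {
  t <- seq(0, span, by = dt)
  y <- rep(baseline, length(t))
  for (i in seq_along(h))
    y <- y + h[i] * exp(-(t - t0[i])^2 / (2 * sigma[i]^2))
  chromatogram(t, y, sample_id = sample_id)
}

marker_rt_default <- function() {
  specs <- target_compound_specs()
  specs$rt[specs$name == "forsythoside_A"]
}

expected_rel_rt_default <- function() {
  specs <- target_compound_specs()
  stats::setNames(specs$rt / marker_rt_default(), specs$name)
}

# minimal hand-assembled mzML chromatogram file (synthetic fixture; built
# from the schema's vocabulary, independent of the package's parser)
write_test_mzml <- function(path, time, intensity,
                            time_unit = c("minute", "second"), size = 8L) {
  time_unit <- match.arg(time_unit)
  unit <- if (time_unit == "minute")
    c("UO:0000031", "minute") else c("UO:0000010", "second")
  b64 <- function(v) jsonlite::base64_enc(
    writeBin(as.numeric(v), raw(), size = size, endian = "little"))
  float_acc <- if (size == 8L) c("MS:1000523", "64-bit float")
               else c("MS:1000521", "32-bit float")
  arr <- function(data, kind_acc, kind_name, unit_attr = "") paste0(
    '   <binaryDataArray encodedLength="', nchar(data), '">\n',
    '    <cvParam cvRef="MS" accession="', float_acc[1], '" name="',
    float_acc[2], '"/>\n',
    '    <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '    <cvParam cvRef="MS" accession="', kind_acc, '" name="', kind_name,
    '"', unit_attr, '/>\n',
    '    <binary>', data, '</binary>\n',
    '   </binaryDataArray>\n')
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    ' <run id="run1">\n',
    '  <chromatogramList count="1">\n',
    '   <chromatogram id="TIC" index="0" defaultArrayLength="',
    length(time), '">\n',
    '  <binaryDataArrayList count="2">\n',
    arr(b64(time), "MS:1000595", "time array",
        paste0(' unitCvRef="UO" unitAccession="', unit[1],
               '" unitName="', unit[2], '"')),
    arr(b64(intensity), "MS:1000515", "intensity array"),
    '  </binaryDataArrayList>\n',
    '   </chromatogram>\n',
    '  </chromatogramList>\n',
    ' </run>\n',
    '</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

# calibration table from the generator's exact (contract) areas
exact_calibration <- function(config = quiet_config()) {
  generate_calibration_series(config = config)$table
}
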