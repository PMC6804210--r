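#' Bundled reference tables of the validation study
#'
#' Published validation data of a seven-compound, single-marker UPLC
#' assay of an eleven-herb liquid preparation (254 nm, forsythoside A as
#' the marker), shipped as plain-text CSV under `extdata`:
#'
#' * `calibration`: regression equation (slope/intercept of area on
#'   ug/mL), linear range, R^2, LOD and LOQ per compound.
#' * `rcf`: relative correction factors against forsythoside A under the
#'   routine condition.
#' * `rcf_robustness`: RCFs re-measured across instruments/columns, flow
#'   rates, injection volumes and column temperatures (data rows only).
#' * `rcf_robustness_summary`: the published mean/RSD rows of the above.
#' * `relative_rt`: relative retention times across instruments/columns,
#'   and `relative_rt_summary` for the published summary rows.
#' * `batch_contents`: ESM and QAMS contents (ug/mL) with published
#'   relative errors for 15 batches x 7 compounds (long format; the
#'   marker has no QAMS column - it is its own reference).
#' * `method_validation`: precision/stability/repeatability RSDs and
#'   spike-recovery means/RSDs.
#'
#' @param name Which table to load.
#' @return A data.frame.
#' @examples
#' head(reference_table("batch_contents"))
#' @export
reference_table <- function(name = c("calibration", "rcf",
                                     "rcf_robustness",
                                     "rcf_robustness_summary",
                                     "relative_rt", "relative_rt_summary",
                                     "batch_contents",
                                     "method_validation")) {
  name <- match.arg(name)
  file <- c(calibration = "calibration_reference.csv",
            rcf = "rcf_reference.csv",
            rcf_robustness = "rcf_robustness.csv",
            rcf_robustness_summary = "rcf_robustness_published_summary.csv",
            relative_rt = "relative_rt_robustness.csv",
            relative_rt_summary = "relative_rt_published_summary.csv",
            batch_contents = "batch_contents_reference.csv",
            method_validation = "method_validation_reference.csv")[[name]]
  path <- system.file("extdata", file, package = "qamsfp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
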