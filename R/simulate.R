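#' Default target-compound design
#'
#' The seven quantified marker compounds of the bundled validation study
#' (an eleven-herb antiviral liquid preparation), with the mixed-standard
#' stock concentrations used for the calibration series, detector response
#' slopes (peak area per ug/mL at 254 nm), nominal retention times on a
#' 58-minute gradient, Gaussian peak widths, and monoisotopic masses.
#' Forsythoside A is the single-marker reference compound.
#'
#' `content_ug_ml` is the nominal per-batch content of each compound in the
#' undiluted preparation; sample solutions are injected after the
#' configured dilution (default 2-fold).
#'
#' @return A data.frame with one row per compound: `name`, `stock_mg_ml`,
#'   `content_ug_ml`, `response_factor`, `rt`, `sigma`, `mass`,
#'   `formula_counts` (list column `c(C, H, O)`).
#' @export
target_compound_specs <- function() {
  data.frame(
    name = c("chlorogenic_acid", "liquiritin", "rutin", "forsythoside_A",
             "isochlorogenic_acid_A", "forsythin", "glycyrrhizic_acid"),
    stock_mg_ml = c(0.51, 1.2, 1.25, 9.13, 0.25, 4.12, 2.46),
    content_ug_ml = c(24.3, 56.6, 57.3, 540.9, 100.0, 235.4, 132.9),
    response_factor = c(2e7, 6e6, 2e7, 8e6, 2e7, 1e6, 9e6),
    rt = c(8.72, 18.79, 21.22, 26.00, 28.00, 38.01, 46.99),
    sigma = c(0.045, 0.050, 0.050, 0.055, 0.050, 0.060, 0.055),
    mass = c(354.095082, 418.126382, 610.153385, 624.205400,
             516.126776, 534.210146, 822.403786),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic multi-batch chromatogram generator. The
#' defaults emulate the bundled validation study: 15 batches sharing 49
#' common peaks (7 quantified targets plus 42 unidentified fillers) on a
#' 58-minute run detected at 254 nm, with two quality clusters - batches
#' 11-15 carry elevated liquiritin and glycyrrhizic acid, the pattern a
#' hierarchical clustering of the preparation's batches exposes.
#'
#' @param n_batches Number of batches to simulate.
#' @param n_common_peaks Number of compounds (peaks) shared by all batches.
#' @param rt_jitter_sd Total retention-time jitter SD in minutes, split
#'   into a batch-level shift (80% of the variance) and per-peak jitter.
#' @param baseline_drift_amplitude Amplitude of the smooth baseline hump.
#' @param noise_sd SD of additive white detector noise.
#' @param conc_cv Coefficient of variation of per-batch, per-compound
#'   lognormal concentration variation.
#' @param batch_scale_cv CV of a per-batch global response scale
#'   (injection-volume style variation affecting all peaks together).
#' @param cluster_batches Integer vector: batches forming the second
#'   quality cluster.
#' @param cluster_multipliers Named numeric vector of concentration
#'   multipliers applied to the second cluster's compounds.
#' @param sampling_interval Detector sampling interval in minutes.
#' @param run_length Run length in minutes.
#' @param sample_dilution Dilution factor applied to batch samples before
#'   injection (the quantitation side must multiply contents back up).
#' @param seed Integer seed; a fixed seed makes every generated object
#'   bit-identical across calls.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_batches = 15L, n_common_peaks = 49L,
                       rt_jitter_sd = 0.05, baseline_drift_amplitude = 1e7,
                       noise_sd = 5e6, conc_cv = 0.06, batch_scale_cv = 0.03,
                       cluster_batches = 11:15,
                       cluster_multipliers = c(liquiritin = 1.5,
                                               glycyrrhizic_acid = 1.9),
                       sampling_interval = 0.01, run_length = 58,
                       sample_dilution = 2, seed = 1L) {
  n_targets <- nrow(target_compound_specs())
  stopifnot(n_batches >= 1, n_common_peaks >= n_targets, rt_jitter_sd >= 0,
            noise_sd >= 0, conc_cv >= 0, batch_scale_cv >= 0,
            sampling_interval > 0, run_length > sampling_interval,
            sample_dilution > 0)
  if (missing(cluster_batches)) {
    cluster_batches <- cluster_batches[cluster_batches <= n_batches]
  } else if (length(cluster_batches) && max(cluster_batches) > n_batches) {
    stop("'cluster_batches' outside 1..n_batches")
  }
  structure(list(
    n_batches = as.integer(n_batches),
    n_common_peaks = as.integer(n_common_peaks),
    n_target_compounds = n_targets,
    rt_jitter_sd = rt_jitter_sd,
    baseline_drift_amplitude = baseline_drift_amplitude,
    noise_sd = noise_sd, conc_cv = conc_cv, batch_scale_cv = batch_scale_cv,
    cluster_batches = as.integer(cluster_batches),
    cluster_multipliers = cluster_multipliers,
    sampling_interval = sampling_interval, run_length = run_length,
    sample_dilution = sample_dilution, seed = as.integer(seed)),
    class = "sim_config")
}

# Deterministic seed fan-out: one top-level seed, independent substreams
# for the compound design, each batch's concentrations, jitter and noise.
sub_seed <- function(seed, stream, index = 0L) {
  as.integer(((seed %% 2147483647) * 69069 + stream * 9973 + index) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Compound design underlying a simulation
#'
#' Expands the seven targets with seeded filler compounds so that the run
#' carries `n_common_peaks` peaks in total. Fillers are spread over the
#' 3 min - (run_length - 3) min window, at least 0.55 min apart and kept
#' clear of the target peaks, so every planted peak is resolvable.
#'
#' @param config A [sim_config()].
#' @return data.frame: `name`, `content_ug_ml`, `response_factor`, `rt`,
#'   `sigma`, `mass`, `is_target`.
#' @export
design_compounds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  targets <- target_compound_specs()
  base <- data.frame(name = targets$name,
                     content_ug_ml = targets$content_ug_ml,
                     response_factor = targets$response_factor,
                     rt = targets$rt, sigma = targets$sigma,
                     mass = targets$mass, is_target = TRUE,
                     stringsAsFactors = FALSE)
  n_fill <- config$n_common_peaks - nrow(base)
  if (n_fill > 0L) {
    rts <- with_seed(sub_seed(config$seed, 1L),
                     place_filler_rts(targets$rt, n_fill,
                                      lo = 3, hi = config$run_length - 3))
    fill <- with_seed(sub_seed(config$seed, 1L, 1L), data.frame(
      name = sprintf("filler_%02d", seq_len(n_fill)),
      content_ug_ml = stats::runif(n_fill, 15, 100),
      response_factor = stats::runif(n_fill, 2e6, 2e7),
      rt = rts,
      sigma = stats::runif(n_fill, 0.04, 0.07),
      mass = NA_real_, is_target = FALSE, stringsAsFactors = FALSE))
    base <- rbind(base, fill)
  }
  base <- base[order(base$rt), , drop = FALSE]
  rownames(base) <- NULL
  base
}

# Even-with-jitter placement inside the gaps between target peaks;
# guarantees >= ~0.5 min spacing between any two planted apexes.
place_filler_rts <- function(target_rts, n, lo, hi, clear = 0.6) {
  edges <- sort(c(lo, hi, rep(target_rts, each = 2) +
                    c(-clear, clear)))
  starts <- edges[seq(1, length(edges), by = 2)]
  ends <- edges[seq(2, length(edges), by = 2)]
  keep <- ends - starts > 0.6
  starts <- starts[keep]; ends <- ends[keep]
  len <- ends - starts
  alloc <- floor(len / sum(len) * n)
  while (sum(alloc) < n) {           # hand leftovers to the roomiest gaps
    i <- which.max(len / (alloc + 1))
    alloc[i] <- alloc[i] + 1L
  }
  rts <- numeric(0)
  for (i in seq_along(starts)) {
    k <- alloc[i]
    if (k == 0L) next
    slot <- len[i] / k
    centers <- starts[i] + (seq_len(k) - 0.5) * slot
    rts <- c(rts, centers + stats::runif(k, -0.12, 0.12) * min(slot, 1))
  }
  sort(rts)
}

# Realized per-batch compound table: concentrations (as injected) and
# jittered apex times for one batch, fully determined by (config, batch).
realize_batch <- function(design, config, batch_index) {
  mult <- rep(1, nrow(design))
  if (batch_index %in% config$cluster_batches &&
      length(config$cluster_multipliers)) {
    i <- match(names(config$cluster_multipliers), design$name)
    if (anyNA(i)) stop("cluster multiplier names not in the design")
    mult[i] <- config$cluster_multipliers
  }
  n <- nrow(design)
  conc <- with_seed(sub_seed(config$seed, 2L, batch_index), {
    scale <- exp(stats::rnorm(1, 0, config$batch_scale_cv))
    design$content_ug_ml * mult *
      exp(stats::rnorm(n, 0, config$conc_cv)) * scale
  }) / config$sample_dilution
  apex <- with_seed(sub_seed(config$seed, 3L, batch_index), {
    design$rt + stats::rnorm(1, 0, 0.8 * config$rt_jitter_sd) +
      stats::rnorm(n, 0, 0.6 * config$rt_jitter_sd)
  })
  data.frame(name = design$name, concentration = conc,
             response_factor = design$response_factor, rt = apex,
             sigma = design$sigma, is_target = design$is_target,
             stringsAsFactors = FALSE)
}

sim_time_grid <- function(config)
  seq(0, config$run_length, by = config$sampling_interval)

sim_drift <- function(time, config) {
  u <- time / config$run_length
  config$baseline_drift_amplitude * (4 * u * (1 - u) + 0.2 * u)
}

#' Render one synthetic chromatogram
#'
#' The signal is a smooth baseline hump plus one Gaussian peak per
#' compound (height = response_factor x concentration / (sigma sqrt(2 pi)),
#' so that the integrated peak area equals response_factor x
#' concentration) plus i.i.d. Gaussian detector noise. Retention-time
#' jitter (batch shift + per-peak) is drawn from the `(seed, batch_index)`
#' substream, so the same call is bit-identical and co-rendered negatives
#' share their jitter and noise with the positive sample.
#'
#' @param compounds A compound design as from [design_compounds()], or any
#'   data.frame with `name`, `content_ug_ml`, `response_factor`, `rt`,
#'   `sigma` columns. Concentrations must be non-negative.
#' @param config A [sim_config()].
#' @param batch_index Which batch's jitter/noise substreams to use.
#' @param exclude Character vector of compound names rendered at zero
#'   concentration (negative-sample support).
#' @return A [chromatogram] with `sample_id` `"S<batch_index>"`.
#' @export
render_chromatogram <- function(compounds, config, batch_index = 1L,
                                exclude = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(compounds$content_ug_ml < 0, na.rm = TRUE))
    stop("negative compound concentration")
  if (nrow(compounds) &&
      (any(compounds$rt < 0) || any(compounds$rt > config$run_length)))
    stop("retention times must lie inside the run window")
  realized <- realize_batch(compounds, config, batch_index)
  if (length(exclude)) {
    i <- match(exclude, realized$name)
    if (anyNA(i)) stop("unknown compound name in 'exclude': ",
                       paste(exclude[is.na(i)], collapse = ", "))
    realized$concentration[i] <- 0
  }
  render_realized(realized, config, batch_index)
}

render_realized <- function(realized, config, batch_index) {
  time <- sim_time_grid(config)
  y <- sim_drift(time, config)
  for (i in seq_len(nrow(realized))) {
    h <- realized$response_factor[i] * realized$concentration[i] /
      (realized$sigma[i] * sqrt(2 * pi))
    if (h == 0) next
    y <- y + h * exp(-(time - realized$rt[i])^2 / (2 * realized$sigma[i]^2))
  }
  if (config$noise_sd > 0)
    y <- y + with_seed(sub_seed(config$seed, 4L, batch_index),
                       stats::rnorm(length(time), 0, config$noise_sd))
  chromatogram(time, y, sample_id = paste0("S", batch_index),
               wavelength = 254)
}

#' Generate a full multi-batch set with ground truth
#'
#' Draws per-batch concentrations (lognormal variation, cluster
#' multipliers, a global per-batch scale) and retention-time jitter for
#' every compound of the design, then renders each batch. The ground truth
#' records, for every rendered peak, the batch, apex time, true injected
#' concentration, undiluted content, true area (response_factor x
#' concentration) and the batch's cluster label.
#'
#' @param config A [sim_config()].
#' @param render If `FALSE`, skip signal rendering and return the ground
#'   truth only (fast path for area-level studies).
#' @return A list of class `sim_batches`: `chromatograms` (list of
#'   [chromatogram], or `NULL`), `truth` (data.frame), `design`,
#'   `clusters` (named integer vector, 1 = reference cluster), `config`.
#' @export
generate_batch_set <- function(config = sim_config(), render = TRUE) {
  design <- design_compounds(config)
  clusters <- ifelse(seq_len(config$n_batches) %in% config$cluster_batches,
                     2L, 1L)
  names(clusters) <- paste0("S", seq_len(config$n_batches))
  truth <- vector("list", config$n_batches)
  chroms <- if (render) vector("list", config$n_batches) else NULL
  for (b in seq_len(config$n_batches)) {
    realized <- realize_batch(design, config, b)
    truth[[b]] <- data.frame(
      batch = b, sample_id = paste0("S", b),
      peak_id = sprintf("peak_%02d", seq_len(nrow(realized))),
      compound = realized$name, apex_time = realized$rt,
      concentration = realized$concentration,
      content = realized$concentration * config$sample_dilution,
      area = realized$response_factor * realized$concentration,
      height = realized$response_factor * realized$concentration /
        (realized$sigma * sqrt(2 * pi)),
      is_target = realized$is_target, cluster = unname(clusters[b]),
      stringsAsFactors = FALSE)
    if (render) chroms[[b]] <- render_realized(realized, config, b)
  }
  if (render) names(chroms) <- names(clusters)
  structure(list(chromatograms = chroms,
                 truth = do.call(rbind, truth),
                 design = design, clusters = clusters, config = config),
            class = "sim_batches")
}

#' @export
print.sim_batches <- function(x, ...) {
  cat(sprintf("<sim_batches> %d batches x %d peaks (%d targets), %s\n",
              x$config$n_batches, nrow(x$design),
              sum(x$design$is_target),
              if (is.null(x$chromatograms)) "truth only"
              else sprintf("%d-point traces", length(x$chromatograms[[1]]))))
  invisible(x)
}

#' Generate a mixed-standard calibration series
#'
#' One chromatogram per dilution level of the mixed standard stock. The
#' default six dilution factors span the 3.5-112x range of the validation
#' study (a 32x ratio between the highest and lowest level). Standards are
#' rendered without retention-time jitter or concentration variation;
#' detector noise is optional.
#'
#' @param compounds Standards design, as [target_compound_specs()] (needs
#'   `name`, `stock_mg_ml`, `response_factor`, `rt`, `sigma`).
#' @param dilution_factors Positive, distinct dilution factors.
#' @param config A [sim_config()] controlling the grid/baseline/seed.
#' @param noise_sd Detector noise SD for the standard runs (default 0).
#' @return List: `chromatograms` (one per level, `sample_id` `"std_<k>"`),
#'   `table` (data.frame `level`, `dilution_factor`, `compound`,
#'   `concentration_ug_ml`, `area` - the exact ground-truth areas
#'   `response_factor x concentration`, the generator's linearity
#'   contract; integrate the rendered traces instead when exercising the
#'   detection path).
#' @export
generate_calibration_series <- function(compounds = target_compound_specs(),
                                        dilution_factors =
                                          c(3.5, 7, 14, 28, 56, 112),
                                        config = sim_config(),
                                        noise_sd = 0) {
  if (length(dilution_factors) == 0L) stop("empty dilution factor list")
  if (any(dilution_factors <= 0)) stop("dilution factors must be positive")
  if (anyDuplicated(dilution_factors)) stop("dilution factors must be distinct")
  cfg <- config
  cfg$rt_jitter_sd <- 0; cfg$conc_cv <- 0; cfg$batch_scale_cv <- 0
  cfg$cluster_batches <- integer(0); cfg$noise_sd <- noise_sd
  cfg$sample_dilution <- 1
  tab <- list(); chroms <- list()
  for (k in seq_along(dilution_factors)) {
    df <- dilution_factors[k]
    conc <- compounds$stock_mg_ml * 1000 / df
    realized <- data.frame(name = compounds$name, concentration = conc,
                           response_factor = compounds$response_factor,
                           rt = compounds$rt, sigma = compounds$sigma,
                           stringsAsFactors = FALSE)
    ch <- render_realized(realized, cfg, batch_index = 1000L + k)
    ch$sample_id <- sprintf("std_%d", k)
    chroms[[k]] <- ch
    tab[[k]] <- data.frame(level = k, dilution_factor = df,
                           compound = compounds$name,
                           concentration_ug_ml = conc,
                           area = compounds$response_factor * conc,
                           stringsAsFactors = FALSE)
  }
  list(chromatograms = chroms, table = do.call(rbind, tab))
}

#' Ideal peak tables from simulation ground truth
#'
#' Converts the ground truth of a [generate_batch_set()] result into one
#' [peak_table] per batch carrying the exact apex times and true areas
#' (`response_factor x concentration`) of every planted peak - the
#' generator's contract view, free of detection and integration error.
#' Useful for exercising alignment and quantitation exactly, and for fast
#' replicate studies that do not need signal rendering.
#'
#' @param batch_set A [generate_batch_set()] result.
#' @return Named list of [peak_table]s.
#' @export
truth_peak_tables <- function(batch_set) {
  stopifnot(inherits(batch_set, "sim_batches"))
  truth <- batch_set$truth
  lapply(split(truth, truth$sample_id)[unique(truth$sample_id)],
         function(d)
           peak_table(data.frame(apex_time = d$apex_time,
                                 left = d$apex_time - 0.3,
                                 right = d$apex_time + 0.3,
                                 height = d$height, area = d$area,
                                 snr = Inf),
                      sample_id = d$sample_id[1L], noise_sd = 0))
}

#' Generate a negative (herb-deficient) sample
#'
#' Identical to the positive batch chromatogram under the same seed except
#' that the excluded compounds are rendered at zero concentration, so
#' their peaks are absent while every other peak, the jitter and the
#' noise are unchanged. Emulates re-making the preparation with specific
#' herbs omitted to confirm peak specificity.
#'
#' @param config A [sim_config()].
#' @param excluded_compounds Character vector of design compound names to
#'   remove (unknown names are an error).
#' @param batch_index Which batch to mirror.
#' @return A [chromatogram].
#' @export
generate_negative_sample <- function(config, excluded_compounds,
                                     batch_index = 1L) {
  design <- design_compounds(config)
  render_chromatogram(design, config, batch_index,
                      exclude = excluded_compounds)
}
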