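test_that("rendered apex intensity equals the analytic peak height", {
  cfg <- quiet_config(run_length = 20, sample_dilution = 1)
  one <- data.frame(name = "x", content_ug_ml = 10, response_factor = 1e6,
                    rt = 10, sigma = 0.05, mass = NA, is_target = TRUE)
  ch <- render_chromatogram(one, cfg)
  h <- 1e6 * 10 / (0.05 * sqrt(2 * pi))
  expect_equal(ch$intensity[ch$time == 10], h, tolerance = 1e-12)

  # zero compounds: flat baseline
  flat <- render_chromatogram(one[0, ], cfg)
  expect_true(all(flat$intensity == 0))

  expect_error(render_chromatogram(transform(one, content_ug_ml = -1), cfg),
               "negative")
  expect_error(render_chromatogram(transform(one, rt = 25), cfg), "window")
})

test_that("isolated Gaussian trace integrates to h*sigma*sqrt(2*pi)", {
  cfg <- quiet_config(run_length = 20, sampling_interval = 0.002,
                      sample_dilution = 1)
  one <- data.frame(name = "x", content_ug_ml = 1,
                    response_factor = 0.05 * sqrt(2 * pi),  # height 1
                    rt = 10, sigma = 0.05, mass = NA, is_target = TRUE)
  ch <- render_chromatogram(one, cfg)
  dt <- sampling_interval(ch)
  y <- ch$intensity
  area <- sum((y[-1] + y[-length(y)]) / 2) * dt
  expect_equal(area, 1 * 0.05 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(area, 0.12533, tolerance = 0.01)
})

test_that("batch sets carry complete ground truth at the designed size", {
  cfg <- sim_config(seed = 11)
  bs <- generate_batch_set(cfg, render = FALSE)
  expect_equal(nrow(bs$truth), 15 * 49)
  expect_equal(length(unique(bs$truth$sample_id)), 15L)
  expect_equal(sum(bs$truth$is_target), 15 * 7)
  expect_equal(unname(bs$clusters), rep(c(1L, 2L), c(10, 5)))
  # every peak has exactly one ground-truth record
  expect_false(anyDuplicated(bs$truth[c("sample_id", "peak_id")]) > 0)
})

test_that("jitter-free batches share identical apex times", {
  cfg <- quiet_config(seed = 3)
  bs <- generate_batch_set(cfg, render = FALSE)
  apex <- matrix(bs$truth$apex_time, ncol = cfg$n_batches)
  expect_true(all(apex == apex[, 1]))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_batches = 3)
  a <- generate_batch_set(cfg)
  b <- generate_batch_set(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$chromatograms, b$chromatograms)
  c2 <- generate_batch_set(sim_config(seed = 100, n_batches = 3))
  expect_false(identical(a$chromatograms[[1]]$intensity,
                         c2$chromatograms[[1]]$intensity))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(generate_batch_set(sim_config(seed = 5, n_batches = 2),
                               render = FALSE))
  expect_identical(.Random.seed, before)
})

test_that("calibration series follows the 3.5-112x dilution design", {
  cal <- generate_calibration_series(config = quiet_config())
  expect_equal(length(cal$chromatograms), 6L)
  rng <- tapply(cal$table$concentration_ug_ml, cal$table$compound, range)
  for (r in rng) expect_equal(r[2] / r[1], 32)
  # top level is stock / 3.5, bottom stock / 112
  specs <- target_compound_specs()
  top <- cal$table[cal$table$level == 1, ]
  expect_equal(top$concentration_ug_ml[match(specs$name, top$compound)],
               specs$stock_mg_ml * 1000 / 3.5)

  one <- generate_calibration_series(dilution_factors = 1,
                                     config = quiet_config())
  expect_equal(one$table$concentration_ug_ml[
                 match(specs$name, one$table$compound)],
               specs$stock_mg_ml * 1000)

  expect_error(generate_calibration_series(dilution_factors = numeric(0)),
               "empty")
  expect_error(generate_calibration_series(dilution_factors = c(2, 2)),
               "distinct")
  expect_error(generate_calibration_series(dilution_factors = c(1, -2)),
               "positive")
})

test_that("noiseless detector response is exactly linear in concentration", {
  cal <- generate_calibration_series(config = quiet_config())
  for (cp in unique(cal$table$compound)) {
    d <- cal$table[cal$table$compound == cp, ]
    expect_equal(cor(d$concentration_ug_ml, d$area)^2, 1,
                 tolerance = 1e-10)
    expect_lt(abs(coef(lm(area ~ concentration_ug_ml, d))[1]),
              1e-9 * max(d$area))
  }
})

test_that("negative samples drop exactly the excluded peaks", {
  cfg <- sim_config(seed = 8, n_common_peaks = 12, noise_sd = 0,
                    baseline_drift_amplitude = 0)
  pos <- generate_batch_set(cfg)$chromatograms[[1]]
  neg <- generate_negative_sample(
    cfg, c("liquiritin", "glycyrrhizic_acid"))
  specs <- target_compound_specs()
  gone <- specs$rt[specs$name %in% c("liquiritin", "glycyrrhizic_acid")]
  near <- function(ch, rts) abs(outer(ch$time, rts, "-")) < 0.5
  touched <- rowSums(near(neg, gone)) > 0
  expect_lt(max(neg$intensity[touched]), 1e-3 * max(pos$intensity))
  # untouched regions only differ by the removed peaks' far tails
  expect_lt(max(abs(neg$intensity - pos$intensity)[!touched]),
            1e-8 * max(pos$intensity))

  # empty exclusion reproduces the positive sample bit for bit
  expect_identical(generate_negative_sample(cfg, character(0)), pos)
  # excluding everything leaves a baseline-only trace
  allneg <- generate_negative_sample(cfg, design_compounds(cfg)$name)
  expect_true(all(allneg$intensity == 0))
  expect_error(generate_negative_sample(cfg, "no_such_compound"),
               "unknown compound")
})

test_that("cluster multipliers are recovered from mean true areas", {
  # pool several seeded replicates so the ratio of means is well inside
  # its central-limit regime, then check against the configured contrast
  tr <- do.call(rbind, lapply(1:8, function(s)
    generate_batch_set(sim_config(seed = 120 + s), render = FALSE)$truth))
  cfg <- sim_config()
  for (cp in names(cfg$cluster_multipliers)) {
    a1 <- tr$area[tr$compound == cp & tr$cluster == 1L]
    a2 <- tr$area[tr$compound == cp & tr$cluster == 2L]
    ratio <- mean(a2) / mean(a1)
    se <- ratio * sqrt(sd(a1)^2 / mean(a1)^2 / length(a1) +
                       sd(a2)^2 / mean(a2)^2 / length(a2))
    expect_lt(abs(ratio - cfg$cluster_multipliers[[cp]]), 2 * se)
  }
})

test_that("truth peak tables mirror the ground truth exactly", {
  bs <- generate_batch_set(sim_config(seed = 4, n_batches = 2),
                           render = FALSE)
  tabs <- truth_peak_tables(bs)
  expect_named(tabs, c("S1", "S2"))
  t1 <- subset(bs$truth, sample_id == "S1")
  expect_equal(sort(tabs$S1$area), sort(t1$area))
  expect_equal(nrow(tabs$S2), 49L)
})
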