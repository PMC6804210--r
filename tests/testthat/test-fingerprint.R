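make_tabs <- function(n = 3, extra = NULL) {
  base <- data.frame(apex_time = c(5, 10, 15, 26, 40),
                     left = c(5, 10, 15, 26, 40) - 0.2,
                     right = c(5, 10, 15, 26, 40) + 0.2,
                     height = c(1, 2, 3, 10, 4) * 1e6,
                     area = c(1, 2, 3, 10, 4) * 1e5, snr = 100)
  lapply(seq_len(n), function(i) {
    d <- base
    if (!is.null(extra) && i == extra)
      d <- rbind(d, data.frame(apex_time = 33, left = 32.8, right = 33.2,
                               height = 5e5, area = 5e4, snr = 50))
    peak_table(d, sample_id = paste0("S", i), noise_sd = 1e4)
  })
}

test_that("identical peak tables align with every peak common", {
  al <- align_common_peaks(make_tabs(3), marker_rt = 26)
  expect_equal(nrow(al$areas), 5L)
  expect_true(all(!is.na(al$areas)))
  expect_true(all(vapply(al$noncommon, nrow, integer(1)) == 0L))
  expect_equal(unname(al$rel_rt), c(5, 10, 15, 26, 40) / 26,
               tolerance = 1e-12)
})

test_that("a spurious peak is non-common for its sample only", {
  al <- align_common_peaks(make_tabs(3, extra = 2), marker_rt = 26)
  expect_equal(nrow(al$areas), 5L)
  expect_equal(vapply(al$noncommon, nrow, integer(1)),
               c(S1 = 0L, S2 = 1L, S3 = 0L))
  expect_equal(al$noncommon$S2$apex_time, 33)
  t2 <- make_tabs(3, extra = 2)[[2]]
  expect_equal(noncommon_area_percentage(t2, which(t2$apex_time != 33)),
               100 * 5e4 / 2.05e6)
})

test_that("alignment rejects samples lacking the marker peak", {
  tabs <- make_tabs(2)
  tabs[[2]] <- peak_table(as.data.frame(tabs[[2]])[-4, ], "S2", 1e4)
  expect_error(align_common_peaks(tabs, marker_rt = 26),
               class = "qamsfp_marker_error")
})

test_that("alignment is invariant to sample order", {
  cfg <- sim_config(seed = 31)
  tabs <- truth_peak_tables(generate_batch_set(cfg, render = FALSE))
  a <- align_common_peaks(tabs, reference_sample = "S1",
                          marker_rt = marker_rt_default())
  b <- align_common_peaks(rev(tabs), reference_sample = "S1",
                          marker_rt = marker_rt_default())
  expect_identical(a$areas, b$areas[, colnames(a$areas)])
  # consensus rel-RT means accumulate in sample order: equal to rounding
  expect_equal(a$rel_rt, b$rel_rt, tolerance = 1e-12)
})

test_that("synthetic 15x49 batches recover exactly the planted peaks", {
  cfg <- sim_config(seed = 17)
  bs <- generate_batch_set(cfg, render = FALSE)
  al <- align_common_peaks(truth_peak_tables(bs), reference_sample = "S1",
                           marker_rt = marker_rt_default())
  expect_equal(nrow(al$areas), 49L)
  expect_true(all(!is.na(al$areas)))
  # correspondence equals ground truth: areas per sample match by peak
  tr1 <- subset(bs$truth, sample_id == "S7")
  tr1 <- tr1[order(tr1$apex_time), ]
  expect_equal(unname(al$areas[, "S7"]), tr1$area)
})

test_that("reference fingerprint is the elementwise mean or median", {
  al <- align_common_peaks(make_tabs(3), marker_rt = 26)
  expect_equal(unname(build_reference_fingerprint(al)),
               c(1, 2, 3, 10, 4) * 1e5)
  two <- list(
    peak_table(data.frame(apex_time = c(5, 26), left = c(4.8, 25.8),
                          right = c(5.2, 26.2), height = c(1, 9) * 1e6,
                          area = c(1, 9) * 1e5, snr = 10), "A", 1),
    peak_table(data.frame(apex_time = c(5, 26), left = c(4.8, 25.8),
                          right = c(5.2, 26.2), height = c(3, 9) * 1e6,
                          area = c(3, 9) * 1e5, snr = 10), "B", 1))
  al2 <- align_common_peaks(two, marker_rt = 26)
  expect_equal(unname(build_reference_fingerprint(al2))[1], 2e5)
})

test_that("cosine similarity follows its definition", {
  v <- c(3, 1, 4, 1, 5)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, 7 * v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("non-common area percentage covers its edge cases", {
  t1 <- make_tabs(1)[[1]]
  expect_equal(noncommon_area_percentage(t1, seq_len(nrow(t1))), 0)
  expect_equal(noncommon_area_percentage(t1, integer(0)), 100)
  t2 <- peak_table(data.frame(apex_time = 1:3, left = 1:3 - .1,
                              right = 1:3 + .1, height = 1,
                              area = c(80, 10, 10), snr = 1), "x", 0)
  expect_equal(noncommon_area_percentage(t2, 1L), 20)
  expect_error(noncommon_area_percentage(t2[0, ], 1L), "empty")
})

test_that("noiseless batches are all perfectly similar to the reference", {
  cfg <- quiet_config(seed = 5, n_batches = 5)
  bs <- generate_batch_set(cfg, render = FALSE)
  al <- align_common_peaks(truth_peak_tables(bs),
                           marker_rt = marker_rt_default())
  rep_ <- similarity_report(al)
  expect_equal(rep_$similarity, rep(1, 5), tolerance = 1e-9)
  expect_equal(rep_$non_common_area_pct, rep(0, 5))
})

test_that("more concentration noise means lower mean similarity", {
  mean_sim <- function(cv, seed) {
    cfg <- sim_config(seed = seed, conc_cv = cv,
                      cluster_batches = integer(0), noise_sd = 0)
    al <- align_common_peaks(
      truth_peak_tables(generate_batch_set(cfg, render = FALSE)),
      marker_rt = marker_rt_default())
    mean(similarity_report(al)$similarity)
  }
  sims <- sapply(c(0.02, 0.08, 0.25), function(cv)
    mean(sapply(1:6, function(s) mean_sim(cv, s))))
  expect_true(all(diff(sims) < 0))
})

test_that("trace cosine is 1 for a trace against itself", {
  ch <- gauss_chrom(c(1, 2), c(0.05, 0.1), c(5, 12))
  expect_equal(trace_cosine(ch, ch), 1, tolerance = 1e-12)
})

test_that("clustering merges identical samples at distance zero", {
  m <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9))
  cl <- cluster_heatmap(m, k = 2)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(unname(cl$labels[c("A", "B")]), c(1, 1))
  expect_equal(unname(cl$labels["C"]), 2)
  expect_error(cluster_heatmap(m[, 1, drop = FALSE]), "two samples")
})

test_that("uniform rescaling shifts log2 areas without changing topology", {
  cfg <- sim_config(seed = 23)
  al <- align_common_peaks(
    truth_peak_tables(generate_batch_set(cfg, render = FALSE)),
    marker_rt = marker_rt_default())
  c1 <- cluster_heatmap(al, k = 2, offset = 0)
  c4 <- cluster_heatmap(al$areas * 4, k = 2, offset = 0)
  expect_equal(c4$matrix, c1$matrix + 2, tolerance = 1e-12)
  expect_identical(c4$hclust$merge, c1$hclust$merge)
  expect_equal(c4$hclust$height, c1$hclust$height, tolerance = 1e-9)
})

test_that("the planted two-cluster batch design is recovered at k = 2", {
  cfg <- sim_config(seed = 37)
  bs <- generate_batch_set(cfg, render = FALSE)
  al <- align_common_peaks(truth_peak_tables(bs),
                           marker_rt = marker_rt_default())
  rel <- expected_rel_rt_default()
  ids <- vapply(rel, function(r) which.min(abs(al$rel_rt - r)), integer(1))
  cl <- cluster_heatmap(al, peaks = ids, k = 2)
  agree <- max(mean((cl$labels == 1) == (bs$clusters == 1)),
               mean((cl$labels == 2) == (bs$clusters == 1)))
  expect_equal(agree, 1)
})
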