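test_that("waveform shape criteria separate somatic from noise shapes", {
  fsw <- 30000
  good <- template_waveform(fsw, 400)
  ws <- qc_waveform_shape(good, fsw)
  expect_true(ws$pass_shape && ws$pass_duration && ws$pass_baseline)
  expect_equal(ws$trough_to_peak_us, 400, tolerance = 60)
  # 50 microsecond trough-to-peak fails the duration bound
  fast <- template_waveform(fsw, 50)
  expect_false(qc_waveform_shape(fast, fsw)$pass_duration)
  # a dominant peak preceding the trough violates the shape criterion
  expect_false(qc_waveform_shape(rev(good), fsw)$pass_shape)
  # trough smaller than peak violates the shape criterion
  expect_false(qc_waveform_shape(-0.5 * good, fsw)$pass_shape)
  flat <- qc_waveform_shape(rep(0, 82), fsw)
  expect_false(flat$pass_shape)
  expect_identical(flat$reason, "flat waveform")
})

test_that("spatial-decay slope criterion applies the configured floor", {
  d <- 0:9
  expect_true(qc_spatial_decay(rep(60, 10), d)$pass)       # slope 0
  steep <- qc_spatial_decay(200 - 25 * d, d)
  expect_false(steep$pass)
  expect_equal(steep$slope, -25, tolerance = 1e-9)
  shallow <- qc_spatial_decay(200 - 5 * d, d)
  expect_true(shallow$pass)
  expect_equal(shallow$slope, -5, tolerance = 1e-9)
  expect_true(qc_spatial_decay(c(1, 2), c(0, 1))$pass)     # indeterminate
})

test_that("missing-spike fraction matches the Gaussian tail mass", {
  set.seed(4)
  a <- rnorm(30000, 50, 10)
  expect_lt(estimate_missing_fraction(a, 0)$fraction, 0.01)
  m1 <- estimate_missing_fraction(a[a >= 40], 40)
  expect_lt(abs(m1$fraction - pnorm(-1)), 0.03)    # within 3 points
  m2 <- estimate_missing_fraction(a[a >= 45], 45)
  expect_lt(abs(m2$fraction - pnorm(-0.5)), 0.03)
  expect_gt(m2$fraction, 0.20)   # would fail the QC cap
  expect_warning(estimate_missing_fraction(rep(5, 100), 5), "degenerate")
})

test_that("missingness estimate sharpens with sample size", {
  errs <- vapply(c(1e3, 1e5), function(n) {
    set.seed(11)
    a <- rnorm(n, 50, 10)
    abs(estimate_missing_fraction(a[a >= 40], 40)$fraction - pnorm(-1))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.005)
})

test_that("contamination inversion reproduces the printed formula", {
  p <- qc_params()
  # zero violations give F_p = 0
  clean <- cumsum(0.003 + rexp(500, 50))
  r0 <- refractory_contamination(clean, max(clean), p)
  expect_identical(r0$r, 0L)
  expect_equal(r0$f_p, 0)
  # worked point: N = 10000, T = 3600 s, r = 5 inverts near 0.05
  cc <- 5 * 3600 / (2 * (p$tau_r - p$tau_c) * 1e4^2)
  expect_equal((1 - sqrt(1 - 4 * cc)) / 2, 0.0499, tolerance = 1e-3)
  # forward-evaluating the formula at the returned F_p recovers r
  u <- simulate_units(unit_truth(base_rate = 10, f_p_true = 0.1),
                      duration = 900, seed = 5)[[1]]
  est <- refractory_contamination(u$spike_times, 900, p)
  expect_equal(expected_violations(est$f_p, est$n, 900, p), est$r,
               tolerance = 1e-6)
  # saturated violation counts return F_p = 1 with a flag
  burst <- sort(runif(2000, 0, 1))
  sat <- refractory_contamination(burst, 1, p)
  expect_true(sat$flagged)
  expect_equal(sat$f_p, 1)
  expect_warning(refractory_contamination(1.5, 10, p), "fewer than 2")
})

test_that("simulated spike trains honor refractory and truncation truths", {
  u0 <- simulate_units(unit_truth(base_rate = 5, f_p_true = 0),
                       duration = 600, seed = 6)[[1]]
  expect_identical(sum(diff(u0$spike_times) < 0.002), 0L)
  n <- length(u0$spike_times)
  expect_lt(abs(n - 3000), 3 * sqrt(3000))
  # amplitude floor at mu - sigma removes the lower Gaussian tail
  ut <- unit_truth(base_rate = 10, detection_floor = 40)
  kept <- simulate_units(ut, duration = 1200, seed = 7)[[1]]
  n_expected <- 10 * 1200 * (1 - pnorm(-1))
  expect_equal(length(kept$spike_times) / (10 * 1200), 1 - pnorm(-1),
               tolerance = 0.03)
  expect_true(all(kept$amplitudes >= 40))
})

test_that("full QC passes clean units and fails planted defects", {
  clean <- simulate_units(unit_truth(base_rate = 6), duration = 600,
                          seed = 2)[[1]]
  q <- classify_unit_quality(clean)
  expect_true(q$pass)
  expect_true(all(q$criteria))
  # contamination
  dirty <- simulate_units(unit_truth(base_rate = 8, f_p_true = 0.2),
                          duration = 600, seed = 3)[[1]]
  q2 <- classify_unit_quality(dirty)
  expect_false(q2$criteria[["contamination"]])
  expect_false(q2$pass)
  # spike count
  sparse <- simulate_units(unit_truth(base_rate = 0.4), duration = 500,
                           seed = 4)[[1]]
  q3 <- classify_unit_quality(sparse)
  expect_false(q3$criteria[["count"]])
  # truncation: floor at mu - 0.5 sd loses ~31% of spikes
  cut <- simulate_units(unit_truth(base_rate = 8, detection_floor = 45),
                        duration = 600, seed = 5)[[1]]
  q4 <- classify_unit_quality(cut)
  expect_false(q4$criteria[["missing"]])
  # missing inputs make the unit indeterminate and failing
  q5 <- classify_unit_quality(list(spike_times = 1:10))
  expect_false(q5$pass)
  expect_true(all(is.na(q5$criteria)))
})

test_that("QC metrics are invariant to uniform amplitude rescaling", {
  u <- simulate_units(unit_truth(base_rate = 6), duration = 600,
                      seed = 12)[[1]]
  v <- u
  v$waveform <- 3 * u$waveform
  v$amplitudes <- 3 * u$amplitudes
  qu <- classify_unit_quality(u)
  qv <- classify_unit_quality(v)
  expect_equal(qu$trough_to_peak_us, qv$trough_to_peak_us)
  expect_equal(qu$baseline_frac, qv$baseline_frac)
  expect_lt(abs(qu$missing_fraction - qv$missing_fraction), 1e-3)
  expect_equal(qu$f_p, qv$f_p)
  # the decay slope is the one scale-dependent quantity (documented)
  expect_identical(unname(qu$criteria[names(qu$criteria) != "decay"]),
                   unname(qv$criteria[names(qv$criteria) != "decay"]))
})

test_that("cell-type split uses the duration threshold with wide ties", {
  expect_identical(classify_cell_type(250), "narrow")
  expect_identical(classify_cell_type(600), "wide")
  expect_identical(classify_cell_type(400), "wide")
  expect_identical(classify_cell_type(c(100, 500), threshold_us = 300),
                   c("narrow", "wide"))
})

test_that("multiunit normalization softens by the pooled 10th percentile", {
  set.seed(8)
  bl <- list(runif(40, 2, 6), runif(40, 1, 9), runif(40, 4, 12))
  rates <- list(rep(mean(bl[[1]]), 50), 2 * mean(bl[[2]]) + numeric(50),
                rnorm(50, 5))
  nm <- normalize_multiunit(rates, bl)
  pooled <- sort(unlist(bl))
  expect_equal(nm$soften, unname(quantile(pooled, 0.1)), tolerance = 1e-9)
  expect_true(all(abs(nm$normalized[[1]]) < 1e-9))
  r2 <- (2 * mean(bl[[2]]) - mean(bl[[2]])) / (mean(bl[[2]]) + nm$soften)
  expect_equal(nm$normalized[[2]][1], r2, tolerance = 1e-9)
  expect_lt(abs(r2 - 1), 0.35)   # approaches 1 as softening vanishes
  expect_error(normalize_multiunit(rates, list()), "differ in length")
})

test_that("shuffle responsiveness flags planted effects with exact minimum p", {
  none <- shuffle_responsiveness(rep(5, 50), rep(5, 50), n_shuffles = 500)
  expect_equal(none$statistic, 0)
  expect_false(none$significant)
  set.seed(9)
  b <- rpois(50, 2)
  up <- shuffle_responsiveness(b, b + 10, n_shuffles = 1000, seed = 2)
  expect_equal(up$p_value, 1 / 1001)
  expect_identical(up$sign, "positive")
  dn <- shuffle_responsiveness(b + 10, b, n_shuffles = 1000, seed = 3)
  expect_identical(dn$sign, "negative")
  few <- shuffle_responsiveness(1:3, 4:6)
  expect_true(is.na(few$p_value))
})

test_that("surface-channel detection finds block boundaries and rejects flat maps", {
  C <- diag(40); C[1:20, 1:20] <- 0.9; diag(C) <- 1
  expect_identical(detect_surface_channel(C)$surface_channel, 21L)
  u <- matrix(0.3, 40, 40); diag(u) <- 1
  expect_warning(res <- detect_surface_channel(u), "no detectable")
  expect_true(is.na(res$surface_channel))
  # simulated LFP: shared noise above the surface, independent below
  set.seed(10)
  nt <- 4000; nch <- 32; surface <- 12
  shared <- rnorm(nt)
  lfp <- sapply(seq_len(nch), function(ch)
    if (ch < surface) shared + rnorm(nt, 0, 0.4)
    else rnorm(nt) + 0.3 * rnorm(nt))
  res2 <- detect_surface_channel(cor(lfp))
  expect_lt(abs(res2$surface_channel - surface), 2)
})
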