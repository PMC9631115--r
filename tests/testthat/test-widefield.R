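bandpower <- function(x, fs, lo, hi) {
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}

test_that("SVD compression is exact at the planted rank", {
  set.seed(1)
  u <- rnorm(50); v <- rnorm(200)
  movie <- outer(u, v)
  sv <- svd_compress(movie, 1)
  expect_lt(max(abs(svd_reconstruct(sv) - movie)), 1e-10)
  expect_lt(max(abs(crossprod(sv$U) - diag(1))), 1e-10)
  # planted rank-5 + noise: 5 components capture at least the planted share
  U5 <- matrix(rnorm(50 * 5), 50); V5 <- matrix(rnorm(5 * 200), 5)
  noise <- matrix(rnorm(50 * 200, 0, 0.1), 50)
  noisy <- U5 %*% V5 + noise
  s5 <- svd_compress(noisy, 5)
  # best-rank-5 optimality: residual cannot exceed the planted noise energy
  expect_lte(sum((noisy - svd_reconstruct(s5))^2), sum(noise^2))
  expect_error(svd_compress(noisy, 51), "out of range")
})

test_that("hemodynamic correction removes the shared heartbeat artifact", {
  tr <- widefield_truth(noise_sd = 0.2)
  st <- simulate_widefield(NULL, tr, seed = 4, duration = 40)
  expect_true(all(st$illumination[c(TRUE, FALSE)] == "blue"))
  expect_true(all(st$illumination[c(FALSE, TRUE)] == "violet"))
  ch <- split_channels(st)
  # raw blue spectrum carries the planted in-band artifact
  pix <- which.max(as.vector(tr$gain_map))
  raw_band <- bandpower(ch$blue[pix, ], 35, 5, 15)
  out_band <- bandpower(ch$blue[pix, ], 35, 0.5, 4)
  expect_gt(raw_band, out_band)
  hc <- hemodynamic_correct(ch$blue, ch$violet, ch$times_blue,
                            ch$times_violet, geometry = ch$geometry)
  att <- 1 - bandpower(hc$corrected[pix, ], 35, 5, 15) / raw_band
  expect_gt(att, 0.9)
  expect_true(all(is.finite(hc$model$scale)))
})

test_that("correction preserves slow signals, skips silent violet, idempotent", {
  s <- simulate_session(behavior_regime("associated"), n_trials = 8,
                        seed = 2)
  st <- simulate_widefield(s, widefield_truth(noise_sd = 0), seed = 5)
  ch <- split_channels(st)
  hc <- hemodynamic_correct(ch$blue, ch$violet, ch$times_blue,
                            ch$times_violet, geometry = ch$geometry)
  vt <- st$truth$visual_trace[st$illumination == "blue"]
  pix <- which.max(as.vector(st$truth$visual_map))
  amp <- function(x) unname(stats::coef(stats::lm(x ~ vt))[2])
  expect_gt(amp(hc$corrected[pix, ]) / amp(ch$blue[pix, ]), 0.95)
  # silent violet channel: output equals blue
  z <- matrix(0, nrow(ch$violet), ncol(ch$violet))
  expect_warning(
    hc0 <- hemodynamic_correct(ch$blue, z, ch$times_blue, ch$times_violet),
    "silent")
  expect_identical(hc0$corrected, ch$blue)
  # idempotency: a second pass changes the result by < 1% RMS
  hc2 <- hemodynamic_correct(hc$corrected, ch$violet, ch$times_blue,
                             ch$times_violet, geometry = ch$geometry)
  rel <- sqrt(mean((hc2$corrected - hc$corrected)^2)) /
    sqrt(mean((hc$corrected - mean(hc$corrected))^2))
  expect_lt(rel, 0.01)
})

test_that("dF/F normalization zeroes constants and removes ramps", {
  expect_true(all(normalize_dff(matrix(7, 3, 400), 35)$dff == 0))
  set.seed(6)
  fs <- 35
  t <- seq_len(2000) / fs
  x <- 100 + 5 * t + sin(2 * pi * 0.5 * t)
  d <- normalize_dff(rbind(x, x), fs)
  slope <- stats::coef(stats::lm(d$dff[1, ] ~ t))[2]
  expect_lt(abs(slope), 1e-3)
  expect_equal(d$soften, stats::median(d$F0))
  expect_warning(normalize_dff(matrix(0, 2, 100), 35), "zero baseline")
})

test_that("deconvolution inverts the calcium kernel", {
  x <- matrix(rnorm(600), 3)
  expect_equal(deconvolve(x, 1, lambda = 0), x, tolerance = 1e-10)
  k <- gcamp_kernel(35)
  imp <- numeric(500); imp[c(50, 200, 340)] <- 1
  set.seed(9)
  y <- stats::convolve(imp, rev(k), type = "open")[1:500] +
    rnorm(500, 0, 0.01)
  rec <- deconvolve(y, k, lambda = 1e-5)
  expect_gt(cor(rec, imp), 0.9)
})

test_that("temporal operations commute with spatial reconstruction", {
  set.seed(10)
  movie <- matrix(rnorm(40 * 300), 40) +
    outer(rnorm(40), stats::filter(rnorm(300), rep(0.2, 5),
                                   circular = TRUE))
  sv <- svd_compress(movie, 10)
  k <- gcamp_kernel(35, duration = 2)
  via_sv <- sv$U %*% deconvolve(sv$SV, k, 1e-3)
  via_pix <- deconvolve(svd_reconstruct(sv), k, 1e-3)
  expect_equal(via_sv, via_pix, tolerance = 1e-8)
})

test_that("master-basis recasting satisfies the projection identities", {
  set.seed(11)
  X <- matrix(rnorm(60 * 120), 60)
  sv <- svd_compress(X, 8)
  # identical bases: recast is the identity
  expect_equal(recast_to_master(sv$U, sv$U, sv$SV), sv$SV,
               tolerance = 1e-10)
  # containment: master holds the experiment's column space
  master <- svd_compress(X, 12)
  rec <- recast_to_master(master$U, sv$U, sv$SV)
  expect_equal(master$U %*% rec, sv$U %*% sv$SV, tolerance = 1e-8)
  # partial overlap: residual equals the orthogonal-complement projection
  small <- svd_compress(X + matrix(rnorm(60 * 120), 60), 5)
  rec2 <- recast_to_master(small$U, sv$U, sv$SV)
  P <- small$U %*% t(small$U)
  resid_direct <- (diag(60) - P) %*% (sv$U %*% sv$SV)
  expect_equal(sv$U %*% sv$SV - small$U %*% rec2, resid_direct,
               tolerance = 1e-8)
  expect_error(recast_to_master(sv$U[1:10, ], sv$U, sv$SV), "pixel spaces")
})

test_that("rigid alignment recovers planted transforms of a vascular phantom", {
  set.seed(3)
  base <- gaussian_blur(matrix(rnorm(128 * 128), 128), 2) +
    0.3 * gaussian_blur(matrix(rnorm(128 * 128), 128), 6)
  tf_id <- align_days(list(base, base))
  expect_equal(tf_id$dx[2], 0, tolerance = 0.1)
  expect_equal(tf_id$dy[2], 0, tolerance = 0.1)
  expect_equal(tf_id$theta[2], 0, tolerance = 0.25)
  mov <- apply_rigid(base, dx = 3.2, dy = -2.1, theta = 2)
  tf <- align_days(list(base, mov))
  # recovered transform is the inverse of the applied one
  th <- -2 * pi / 180
  inv_dx <- -(cos(th) * 3.2 - sin(th) * -2.1)
  inv_dy <- -(sin(th) * 3.2 + cos(th) * -2.1)
  expect_equal(tf$theta[2], -2, tolerance = 0.5)
  expect_equal(tf$dx[2], inv_dx, tolerance = 0.5)
  expect_equal(tf$dy[2], inv_dy, tolerance = 0.5)
  expect_error(align_days(list(base, matrix(1, 128, 128))), "degenerate")
})

test_that("hemisphere ratio fitting matches planted movement gains", {
  set.seed(12)
  fs <- 35
  n <- 35 * 120
  M <- pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.02), rep(1, 14),
                                        sides = 1)))
  M[is.na(M)] <- 0
  V <- pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.01), rep(1, 10),
                                        sides = 1)))
  V[is.na(V)] <- 0
  FL <- 1.0 * V + 0.8 * M
  FR <- 0.2 * V + 1.0 * M
  mon <- which(diff(c(0, M > 0)) == 1) / fs
  ok <- vapply(mon, function(o) {
    i <- round((o + seq(-0.2, 0.6, 1 / fs)) * fs) + 1
    i <- i[i >= 1 & i <= n]
    all(V[i] == 0)
  }, logical(1))
  ep <- data.frame(onset = mon[ok])
  hm <- fit_hemisphere_ratio(FL, FR, ep, fs)
  expect_equal(hm$ratio, 0.8, tolerance = 1e-6)
  # right = 1.25 x left forces ratio 0.8 directly
  hm2 <- fit_hemisphere_ratio(FL, 1.25 * FL, ep, fs)
  expect_equal(hm2$ratio, 0.8, tolerance = 1e-9)
  # equal traces give ratio 1 and zero asymmetry
  hm3 <- fit_hemisphere_ratio(FL, FL, ep, fs)
  expect_equal(hm3$ratio, 1, tolerance = 1e-9)
  expect_true(all(abs(hemisphere_subtract(FL, FL, hm3)) < 1e-9))
  # subtraction cancels a purely bilateral signal and keeps the visual one
  asym <- hemisphere_subtract(FL, FR, hm)
  fit <- stats::coef(stats::lm(asym ~ V + M))
  expect_equal(unname(fit["V"]), 1 - 0.8 * 0.2 / 1.0, tolerance = 1e-6)
  expect_lt(abs(fit["M"]) / 0.8, 0.01)     # movement leakage < 1%
  expect_error(fit_hemisphere_ratio(FL, FR, ep[1:2, , drop = FALSE], fs),
               "qualifying epochs")
})

test_that("ROI traces in component space equal pixel-space averages", {
  set.seed(13)
  movie <- matrix(rnorm(24 * 40 * 100), 24 * 40)
  sv <- svd_compress(movie, 30)
  mask <- matrix(FALSE, 24, 40); mask[5:8, 10:14] <- TRUE
  expect_equal(roi_trace(sv$U, sv$SV, mask),
               colMeans(svd_reconstruct(sv)[as.vector(mask), ]),
               tolerance = 1e-8)
  one <- matrix(FALSE, 24, 40); one[3, 7] <- TRUE
  expect_equal(roi_trace(sv$U, sv$SV, one),
               svd_reconstruct(sv)[which(as.vector(one)), ],
               tolerance = 1e-8)
  expect_equal(roi_trace(sv$U, sv$SV, matrix(TRUE, 24, 40)),
               colMeans(svd_reconstruct(sv)), tolerance = 1e-8)
  expect_error(roi_trace(sv$U, sv$SV, matrix(FALSE, 24, 40)), "empty")
})
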