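# Shared fixtures and independent oracles for the test suite.

# Assemble a session-like object from hand-specified bouts and trials,
# bypassing the generator, for hand-enumerable scenarios.
manual_session <- function(bouts, trials, grid, fs = 1000, duration = NULL) {
  if (is.null(duration))
    duration <- max(c(trials$first_move, trials$stim_onset,
                      bouts$onset + bouts$duration), na.rm = TRUE) + 1
  structure(list(trials = trials, bouts = bouts,
                 wheel = visuomotor:::bouts_to_trace(bouts, duration, fs),
                 grid = grid, fs = fs, move_floor = 1,
                 regime = list(mode = "manual"), mouse = "mx", day = 1L),
            class = "vm_session")
}

single_sample_bout <- function(onset, fs = 1000, amplitude = 400) {
  data.frame(onset = onset, duration = 1 / fs, amplitude = amplitude)
}

# Independent brute-force replay oracle: walks the sampled movement vector
# and applies the timer rules literally, sample by sample.
naive_replay <- function(moving, fs, t0, quiescence, t_max = Inf) {
  n <- length(moving)
  timer_start <- t0
  i <- max(1L, floor(t0 * fs) + 2L)  # first sample strictly after t0
  while (i <= n) {
    t <- (i - 1L) / fs
    done <- timer_start + quiescence
    if (t > done + 1e-9)             # timer completed between samples
      return(if (done <= t_max) done else NA_real_)
    if (moving[i]) timer_start <- t  # any movement (incl. at t == done) resets
    i <- i + 1L
  }
  v <- timer_start + quiescence
  if (v <= (n - 1L) / fs + 1e-9 && v <= t_max) v else NA_real_
}

# Poisson rate traces for shuffle-test calibration: counts in equal-length
# windows converted to Hz.
poisson_window_rates <- function(n_trials, rate_hz, window_s) {
  stats::rpois(n_trials, rate_hz * window_s) / window_s
}
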