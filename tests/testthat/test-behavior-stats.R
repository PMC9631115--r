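test_that("reaction times follow the movement-after-stimulus definition", {
  g <- delay_grid(c(1, 1.1), c(0.5, 0.6))
  # five trials on a hand-built trace: still wheel, one bout after each
  # stimulus; trial 3 has a fast (masked) movement, trial 5 none at all
  bouts <- rbind(single_sample_bout(3.0), single_sample_bout(8.2),
                 single_sample_bout(12.05), single_sample_bout(17.15))
  prev <- c(0, 4, 10, 14, 19)
  iti <- c(1, 1.1, 1, 1, 1.1)
  qui <- c(0.5, 0.6, 1, 2, 0.6)
  v <- prev + iti + qui                     # still wheel before each onset
  m <- c(3.0, 8.2, 12.05, 17.15, NA)
  tr <- data.frame(index = 1:5, prev_outcome_time = prev, iti = iti,
                   quiescence = qui, stim_onset = v, first_move = m,
                   rt = m - v, outcome = "none", outcome_time = prev + 3.9)
  s <- manual_session(bouts, tr, g, duration = 30)
  rts <- compute_reaction_times(s)
  expect_equal(rts$rt, c(1.5, 2.5, 0.05, 0.15, NA)[1:4], tolerance = 1e-9)
  expect_identical(rts$masked, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(rts$n_dropped, 1L)
})

test_that("stimulus replay handles still, restarting, and saturated wheels", {
  fs <- 1000
  still <- list(onsets = numeric(), offsets = numeric())
  expect_equal(replay_stimulus_time(still, 2, 1.5, 0.7), 4.2)
  # one movement inside the quiescence window delays onset by one restart
  one <- list(onsets = 3.9, offsets = 3.9)
  expect_equal(replay_stimulus_time(one, 2, 1.5, 0.7), 4.6)  # 3.9 + 0.7
  # movement everywhere: timer never completes
  wall <- list(onsets = 0, offsets = 1000)
  expect_true(is.na(replay_stimulus_time(wall, 2, 1.5, 0.7, t_max = 900)))
})

test_that("exact enumeration matches hand enumeration on a toy session", {
  g <- delay_grid(c(1, 1.1), c(0.5, 0.6))
  # trial 1: still wheel until the answering bout at 3.0
  # trial 2: a lone blip at 5.55 blocks combos that land just before it
  bouts <- rbind(single_sample_bout(3.0), single_sample_bout(5.55),
                 single_sample_bout(6.2))
  tr <- data.frame(index = 1:2, prev_outcome_time = c(0, 4),
                   iti = c(1, 1.1), quiescence = c(0.5, 0.6),
                   stim_onset = c(1.5, 6.15), first_move = c(3.0, 6.2),
                   rt = c(1.5, 0.05), outcome = "none",
                   outcome_time = c(3.5, 7))
  s <- manual_session(bouts, tr, g, duration = 10)
  sup <- exact_conditional_null(s)
  # trial 1: all four combos accepted; RT = 3 - (iti + q)
  expect_equal(sort(sup$trial_rts[[1]]), c(1.3, 1.4, 1.4, 1.5),
               tolerance = 1e-9)
  # trial 2 by hand: (1,0.5) -> V=5.5, next move 5.55 != 6.2: rejected;
  # (1,0.6) -> restart at 5.55, V=6.15, RT=0.05; (1.1,0.5) -> restart,
  # V=6.05, RT=0.15; (1.1,0.6) -> V=6.15, RT=0.05
  expect_equal(sort(sup$trial_rts[[2]]), c(0.05, 0.05, 0.15),
               tolerance = 1e-9)
  expect_equal(sup$acceptance_rate, c(1, 0.75))
})

test_that("acceptance sets always contain the observed delay parameters", {
  for (seed in 1:4) {
    s <- simulate_session(behavior_regime("null"), n_trials = 15,
                          seed = 300 + seed)
    sup <- exact_conditional_null(s)
    obs_rt <- compute_reaction_times(s, rt_floor = 0)$rt
    for (k in seq_along(sup$trial_index)) {
      i <- sup$trial_index[k]
      expect_true(any(abs(sup$trial_rts[[k]] - obs_rt[k]) < 1e-9),
                  label = sprintf("observed RT in support (seed %d trial %d)",
                                  seed, i))
    }
  }
})

test_that("accepted resamples reproduce the observed movement times", {
  s <- simulate_session(behavior_regime("null"), n_trials = 12, seed = 42)
  iv <- movement_intervals(s$wheel, s$move_floor)
  g <- s$grid
  tr <- s$trials[!is.na(s$trials$first_move), ]
  combos <- expand.grid(iti = g$iti_values, qui = g$quiescence_values)
  for (i in seq_len(nrow(tr))) {
    v <- replay_stimulus_time(iv, tr$prev_outcome_time[i], combos$iti,
                              combos$qui)
    nm <- visuomotor:::next_movement(iv$onsets, v)
    ok <- !is.na(v) & !is.na(nm) & abs(nm - tr$first_move[i]) < 1e-9
    # every accepted combo replays to a stimulus whose next movement is M_i
    expect_true(all(abs(nm[ok] - tr$first_move[i]) < 1e-9))
    # and the support reaction times equal M_i - V for those combos
    sup <- visuomotor:::trial_support(s, tr$index[i])
    expect_equal(sort(sup), sort(tr$first_move[i] - v[ok]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate grids give a point-mass null and p = 1", {
  g1 <- delay_grid(c(2, 2), c(0.8, 0.8))
  s <- simulate_session(behavior_regime("null"), g1, n_trials = 15,
                        seed = 11)
  a <- test_association(s, n_resamples = 200, seed = 1)
  expect_equal(a$p_value, 1)
  expect_equal(a$chance_median, a$observed_median)
  expect_equal(a$performance_index, 0)
  nul <- conditional_null(s, 100, seed = 2)
  expect_true(all(abs(nul$medians - a$observed_median) < 1e-9))
})

test_that("a tight stimulus-locked session attains the minimum p-value", {
  g <- delay_grid()
  set.seed(13)
  prev <- cumsum(c(0, rep(12, 29)))
  iti <- sample(g$iti_values, 30, replace = TRUE)
  qui <- sample(g$quiescence_values, 30, replace = TRUE)
  v <- prev + iti + qui
  m <- v + 0.15                            # fixed 150 ms reaction everywhere
  bouts <- do.call(rbind, lapply(m, single_sample_bout))
  tr <- data.frame(index = 1:30, prev_outcome_time = prev, iti = iti,
                   quiescence = qui, stim_onset = v, first_move = m,
                   rt = 0.15, outcome = "none", outcome_time = prev + 11)
  s <- manual_session(bouts, tr, g)
  a <- test_association(s, n_resamples = 400, seed = 3)
  expect_equal(a$p_value, 1 / 401)
  expect_gt(a$performance_index, 0)
})

test_that("rejection sampling converges to the enumerated null", {
  s <- simulate_session(behavior_regime("null"), n_trials = 20, seed = 77)
  n1 <- conditional_null(s, 2000, seed = 1, method = "enumeration")
  n2 <- conditional_null(s, 2000, seed = 2, method = "rejection")
  ks <- suppressWarnings(
    ks.test(n1$medians, n2$medians)$statistic)
  # two-sample DKW-style bound at alpha = 0.01 per sample
  bound <- 2 * sqrt(log(2 / 0.01) / (2 * 2000))
  expect_lt(unname(ks), bound)
})

test_that("association day picks the first sub-threshold day", {
  expect_identical(association_day(c(0.4, 0.2, 0.01, 0.3)), 3L)
  expect_identical(association_day(c(0.4, NA, 0.03)), 3L)
  expect_true(is.na(association_day(c(0.5, 0.2, 0.6))))
})

test_that("performance index follows its ratio definition and bounds", {
  expect_equal(performance_index(1, 1), 0)
  expect_equal(performance_index(1, 3), 0.5)
  expect_equal(performance_index(1e-9, 2), 1, tolerance = 1e-8)
  expect_error(performance_index(-1, 2), "positive")
})

test_that("trial thirds are contiguous with earliest-largest sizes", {
  expect_identical(split_thirds(9), list(1:3, 4:6, 7:9))
  th <- split_thirds(10)
  expect_identical(lengths(th), c(4L, 3L, 3L))
  expect_identical(unlist(th), 1:10)
  expect_identical(lengths(split_thirds(3)), c(1L, 1L, 1L))
  expect_error(split_thirds(2), "at least 3")
})

test_that("too few usable trials yields an absent p-value", {
  s <- simulate_session(behavior_regime("null"), n_trials = 6, seed = 15)
  a <- test_association(s, n_resamples = 100, seed = 1, min_trials = 50)
  expect_true(is.na(a$p_value))
  expect_false(a$significant)
})

test_that("rejection power is monotone in response probability", {
  probs <- c(0.1, 0.5, 0.9)
  rej <- vapply(seq_along(probs), function(j) {
    p <- vapply(1:20, function(i) {
      s <- simulate_session(
        behavior_regime("associated", response_probability = probs[j]),
        n_trials = 40, seed = 5000 + 100 * j + i)
      test_association(s, n_resamples = 500, seed = i)$p_value
    }, numeric(1))
    mean(p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(rej[1] <= rej[2] + 0.1 && rej[2] <= rej[3] + 0.1)
  expect_gt(rej[3], rej[1])
})
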