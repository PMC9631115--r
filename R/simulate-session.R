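#' Simulate a wheel-movement trace
#'
#' Generates a wheel velocity/position trace sampled at `fs` Hz. Movement
#' bouts are boxcar velocity pulses drawn from a thinned Poisson process. In
#' `"associated"` mode, each stimulus time in `stim_times` is answered with
#' probability `regime$response_probability` by an added counterclockwise
#' bout at a drawn latency.
#'
#' @param regime a [behavior_regime()].
#' @param duration trace length, seconds.
#' @param stim_times stimulus onset times to answer in `"associated"` mode.
#' @param seed RNG seed (integer).
#' @param fs sampling rate, Hz (default 1000).
#' @return a `vm_wheel` object with fields `t`, `position`, `velocity`,
#'   `fs`, and attribute `"bouts"` (the generating bout table).
#' @examples
#' w <- simulate_wheel(behavior_regime("null", bout_rate = 0.2), 60, seed = 1)
#' length(movement_intervals(w)$onsets)
#' @export
simulate_wheel <- function(regime, duration, stim_times = numeric(),
                           seed = 1, fs = 1000) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  bouts <- draw_bouts(regime, duration, fs)
  if (regime$mode == "associated" && length(stim_times)) {
    ans <- stats::runif(length(stim_times)) < regime$response_probability
    lat <- draw_latency(regime, length(stim_times))
    for (i in which(ans)) {
      on <- round((stim_times[i] + lat[i]) * fs) / fs
      du <- max(1, round(stats::runif(1, regime$bout_duration[1],
                                      regime$bout_duration[2]) * fs)) / fs
      am <- -stats::runif(1, regime$bout_amplitude[1], regime$bout_amplitude[2])
      bouts <- insert_bout(bouts, on, du, am, fs)
    }
  }
  w <- bouts_to_trace(bouts, duration, fs)
  attr(w, "bouts") <- bouts
  w
}

# Insert a bout unless it would overlap (within 2 samples of) an existing
# one; overlapping insertions are skipped so threshold detection on the
# summed trace still recovers the bout table exactly.
insert_bout <- function(bouts, onset, duration, amplitude, fs) {
  dt <- 1 / fs
  if (nrow(bouts) > 0) {
    clash <- any(onset < bouts$onset + bouts$duration + 2 * dt &
                 bouts$onset < onset + duration + 2 * dt)
    if (clash) return(bouts)
  }
  out <- rbind(bouts, data.frame(onset = onset, duration = duration,
                                 amplitude = amplitude))
  out[order(out$onset), , drop = FALSE]
}

#' Simulate a full task session
#'
#' Replays the task's trial logic over a synthetic wheel: the ITI runs from
#' the previous outcome, a quiescence timer restarts on any wheel movement,
#' the stimulus appears when the timer completes, and the stimulus is yoked
#' to cumulative wheel displacement until it crosses the reward
#' (counterclockwise) or punish (clockwise) threshold. Stimulus onsets are
#' derived with the same replay function used by the randomization test, so
#' re-replaying each trial's delays against the final trace reproduces the
#' recorded onsets exactly.
#'
#' @param regime a [behavior_regime()].
#' @param grid a [delay_grid()].
#' @param n_trials number of trials to attempt.
#' @param seed RNG seed.
#' @param fs wheel sampling rate, Hz.
#' @param move_floor velocity detection floor, degrees/s.
#' @param reward_threshold signed displacement (degrees) for reward
#'   (counterclockwise is negative).
#' @param punish_threshold signed displacement for punishment.
#' @param stim_timeout seconds after stimulus onset before an unanswered
#'   trial ends with outcome `"none"`.
#' @param stim_wait_timeout maximum seconds to wait for a quiescence
#'   completion; exceeded waits truncate the session with a warning.
#' @param consume_time post-reward consumption period added before the next
#'   ITI starts, seconds.
#' @param mouse,day metadata labels stored on the session.
#' @return an object of class `vm_session`: `trials` (data.frame with
#'   `index`, `prev_outcome_time`, `iti`, `quiescence`, `stim_onset`,
#'   `first_move`, `rt`, `outcome`, `outcome_time`), `wheel`, `bouts`,
#'   `grid`, `regime`, `move_floor`, and metadata.
#' @export
simulate_session <- function(regime, grid = delay_grid(), n_trials = 60,
                             seed = 1, fs = 1000, move_floor = 1,
                             reward_threshold = -90, punish_threshold = 90,
                             stim_timeout = 10, stim_wait_timeout = 60,
                             consume_time = 1, mouse = "m1", day = 1L) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  set.seed(seed)
  horizon <- n_trials *
    (grid$iti[2] + 4 * grid$quiescence[2] + stim_timeout + consume_time) + 30
  bouts <- draw_bouts(regime, horizon, fs)
  iv <- bout_intervals(bouts, fs)

  tr <- vector("list", n_trials)
  t_prev <- 0
  truncated <- FALSE
  for (i in seq_len(n_trials)) {
    iti <- grid$iti_values[sample.int(length(grid$iti_values), 1)]
    qui <- grid$quiescence_values[sample.int(length(grid$quiescence_values), 1)]
    v <- replay_core(iv$onsets, iv$offsets, t_prev + iti, qui,
                     t_max = min(horizon - stim_timeout - 1,
                                 t_prev + iti + stim_wait_timeout))
    if (is.na(v)) {
      truncated <- TRUE
      warning(sprintf(
        "session truncated at trial %d: no quiescence completion within %g s",
        i, stim_wait_timeout))
      break
    }
    if (regime$mode == "associated" &&
        stats::runif(1) < regime$response_probability) {
      on <- round((v + draw_latency(regime)) * fs) / fs
      du <- max(1, round(stats::runif(1, regime$bout_duration[1],
                                      regime$bout_duration[2]) * fs)) / fs
      am <- -stats::runif(1, regime$bout_amplitude[1],
                          regime$bout_amplitude[2])
      nb <- insert_bout(bouts, on, du, am, fs)
      if (nrow(nb) > nrow(bouts)) {
        bouts <- nb
        iv <- bout_intervals(bouts, fs)
      }
    }
    m <- next_movement(iv$onsets, v)
    cross <- first_crossing(bouts, v, reward_threshold, punish_threshold,
                            v + stim_timeout)
    out_t <- cross$time + if (cross$outcome == "reward") consume_time else 0
    tr[[i]] <- data.frame(
      index = i, prev_outcome_time = t_prev, iti = iti, quiescence = qui,
      stim_onset = v, first_move = m, rt = m - v,
      outcome = cross$outcome, outcome_time = out_t)
    t_prev <- out_t
  }
  trials <- do.call(rbind, tr[!vapply(tr, is.null, logical(1))])
  if (is.null(trials) || nrow(trials) == 0)
    stop("no trials completed before truncation")
  # first movements are defined against the finished trace: a later trial's
  # stimulus-triggered bout may precede a slow background bout recorded
  # mid-walk for an unanswered trial
  iv <- bout_intervals(bouts, fs)
  trials$first_move <- next_movement(iv$onsets, trials$stim_onset)
  trials$rt <- trials$first_move - trials$stim_onset
  t_end <- min(horizon, max(c(trials$outcome_time, trials$stim_onset,
                              trials$first_move), na.rm = TRUE) + 2)
  bouts <- bouts[bouts$onset < t_end, , drop = FALSE]
  if (nrow(bouts) > 0)   # keep every retained bout fully inside the trace
    t_end <- min(horizon, max(t_end, max(bouts$onset + bouts$duration) + 0.1))
  wheel <- bouts_to_trace(bouts, t_end, fs)
  structure(list(trials = trials, wheel = wheel, bouts = bouts, grid = grid,
                 regime = regime, move_floor = move_floor,
                 truncated = truncated, mouse = mouse, day = day,
                 fs = fs),
            class = "vm_session")
}

#' @export
print.vm_session <- function(x, ...) {
  cat(sprintf("<vm_session> mouse %s day %s: %d trials, %.0f s, %s regime\n",
              x$mouse, x$day, nrow(x$trials), x$wheel$duration,
              x$regime$mode))
  cat(sprintf("  outcomes: %s\n",
              paste(names(table(x$trials$outcome)),
                    table(x$trials$outcome), sep = "=", collapse = " ")))
  invisible(x)
}

# Movement intervals of a session, derived from the stored bout table
# (identical to threshold detection on the trace by construction).
session_intervals <- function(session) {
  bout_intervals(session$bouts, session$fs)
}
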