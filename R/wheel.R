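#' Delay-parameter grid for the wheel task
#'
#' The task separates consecutive stimuli by two independently drawn delays:
#' a fixed inter-trial interval (ITI) counted from the previous trial's
#' outcome, and an enforced quiescence period whose timer restarts whenever
#' the wheel moves. Both delays are drawn uniformly from a discrete grid in
#' fixed increments (100 ms in the trained task configuration).
#'
#' @param iti length-2 numeric, min/max of the ITI range in seconds.
#' @param quiescence length-2 numeric, min/max of the quiescence range in
#'   seconds.
#' @param increment grid step in seconds (default 0.1).
#' @return An object of class `vm_delay_grid` with elements `iti_values` and
#'   `quiescence_values` (the full discrete supports) plus the arguments.
#' @examples
#' g <- delay_grid(c(4, 7), c(0.5, 2))
#' length(g$iti_values) * length(g$quiescence_values)  # combinations per trial
#' @export
delay_grid <- function(iti = c(4, 7), quiescence = c(0.5, 2), increment = 0.1) {
  stopifnot(length(iti) == 2, length(quiescence) == 2, increment > 0)
  if (iti[1] > iti[2] || quiescence[1] > quiescence[2])
    stop("delay range minimum exceeds maximum")
  chk <- function(r) {
    k <- (r[2] - r[1]) / increment
    if (abs(k - round(k)) > 1e-8)
      stop("delay range is not an integer multiple of the increment")
  }
  chk(iti); chk(quiescence)
  g <- list(
    iti = iti, quiescence = quiescence, increment = increment,
    iti_values = round(seq(iti[1], iti[2], by = increment), 10),
    quiescence_values = round(seq(quiescence[1], quiescence[2], by = increment), 10)
  )
  class(g) <- "vm_delay_grid"
  g
}

#' Behavioral regime for synthetic sessions
#'
#' Describes how a simulated mouse moves the wheel. In `"null"` mode,
#' movement bouts form a Poisson process unrelated to stimuli. In
#' `"associated"` mode a stimulus-triggered bout is added after each answered
#' stimulus at a latency drawn from a shifted log-normal distribution, whose
#' mode defaults to 150 ms to mimic a trained animal.
#'
#' @param mode `"null"` or `"associated"`.
#' @param bout_rate background bout rate, bouts/second.
#' @param bout_duration length-2 numeric, min/max bout duration in seconds.
#' @param bout_amplitude length-2 numeric, min/max absolute wheel speed during
#'   a bout, degrees/second.
#' @param p_ccw probability that a background bout turns counterclockwise
#'   (the rewarded direction).
#' @param latency_shift,latency_meanlog,latency_sdlog shifted log-normal
#'   reaction-latency parameters (seconds); defaults place the mode at
#'   ~150 ms.
#' @param response_probability fraction of stimuli answered with a triggered
#'   bout in `"associated"` mode.
#' @return An object of class `vm_regime`.
#' @export
behavior_regime <- function(mode = c("null", "associated"),
                            bout_rate = 0.35,
                            bout_duration = c(0.2, 0.4),
                            bout_amplitude = c(300, 600),
                            p_ccw = 0.85,
                            latency_shift = 0.05,
                            latency_meanlog = log(0.11),
                            latency_sdlog = 0.3,
                            response_probability = 0.9) {
  mode <- match.arg(mode)
  if (bout_rate < 0) stop("bout_rate must be non-negative")
  if (any(bout_duration <= 0) || any(bout_amplitude <= 0))
    stop("bout durations and amplitudes must be positive")
  if (response_probability < 0 || response_probability > 1)
    stop("response_probability must lie in [0, 1]")
  lat_mode <- latency_shift + exp(latency_meanlog - latency_sdlog^2)
  if (lat_mode < 0 || lat_mode > 2)
    stop("latency mode must lie within [0, 2] s")
  structure(list(mode = mode, bout_rate = bout_rate,
                 bout_duration = bout_duration,
                 bout_amplitude = bout_amplitude, p_ccw = p_ccw,
                 latency_shift = latency_shift,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 response_probability = response_probability),
            class = "vm_regime")
}

# Draw a background Matern-thinned bout table over [0, duration].
# Bouts are boxcar velocity pulses; thinning enforces a >= 2-sample gap so
# threshold detection on the synthesized trace recovers exactly these
# intervals.
draw_bouts <- function(regime, duration, fs) {
  dt <- 1 / fs
  n <- stats::rpois(1, regime$bout_rate * duration)
  if (n == 0)
    return(data.frame(onset = numeric(), duration = numeric(),
                      amplitude = numeric()))
  onset <- round(sort(stats::runif(n, 0, duration)) * fs) / fs
  dur <- pmax(1, round(stats::runif(n, regime$bout_duration[1],
                                    regime$bout_duration[2]) * fs)) / fs
  amp <- stats::runif(n, regime$bout_amplitude[1], regime$bout_amplitude[2])
  sgn <- ifelse(stats::runif(n) < regime$p_ccw, -1, 1)
  keep <- logical(n)
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (onset[i] >= last_end + 2 * dt) {
      keep[i] <- TRUE
      last_end <- onset[i] + dur[i]
    }
  }
  data.frame(onset = onset[keep], duration = dur[keep],
             amplitude = (amp * sgn)[keep])
}

draw_latency <- function(regime, n = 1) {
  regime$latency_shift +
    stats::rlnorm(n, regime$latency_meanlog, regime$latency_sdlog)
}

# Movement-interval view of a bout table: onset = first moving sample,
# offset = last moving sample (boxcar pulses occupy [onset, onset+dur-dt]).
bout_intervals <- function(bouts, fs) {
  if (nrow(bouts) == 0)
    return(list(onsets = numeric(), offsets = numeric()))
  o <- bouts$onset
  f <- bouts$onset + bouts$duration - 1 / fs
  ord <- order(o)
  list(onsets = o[ord], offsets = f[ord])
}

# Synthesize velocity/position traces from a bout table.
bouts_to_trace <- function(bouts, duration, fs) {
  nt <- floor(duration * fs) + 1L
  t <- (seq_len(nt) - 1L) / fs
  v <- numeric(nt)
  if (nrow(bouts) > 0) {
    i0 <- pmax(1L, round(bouts$onset * fs) + 1L)
    i1 <- pmin(nt, round((bouts$onset + bouts$duration) * fs))
    for (k in seq_len(nrow(bouts))) {
      if (i0[k] <= i1[k]) v[i0[k]:i1[k]] <- v[i0[k]:i1[k]] + bouts$amplitude[k]
    }
  }
  pos <- cumsum(v) / fs
  structure(list(t = t, position = pos, velocity = v, fs = fs,
                 duration = duration),
            class = "vm_wheel")
}

#' Detect movement intervals on a wheel trace
#'
#' A sample is "moving" when `|velocity| > floor`. Returns run boundaries as
#' times of the first and last moving sample of each run.
#'
#' @param wheel a `vm_wheel` object (fields `t`, `velocity`, `fs`).
#' @param floor velocity detection floor, same units as `velocity`
#'   (default 1).
#' @return list with numeric vectors `onsets` and `offsets` (seconds).
#' @export
movement_intervals <- function(wheel, floor = 1) {
  mv <- abs(wheel$velocity) > floor
  if (!any(mv)) return(list(onsets = numeric(), offsets = numeric()))
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  list(onsets = wheel$t[on], offsets = wheel$t[off])
}

# Vectorized replay of the ITI + resetting-quiescence timer against a fixed
# set of movement intervals. `t0` is the quiescence-timer start (previous
# outcome + ITI). A movement event exactly at timer completion resets the
# timer (strict inequality). Returns stimulus onset times, NA where the timer
# never completes before t_max.
replay_core <- function(onsets, offsets, t0, quiescence, t_max = Inf) {
  eps <- 1e-9
  n <- max(length(t0), length(quiescence))
  t0 <- rep_len(t0, n)
  q <- rep_len(quiescence, n)
  v <- rep(NA_real_, n)
  s <- t0
  active <- rep(TRUE, n)
  K <- length(onsets)
  iter <- 0L
  while (any(active) && iter <= K + 2L) {
    iter <- iter + 1L
    idx <- which(active)
    si <- s[idx]
    if (K > 0) {
      j <- findInterval(si + eps, onsets)           # last onset <= si
      ins <- j >= 1L & si < offsets[pmax(j, 1L)] - eps
      si[ins] <- offsets[j[ins]]                    # ride out the bout
      jn <- findInterval(si + eps, onsets)
      nxt <- ifelse(jn < K, onsets[jn + 1L], Inf)
    } else {
      nxt <- rep(Inf, length(si))
      jn <- integer(length(si))
    }
    done <- si + q[idx] < nxt - eps
    v[idx[done]] <- si[done] + q[idx[done]]
    if (any(!done)) s[idx[!done]] <- offsets[jn[!done] + 1L]
    active[idx[done]] <- FALSE
    if (K == 0) break
  }
  v[!is.na(v) & v > t_max + eps] <- NA_real_
  v
}

#' Replay the trial timer logic against a fixed wheel trace
#'
#' Deterministically reproduces the stimulus onset the task program would
#' have generated for given delay parameters: the ITI runs from
#' `prev_outcome_time`, after which a quiescence timer must elapse with no
#' wheel movement, restarting at every movement sample.
#'
#' @param wheel a `vm_wheel` trace, or a list with `onsets`/`offsets`
#'   movement intervals (seconds).
#' @param prev_outcome_time outcome time of the previous trial, seconds.
#' @param iti inter-trial interval, seconds (may be a vector).
#' @param quiescence quiescence requirement, seconds (may be a vector,
#'   recycled against `iti`).
#' @param t_max latest admissible onset; later completions return `NA`.
#' @param move_floor velocity floor for movement detection when `wheel` is a
#'   trace.
#' @return stimulus onset time(s) in seconds, `NA` where the quiescence
#'   timer never completes.
#' @export
replay_stimulus_time <- function(wheel, prev_outcome_time, iti, quiescence,
                                 t_max = Inf, move_floor = 1) {
  iv <- if (!is.null(wheel$onsets)) wheel else movement_intervals(wheel, move_floor)
  replay_core(iv$onsets, iv$offsets, prev_outcome_time + iti, quiescence,
              t_max)
}

# First movement event strictly after time v: bout onsets are the only
# events reachable from a completed quiescence period.
next_movement <- function(onsets, v) {
  j <- findInterval(v + 1e-9, onsets)
  ifelse(j < length(onsets), onsets[j + 1L], NA_real_)
}

# First time after `from` at which cumulative displacement crosses thr_ccw
# (negative, reward) or thr_cw (positive, punish), scanning boxcar bouts
# analytically. Returns list(time, outcome).
first_crossing <- function(bouts, from, thr_ccw, thr_cw, t_max) {
  disp <- 0
  if (nrow(bouts) > 0) {
    ord <- order(bouts$onset)
    for (k in ord) {
      on <- bouts$onset[k]; du <- bouts$duration[k]; a <- bouts$amplitude[k]
      if (on + du <= from) next
      if (on >= t_max) break
      seg0 <- max(on, from)
      seg1 <- min(on + du, t_max)
      if (seg1 <= seg0) next
      d_end <- disp + a * (seg1 - seg0)
      # crossing within this segment?
      for (thr in list(c(thr_ccw, "reward"), c(thr_cw, "punish"))) {
        th <- as.numeric(thr[1])
        hit <- if (th < 0) (disp > th && d_end <= th) else (disp < th && d_end >= th)
        if (hit) {
          tc <- seg0 + (th - disp) / a
          return(list(time = tc, outcome = thr[2]))
        }
      }
      disp <- d_end
    }
  }
  list(time = t_max, outcome = "none")
}
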