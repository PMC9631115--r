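#' Delay-period movement epochs of a session
#'
#' Finds wheel-movement bouts occurring outside any stimulus-to-outcome
#' window that would have been rewarded had a stimulus been present:
#' counterclockwise bouts whose displacement reaches the reward threshold
#' without first reaching the punish threshold. These movement-without-
#' stimulus epochs identify the bilateral movement gain ratio for
#' hemisphere subtraction.
#'
#' @param session a `vm_session`.
#' @param reward_threshold,punish_threshold signed displacement thresholds,
#'   degrees (defaults match [simulate_session()]).
#' @param pad seconds around each stimulus-to-outcome window to exclude.
#' @return data.frame with `onset` (seconds) and `day`.
#' @export
delay_movement_epochs <- function(session, reward_threshold = -90,
                                  punish_threshold = 90, pad = 0.5) {
  b <- session$bouts
  tr <- session$trials
  if (nrow(b) == 0) return(data.frame(onset = numeric(), day = integer()))
  in_trial <- vapply(b$onset, function(o)
    any(o >= tr$stim_onset - pad & o <= tr$outcome_time + pad, na.rm = TRUE),
    logical(1))
  disp <- b$amplitude * b$duration
  rewarded <- disp <= reward_threshold        # counterclockwise = negative
  data.frame(onset = b$onset[!in_trial & rewarded],
             day = rep(if (is.null(session$day)) 1L else session$day,
                       sum(!in_trial & rewarded)))
}

#' Event-triggered average of a trace
#'
#' @param trace numeric vector sampled at `fs` starting at time 0.
#' @param fs sampling rate, Hz.
#' @param onsets event times, seconds.
#' @param window `c(pre, post)` seconds around each event.
#' @return list with `time` (seconds relative to event), `mean`, `n_events`.
#' @export
event_triggered_average <- function(trace, fs, onsets, window = c(-0.5, 1)) {
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  keep <- !is.na(onsets)
  snips <- lapply(onsets[keep], function(o) {
    idx <- round(o * fs) + 1L + rel
    if (any(idx < 1L | idx > length(trace))) return(NULL)
    trace[idx]
  })
  snips <- snips[!vapply(snips, is.null, logical(1))]
  if (length(snips) == 0) stop("no events fall inside the trace")
  list(time = rel / fs, mean = Reduce(`+`, snips) / length(snips),
       n_events = length(snips))
}
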