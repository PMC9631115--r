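#' Reaction times of a session
#'
#' Reaction time is the interval from stimulus onset to the next wheel
#' movement. Trials whose stimulus was never followed by a movement carry no
#' reaction time and are dropped (their count is reported). Reaction times
#' below `rt_floor` are kept but masked: they are excluded from the test
#' statistic as likely coincidental timing.
#'
#' @param session a `vm_session` (or any list with a `trials` data.frame
#'   holding `stim_onset` and `first_move`).
#' @param rt_floor exclusion floor in seconds (default 0.1).
#' @return list with `rt` (seconds, one per trial with a movement), `masked`
#'   (logical, `rt < rt_floor`), `trial_index`, and `n_dropped`.
#' @export
compute_reaction_times <- function(session, rt_floor = 0.1) {
  tr <- session$trials
  has_move <- !is.na(tr$first_move)
  rt <- tr$first_move[has_move] - tr$stim_onset[has_move]
  list(rt = rt, masked = rt < rt_floor - 1e-12,
       trial_index = tr$index[has_move], n_dropped = sum(!has_move),
       rt_floor = rt_floor)
}

median_with_floor <- function(rt, rt_floor) {
  keep <- rt >= rt_floor - 1e-12
  if (!any(keep)) return(NA_real_)
  stats::median(rt[keep])
}

#' Enumerate the exact conditional support of each trial's reaction time
#'
#' For every trial with an observed post-stimulus movement, enumerates all
#' delay-grid combinations, replays the ITI + resetting-quiescence timer
#' against the session's wheel trace, and accepts combinations for which the
#' first movement after the replayed stimulus onset equals the observed
#' movement time. Under the null hypothesis that movements are unrelated to
#' stimuli, the trial's delay parameters are uniform over this acceptance
#' set, so the accepted replayed reaction times are the trial's exact
#' conditional reaction-time distribution.
#'
#' @param session a `vm_session`.
#' @param rt_floor stored for downstream statistics (seconds).
#' @param max_combos guard against unenumerable grids.
#' @return class `vm_cond_support`: `trial_rts` (list of numeric acceptance
#'   RT sets), `trial_index`, `acceptance_rate` per trial, `n_combos`,
#'   `rt_floor`.
#' @export
exact_conditional_null <- function(session, rt_floor = 0.1,
                                   max_combos = 10000) {
  grid <- session$grid
  combos <- expand.grid(iti = grid$iti_values, qui = grid$quiescence_values)
  if (nrow(combos) > max_combos)
    stop("delay grid too large to enumerate (", nrow(combos), " combinations)")
  iv <- session_intervals(session)
  tr <- session$trials
  use <- which(!is.na(tr$first_move))
  rts <- vector("list", length(use))
  acc <- numeric(length(use))
  for (k in seq_along(use)) {
    i <- use[k]
    v <- replay_core(iv$onsets, iv$offsets,
                     tr$prev_outcome_time[i] + combos$iti,
                     combos$qui)
    nm <- next_movement(iv$onsets, v)
    ok <- !is.na(v) & !is.na(nm) & abs(nm - tr$first_move[i]) < 1e-9
    if (!any(ok))
      stop("empty conditional support at trial ", i,
           ": session is not self-consistent")
    # the observed parameters always satisfy their own condition
    rts[[k]] <- tr$first_move[i] - v[ok]
    acc[k] <- mean(ok)
  }
  structure(list(trial_rts = rts, trial_index = tr$index[use],
                 acceptance_rate = acc, n_combos = nrow(combos),
                 rt_floor = rt_floor, grid = grid),
            class = "vm_cond_support")
}

#' Conditional null distribution of the median reaction time
#'
#' Builds the randomization null for the reaction-time test: per resample,
#' each trial's delay parameters are redrawn uniformly on the grid subject to
#' the condition that the movement time detected with the new delays equals
#' the observed one, and the median reaction time (with the `rt_floor`
#' exclusion) is recorded. Default 10,000 resamples.
#'
#' Two equivalent samplers are provided. `"enumeration"` enumerates each
#' trial's acceptance set once and samples from it. `"rejection"` proposes
#' delay pairs until acceptance, falling back to enumeration for any trial
#' whose acceptance rate makes proposals exceed `cap` per accepted draw.
#'
#' @param session a `vm_session`.
#' @param n_resamples number of null medians (default 10000).
#' @param seed RNG seed.
#' @param rt_floor exclusion floor, seconds.
#' @param method `"enumeration"` or `"rejection"`.
#' @param cap proposal budget per accepted draw before the rejection sampler
#'   falls back to enumeration for that trial.
#' @param support optional precomputed [exact_conditional_null()] result.
#' @return class `vm_null`: `medians`, `n_resamples`, `method`,
#'   `acceptance_rate` per trial, `rt_floor`.
#' @export
conditional_null <- function(session, n_resamples = 10000, seed = 1,
                             rt_floor = 0.1,
                             method = c("enumeration", "rejection"),
                             cap = 1000, support = NULL) {
  method <- match.arg(method)
  if (n_resamples < 1) stop("n_resamples must be at least 1")
  set.seed(seed)
  if (method == "enumeration") {
    if (is.null(support))
      support <- exact_conditional_null(session, rt_floor)
    draws <- vapply(support$trial_rts, function(r)
      r[sample.int(length(r), n_resamples, replace = TRUE)],
      numeric(n_resamples))
    acc <- support$acceptance_rate
  } else {
    draws <- rejection_draws(session, n_resamples, cap)
    acc <- attr(draws, "acceptance_rate")
  }
  draws <- matrix(draws, nrow = n_resamples)
  medians <- apply(draws, 1, median_with_floor, rt_floor = rt_floor)
  structure(list(medians = medians, n_resamples = n_resamples,
                 method = method, acceptance_rate = acc,
                 rt_floor = rt_floor),
            class = "vm_null")
}

# Per-trial rejection sampling of conditional reaction times. Proposals are
# drawn in batches; if a trial's empirical acceptance implies more than
# `cap` proposals per accepted draw, the trial's acceptance set is
# enumerated instead (exactness preserved).
rejection_draws <- function(session, n_resamples, cap) {
  grid <- session$grid
  iv <- session_intervals(session)
  tr <- session$trials
  use <- which(!is.na(tr$first_move))
  out <- matrix(NA_real_, n_resamples, length(use))
  acc <- numeric(length(use))
  for (k in seq_along(use)) {
    i <- use[k]
    got <- numeric(0)
    proposed <- 0L
    accepted <- 0L
    while (length(got) < n_resamples && proposed < cap * n_resamples) {
      b <- min(4L * n_resamples, cap * n_resamples - proposed)
      iti <- grid$iti_values[sample.int(length(grid$iti_values), b,
                                        replace = TRUE)]
      qui <- grid$quiescence_values[
        sample.int(length(grid$quiescence_values), b, replace = TRUE)]
      v <- replay_core(iv$onsets, iv$offsets, tr$prev_outcome_time[i] + iti,
                       qui)
      nm <- next_movement(iv$onsets, v)
      ok <- !is.na(v) & !is.na(nm) & abs(nm - tr$first_move[i]) < 1e-9
      got <- c(got, (tr$first_move[i] - v)[ok])
      proposed <- proposed + b
      accepted <- accepted + sum(ok)
    }
    if (length(got) < n_resamples) {
      sup <- trial_support(session, i, iv)
      got <- c(got, sup[sample.int(length(sup),
                                   n_resamples - length(got),
                                   replace = TRUE)])
    }
    out[, k] <- got[seq_len(n_resamples)]
    acc[k] <- if (proposed > 0) accepted / proposed else NA_real_
  }
  attr(out, "acceptance_rate") <- acc
  out
}

trial_support <- function(session, i, iv = session_intervals(session)) {
  grid <- session$grid
  combos <- expand.grid(iti = grid$iti_values, qui = grid$quiescence_values)
  tr <- session$trials
  v <- replay_core(iv$onsets, iv$offsets,
                   tr$prev_outcome_time[i] + combos$iti, combos$qui)
  nm <- next_movement(iv$onsets, v)
  ok <- !is.na(v) & !is.na(nm) & abs(nm - tr$first_move[i]) < 1e-9
  if (!any(ok)) stop("empty conditional support at trial ", i)
  tr$first_move[i] - v[ok]
}

#' Conditional-randomization test of stimulus-movement association
#'
#' Tests whether reaction times are faster than expected if wheel movements
#' were unrelated to stimulus onsets, accounting for the movement rate. The
#' test statistic is the median reaction time (excluding values below
#' `rt_floor`); the null is the conditional randomization distribution of
#' that median. The one-sided lower-tail p-value uses the add-one
#' permutation correction, with ties counted toward the null tail.
#'
#' @inheritParams conditional_null
#' @param alpha significance level (default 0.05).
#' @param min_trials minimum unmasked reaction times required; below this
#'   the p-value is reported as `NA`.
#' @param two_sided set `TRUE` for a two-sided alternative (off by default:
#'   the scientific question is "faster than chance").
#' @return class `vm_assoc`: `p_value`, `observed_median`, `chance_median`,
#'   `performance_index`, `significant`, `n_used`, `n_dropped`, `null`.
#' @export
test_association <- function(session, n_resamples = 10000, seed = 1,
                             alpha = 0.05, rt_floor = 0.1,
                             method = c("enumeration", "rejection"),
                             min_trials = 10, two_sided = FALSE,
                             support = NULL) {
  method <- match.arg(method)
  rts <- compute_reaction_times(session, rt_floor)
  obs <- median_with_floor(rts$rt, rt_floor)
  n_used <- sum(!rts$masked)
  nul <- conditional_null(session, n_resamples, seed, rt_floor, method,
                          support = support)
  med <- nul$medians[!is.na(nul$medians)]
  if (n_used < min_trials || is.na(obs) || length(med) == 0) {
    p <- NA_real_
  } else {
    lo <- (1 + sum(med <= obs + 1e-12)) / (1 + length(med))
    if (two_sided) {
      hi <- (1 + sum(med >= obs - 1e-12)) / (1 + length(med))
      p <- min(1, 2 * min(lo, hi))
    } else p <- lo
  }
  chance <- stats::median(med)
  structure(list(p_value = p, observed_median = obs, chance_median = chance,
                 performance_index = performance_index(obs, chance),
                 significant = !is.na(p) && p < alpha, alpha = alpha,
                 n_used = n_used, n_dropped = rts$n_dropped, null = nul),
            class = "vm_assoc")
}

#' @export
print.vm_assoc <- function(x, ...) {
  cat(sprintf(
    "<vm_assoc> p = %s, observed median RT = %.3f s, chance = %.3f s, index = %.3f\n",
    format(x$p_value, digits = 3), x$observed_median, x$chance_median,
    x$performance_index))
  invisible(x)
}

#' First day of significant association
#'
#' @param p_values per-day p-values in training order.
#' @param alpha threshold (default 0.05).
#' @return 1-based index of the first day with `p < alpha`, or `NA_integer_`.
#' @export
association_day <- function(p_values, alpha = 0.05) {
  hit <- which(!is.na(p_values) & p_values < alpha)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Task performance index
#'
#' Difference divided by sum of chance and observed median reaction times;
#' positive values mean reaction times shorter than chance, bounded in
#' \[-1, 1\].
#'
#' @param observed_median,chance_median medians in seconds (both positive).
#' @return numeric index.
#' @export
performance_index <- function(observed_median, chance_median) {
  if (is.na(observed_median) || is.na(chance_median)) return(NA_real_)
  if (observed_median < 0 || chance_median < 0)
    stop("medians must be positive")
  (chance_median - observed_median) / (observed_median + chance_median)
}

#' Split trials into contiguous thirds
#'
#' Order-preserving contiguous groups with sizes differing by at most one;
#' when the count is not divisible by three, earlier groups take the extra
#' trials.
#'
#' @param trials a vector of trial identifiers (or a trial count).
#' @return list of three vectors.
#' @export
split_thirds <- function(trials) {
  if (length(trials) == 1 && is.numeric(trials)) trials <- seq_len(trials)
  n <- length(trials)
  if (n < 3) stop("need at least 3 trials")
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, ends[-3] + 1)
  lapply(1:3, function(i) trials[starts[i]:ends[i]])
}
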