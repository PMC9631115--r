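#' Ground truth for a synthetic spike-sorted unit
#'
#' @param base_rate uncontaminated firing rate, Hz.
#' @param f_p_true contamination fraction: expected fraction of spikes
#'   contributed by a uniform (Poisson) contaminating process.
#' @param amp_mean,amp_sd Gaussian spike-amplitude distribution (a.u.).
#' @param detection_floor amplitudes below this are lost (drift/threshold
#'   truncation); `-Inf` disables.
#' @param refractory true refractory period of the base process, seconds.
#' @param trough_to_peak_us template trough-to-peak duration, microseconds.
#' @param decay_slope planted per-channel amplitude decay slope (amplitude
#'   units per channel spacing).
#' @return list of class `vm_unit_truth`.
#' @export
unit_truth <- function(base_rate = 5, f_p_true = 0, amp_mean = 50,
                       amp_sd = 10, detection_floor = -Inf,
                       refractory = 0.002, trough_to_peak_us = 400,
                       decay_slope = -5) {
  if (f_p_true < 0 || f_p_true >= 1) stop("f_p_true must lie in [0, 1)")
  if (refractory <= 0) stop("refractory period must be positive")
  structure(list(base_rate = base_rate, f_p_true = f_p_true,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 detection_floor = detection_floor,
                 refractory = refractory,
                 trough_to_peak_us = trough_to_peak_us,
                 decay_slope = decay_slope),
            class = "vm_unit_truth")
}

#' Parametric template waveform
#'
#' One negative trough followed by one positive peak (Gaussian lobes), the
#' canonical somatic extracellular shape.
#'
#' @param fs_wave waveform sampling rate, Hz (default 30 kHz).
#' @param trough_to_peak_us trough-to-peak duration, microseconds.
#' @param trough_amp,peak_amp lobe amplitudes (trough is negated).
#' @param trough_width_us,peak_width_us Gaussian lobe widths, microseconds
#'   (scaled down automatically for very fast waveforms so the lobes stay
#'   separable).
#' @param n_samples waveform length.
#' @return numeric waveform.
#' @export
template_waveform <- function(fs_wave = 30000, trough_to_peak_us = 400,
                              trough_amp = 60, peak_amp = 25,
                              trough_width_us = NULL, peak_width_us = NULL,
                              n_samples = 82) {
  if (is.null(trough_width_us))
    trough_width_us <- min(80, trough_to_peak_us / 2.5)
  if (is.null(peak_width_us))
    peak_width_us <- min(150, trough_to_peak_us / 1.6)
  t <- (seq_len(n_samples) - n_samples / 2) / fs_wave * 1e6  # microseconds
  -trough_amp * exp(-(t / trough_width_us)^2) +
    peak_amp * exp(-((t - trough_to_peak_us) / peak_width_us)^2)
}

#' Simulate spike-sorted units with known ground truth
#'
#' Spike times combine a refractory-respecting Poisson base process (dead
#' time = `refractory`) with a uniform contaminating Poisson process whose
#' rate is set so the expected contaminated fraction equals `f_p_true`.
#' Per-spike amplitudes are Gaussian; spikes with amplitude below
#' `detection_floor` are removed (amplitude truncation). Template waveforms
#' and a per-channel amplitude profile with the planted decay slope are
#' attached.
#'
#' @param truth a [unit_truth()].
#' @param duration recording duration, seconds.
#' @param n_units number of units to generate.
#' @param seed RNG seed.
#' @param n_channels channels in the amplitude profile.
#' @param fs_wave waveform sampling rate, Hz.
#' @return list of `vm_unit` objects, each with `spike_times`, `amplitudes`,
#'   `waveform`, `fs_wave`, `channel_amplitudes`, `channel_positions` (in
#'   channel-spacing units), `is_contaminant` (ground-truth labels),
#'   `truth`.
#' @export
simulate_units <- function(truth = unit_truth(), duration = 600,
                           n_units = 1, seed = 1, n_channels = 12,
                           fs_wave = 30000) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  lapply(seq_len(n_units), function(u) {
    base <- poisson_refractory(truth$base_rate, duration, truth$refractory)
    contam_rate <- truth$base_rate * truth$f_p_true / (1 - truth$f_p_true)
    n_c <- stats::rpois(1, contam_rate * duration)
    contam <- sort(stats::runif(n_c, 0, duration))
    times <- c(base, contam)
    lab <- c(rep(FALSE, length(base)), rep(TRUE, n_c))
    ord <- order(times)
    times <- times[ord]; lab <- lab[ord]
    amps <- stats::rnorm(length(times), truth$amp_mean, truth$amp_sd)
    keep <- amps >= truth$detection_floor
    wf <- template_waveform(fs_wave, truth$trough_to_peak_us,
                            trough_amp = truth$amp_mean * 1.2,
                            peak_amp = truth$amp_mean * 0.5)
    pos <- seq_len(n_channels) - 1
    ch_amp <- pmax(truth$amp_mean * 1.2 + truth$decay_slope * pos, 1)
    structure(list(spike_times = times[keep], amplitudes = amps[keep],
                   is_contaminant = lab[keep], waveform = wf,
                   fs_wave = fs_wave, channel_amplitudes = ch_amp,
                   channel_positions = pos, duration = duration,
                   truth = truth),
              class = "vm_unit")
  })
}

# Dead-time (refractory) renewal process with EXACT target rate: gaps are
# refractory + Exp(hazard) with hazard chosen so the mean gap is 1/rate.
poisson_refractory <- function(rate, duration, refractory) {
  if (rate <= 0) return(numeric(0))
  if (rate * refractory >= 1)
    stop("rate is incompatible with the refractory period")
  hazard <- rate / (1 - rate * refractory)
  n_guess <- ceiling(rate * duration * 1.5) + 20
  gaps <- refractory + stats::rexp(n_guess, hazard)
  tt <- cumsum(gaps)
  while (tt[length(tt)] < duration) {
    gaps <- refractory + stats::rexp(n_guess, hazard)
    tt <- c(tt, tt[length(tt)] + cumsum(gaps))
  }
  tt[tt <= duration]
}

#' Default unit quality-control parameters
#'
#' Seven criteria: somatic waveform shape; spatial-decay slope above a
#' floor; trough-to-peak duration within bounds; quiet waveform baseline;
#' missing-spike fraction below a cap; minimum spike count; and refractory
#' contamination below a cap.
#'
#' @param tau_r refractory period, seconds (default 0.002).
#' @param tau_c censored period, seconds (default 0.0001).
#' @param min_spikes minimum spike count (default 300).
#' @param duration_bounds_us trough-to-peak bounds, microseconds.
#' @param baseline_amp_frac maximum baseline/maximum amplitude ratio.
#' @param max_missing maximum estimated missing-spike fraction.
#' @param max_contamination maximum refractory contamination `F_p`.
#' @param decay_slope_floor minimum spatial-decay slope (amplitude per
#'   channel spacing; the printed threshold is unitless, so the scale of
#'   `channel_positions` defines the units).
#' @param baseline_frac_window fraction of waveform samples (from the start)
#'   treated as baseline.
#' @param peak_prominence_frac prominence threshold for peak/trough
#'   counting, as a fraction of the trough amplitude.
#' @return list of class `vm_qc_params`.
#' @export
qc_params <- function(tau_r = 0.002, tau_c = 0.0001, min_spikes = 300,
                      duration_bounds_us = c(100, 800),
                      baseline_amp_frac = 0.30, max_missing = 0.20,
                      max_contamination = 0.10, decay_slope_floor = -20,
                      baseline_frac_window = 0.2,
                      peak_prominence_frac = 0.1) {
  stopifnot(tau_r > tau_c, tau_c >= 0,
            baseline_amp_frac >= 0, baseline_amp_frac <= 1,
            max_missing >= 0, max_missing <= 1,
            max_contamination >= 0, max_contamination <= 1)
  structure(as.list(environment()), class = "vm_qc_params")
}

#' Waveform shape criteria
#'
#' Checks (i) at most one trough and two peaks with the trough preceding
#' and larger than the main peak, (ii) trough-to-peak duration within
#' bounds, and (iii) baseline amplitude below a fraction of the maximum.
#' Peaks/troughs are counted with a prominence threshold (default 10% of
#' the trough amplitude).
#'
#' @param waveform numeric waveform on the peak channel.
#' @param fs_wave waveform sampling rate, Hz.
#' @param params a [qc_params()].
#' @return list with `pass_shape`, `pass_duration`, `pass_baseline`,
#'   `trough_to_peak_us`, `baseline_frac`, `n_troughs`, `n_peaks`,
#'   `reason` (on failure).
#' @export
qc_waveform_shape <- function(waveform, fs_wave, params = qc_params()) {
  if (stats::sd(waveform) < .Machine$double.eps)
    return(list(pass_shape = FALSE, pass_duration = FALSE,
                pass_baseline = FALSE, trough_to_peak_us = NA_real_,
                baseline_frac = NA_real_, n_troughs = 0L, n_peaks = 0L,
                reason = "flat waveform"))
  trough_amp <- max(-waveform)
  prom <- params$peak_prominence_frac * trough_amp
  pk <- pracma::findpeaks(waveform, minpeakheight = prom, zero = "+")
  tr <- pracma::findpeaks(-waveform, minpeakheight = prom, zero = "+")
  n_peaks <- if (is.null(pk)) 0L else nrow(pk)
  n_troughs <- if (is.null(tr)) 0L else nrow(tr)
  trough_idx <- which.min(waveform)
  after <- waveform[seq(trough_idx, length(waveform))]
  peak_rel <- which.max(after)
  ttp_us <- (peak_rel - 1) / fs_wave * 1e6
  main_peak <- max(after)
  shape_ok <- n_troughs == 1L && n_peaks <= 2L && main_peak > 0 &&
    trough_amp > main_peak
  # also reject a dominant peak preceding the trough
  if (trough_idx > 1 && max(waveform[seq_len(trough_idx - 1)]) > main_peak)
    shape_ok <- FALSE
  nb <- max(1L, floor(params$baseline_frac_window * length(waveform)))
  baseline_frac <- max(abs(waveform[seq_len(nb)])) / max(abs(waveform))
  list(pass_shape = shape_ok,
       pass_duration = ttp_us > params$duration_bounds_us[1] &&
         ttp_us < params$duration_bounds_us[2],
       pass_baseline = baseline_frac < params$baseline_amp_frac,
       trough_to_peak_us = ttp_us, baseline_frac = baseline_frac,
       n_troughs = n_troughs, n_peaks = n_peaks,
       reason = if (shape_ok) NA_character_ else "shape criterion failed")
}

#' Spatial-decay slope criterion
#'
#' Linear fit of per-channel maximum waveform amplitude against distance
#' from the peak channel. The criterion passes when the fitted slope is
#' above (greater than) the configured floor, eliminating non-localized
#' units. The printed threshold is unitless; here the slope is expressed in
#' amplitude units per channel spacing, so `channel_distances` should be in
#' channel-spacing units to use the default floor.
#'
#' @param channel_amplitudes per-channel maximum waveform amplitude.
#' @param channel_distances distance of each channel from the peak channel
#'   (channel-spacing units by convention; defines the slope units).
#' @param params a [qc_params()].
#' @param indeterminate_pass value returned for `pass` with fewer than 3
#'   channels.
#' @return list with `pass`, `slope`.
#' @export
qc_spatial_decay <- function(channel_amplitudes, channel_distances,
                             params = qc_params(),
                             indeterminate_pass = TRUE) {
  if (length(channel_amplitudes) != length(channel_distances))
    stop("amplitude and distance vectors differ in length")
  if (length(channel_amplitudes) < 3)
    return(list(pass = indeterminate_pass, slope = NA_real_))
  slope <- stats::coef(stats::lm(channel_amplitudes ~ channel_distances))[2]
  list(pass = unname(slope) > params$decay_slope_floor,
       slope = unname(slope))
}

#' Missing-spike fraction from truncated amplitudes
#'
#' Fits a Gaussian to the spike-amplitude distribution truncated at the
#' detection floor (maximum likelihood on the truncated density) and
#' reports the fitted mass below the floor: the estimated fraction of
#' spikes lost to drift/thresholding.
#'
#' @param amplitudes observed spike amplitudes.
#' @param detection_floor truncation point; defaults to `min(amplitudes)`.
#' @return list with `fraction`, `mu`, `sigma`.
#' @export
estimate_missing_fraction <- function(amplitudes,
                                      detection_floor = min(amplitudes)) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 10) stop("too few amplitudes to fit")
  s0 <- stats::sd(amplitudes)
  if (s0 < .Machine$double.eps) {
    warning("degenerate amplitude distribution; missing fraction set to 0")
    return(list(fraction = 0, mu = mean(amplitudes), sigma = 0))
  }
  if (detection_floor <= min(amplitudes) - 5 * s0)
    return(list(fraction = 0, mu = mean(amplitudes), sigma = s0))
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    -sum(stats::dnorm(amplitudes, mu, sig, log = TRUE)) +
      length(amplitudes) *
        stats::pnorm(detection_floor, mu, sig, lower.tail = FALSE,
                     log.p = TRUE)
  }
  fit <- stats::optim(c(mean(amplitudes), log(s0)), nll,
                      method = "Nelder-Mead")
  mu <- fit$par[1]; sig <- exp(fit$par[2])
  list(fraction = stats::pnorm(detection_floor, mu, sig), mu = mu,
       sigma = sig)
}

#' Refractory-period contamination fraction
#'
#' Counts refractory violations `r` (spike pairs with inter-spike interval
#' in `(tau_c, tau_r]`) and inverts
#' `r = 2 (tau_r - tau_c) N^2 (1 - F_p) F_p / T` for the contamination
#' fraction `F_p`, taking the smaller quadratic root. When the observed `r`
#' exceeds the formula's maximum (negative discriminant), `F_p = 1` is
#' returned with `flagged = TRUE`.
#'
#' @param spike_times sorted spike times, seconds.
#' @param T total recording duration, seconds.
#' @param params a [qc_params()] (provides `tau_r`, `tau_c`).
#' @param all_pairs count all ordered pairs in the window (default) or only
#'   consecutive inter-spike intervals.
#' @return list with `f_p`, `r`, `n`, `flagged`.
#' @export
refractory_contamination <- function(spike_times, T, params = qc_params(),
                                     all_pairs = TRUE) {
  if (T <= 0) stop("duration must be positive")
  n <- length(spike_times)
  if (n < 2) {
    warning("fewer than 2 spikes; contamination set to 0")
    return(list(f_p = 0, r = 0L, n = n, flagged = FALSE))
  }
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  r <- count_isi_violations(spike_times, params$tau_c, params$tau_r,
                            all_pairs)
  cc <- r * T / (2 * (params$tau_r - params$tau_c) * n^2)
  disc <- 1 - 4 * cc
  if (disc < 0)
    return(list(f_p = 1, r = r, n = n, flagged = TRUE))
  list(f_p = (1 - sqrt(disc)) / 2, r = r, n = n, flagged = FALSE)
}

count_isi_violations <- function(st, tau_c, tau_r, all_pairs = TRUE) {
  if (!all_pairs) {
    d <- diff(st)
    return(sum(d > tau_c & d <= tau_r))
  }
  # pairs (i < j) with t_j - t_i in (tau_c, tau_r]
  hi <- findInterval(st + tau_r, st)
  lo <- findInterval(st + tau_c, st)
  sum(hi - lo)
}

#' Evaluate the printed violation formula at a contamination fraction
#' @param f_p contamination fraction.
#' @param n spike count.
#' @param T duration, seconds.
#' @param params a [qc_params()].
#' @return expected violation count `r`.
#' @export
expected_violations <- function(f_p, n, T, params = qc_params()) {
  2 * (params$tau_r - params$tau_c) * n^2 * (1 - f_p) * f_p / T
}

#' Classify a unit against all seven quality criteria
#'
#' @param unit a `vm_unit` (or list with `spike_times`, `amplitudes`,
#'   `waveform`, `fs_wave`, `channel_amplitudes`, `channel_positions`).
#' @param T recording duration, seconds (defaults to `unit$duration`).
#' @param params a [qc_params()].
#' @param detection_floor amplitude truncation point for the missingness
#'   fit; defaults to `min(amplitudes)`.
#' @return class `vm_qc`: per-criterion logicals (`shape`, `decay`,
#'   `duration`, `baseline`, `missing`, `count`, `contamination`), derived
#'   quantities (`trough_to_peak_us`, `decay_slope`, `missing_fraction`,
#'   `f_p`, `n_spikes`), and `pass` (their conjunction).
#' @export
classify_unit_quality <- function(unit, T = unit$duration,
                                  params = qc_params(),
                                  detection_floor = NULL) {
  need <- c("spike_times", "amplitudes", "waveform", "fs_wave",
            "channel_amplitudes", "channel_positions")
  missing_fields <- need[!need %in% names(unit)]
  if (length(missing_fields) > 0) {
    crit <- stats::setNames(rep(NA, 7),
                            c("shape", "decay", "duration", "baseline",
                              "missing", "count", "contamination"))
    return(structure(list(criteria = crit, pass = FALSE,
                          missing_fields = missing_fields),
                     class = "vm_qc"))
  }
  ws <- qc_waveform_shape(unit$waveform, unit$fs_wave, params)
  dist <- abs(unit$channel_positions -
              unit$channel_positions[which.max(unit$channel_amplitudes)])
  dec <- qc_spatial_decay(unit$channel_amplitudes, dist, params)
  n <- length(unit$spike_times)
  fl <- if (is.null(detection_floor)) min(unit$amplitudes) else detection_floor
  mf <- if (n >= 10) estimate_missing_fraction(unit$amplitudes, fl)
        else list(fraction = NA_real_)
  fp <- refractory_contamination(unit$spike_times, T, params)
  crit <- c(shape = ws$pass_shape, decay = dec$pass,
            duration = ws$pass_duration, baseline = ws$pass_baseline,
            missing = !is.na(mf$fraction) &&
              mf$fraction < params$max_missing,
            count = n >= params$min_spikes,
            contamination = !fp$flagged && fp$f_p < params$max_contamination)
  structure(list(criteria = crit, pass = all(crit),
                 trough_to_peak_us = ws$trough_to_peak_us,
                 baseline_frac = ws$baseline_frac,
                 decay_slope = dec$slope, missing_fraction = mf$fraction,
                 f_p = fp$f_p, r = fp$r, n_spikes = n),
            class = "vm_qc")
}

#' @export
print.vm_qc <- function(x, ...) {
  cat("<vm_qc>", if (x$pass) "PASS" else "FAIL", "-",
      paste(names(x$criteria)[!x$criteria | is.na(x$criteria)],
            collapse = " "), "\n")
  invisible(x)
}

#' Narrow/wide spiking classification
#'
#' Waveform-duration split into putative fast-spiking interneurons
#' (`"narrow"`) and putative excitatory neurons (`"wide"`). A duration
#' exactly at the threshold classifies as wide.
#'
#' @param trough_to_peak_us trough-to-peak duration(s), microseconds.
#' @param threshold_us boundary (default 400).
#' @return character vector, `"narrow"` or `"wide"`.
#' @export
classify_cell_type <- function(trough_to_peak_us, threshold_us = 400) {
  ifelse(trough_to_peak_us < threshold_us, "narrow", "wide")
}

#' Baseline-normalized multiunit rate traces
#'
#' `(FR - FR0) / (FR0 + s)` per area, where `FR0` is the area's mean
#' baseline rate and the softening constant `s` is the 10th percentile of
#' baseline rates pooled across all areas/recordings.
#'
#' @param rates list of numeric rate traces (or matrices), one per
#'   area/recording.
#' @param baselines list of baseline-rate samples matching `rates`.
#' @param soften_quantile pooled quantile used as the softener (default
#'   0.1).
#' @return list with `normalized` (same structure as `rates`), `baseline`
#'   per area, `soften`.
#' @export
normalize_multiunit <- function(rates, baselines, soften_quantile = 0.1) {
  if (length(rates) != length(baselines))
    stop("rates and baselines differ in length")
  pooled <- unlist(baselines)
  if (length(pooled) == 0) stop("empty baseline")
  s <- unname(stats::quantile(pooled, soften_quantile, type = 7))
  fr0 <- vapply(baselines, function(b) mean(unlist(b)), numeric(1))
  norm <- lapply(seq_along(rates), function(i)
    (rates[[i]] - fr0[i]) / (fr0[i] + s))
  list(normalized = norm, baseline = fr0, soften = s)
}

#' Within-trial shuffle test of event responsiveness
#'
#' Statistic: mean over trials of (response-window rate - baseline-window
#' rate). The null swaps the two windows' values independently within each
#' trial with probability 1/2 per shuffle, preserving trial identity.
#' Two-sided p-value with the add-one correction; ties count toward the
#' null. The response sign is reported when significant.
#'
#' @param baseline_rates,response_rates per-trial firing rates (equal
#'   length), Hz.
#' @param n_shuffles number of shuffles (default 1000).
#' @param alpha significance level (default 0.01).
#' @param seed RNG seed.
#' @param min_trials minimum trials required (default 5).
#' @return class `vm_resp`: `p_value`, `statistic` (Hz), `sign`
#'   (`"positive"`, `"negative"`, `"none"`), `significant`, `n_trials`.
#' @export
shuffle_responsiveness <- function(baseline_rates, response_rates,
                                   n_shuffles = 1000, alpha = 0.01,
                                   seed = 1, min_trials = 5) {
  if (length(baseline_rates) != length(response_rates))
    stop("window trial counts differ")
  n <- length(baseline_rates)
  if (n < min_trials)
    return(structure(list(p_value = NA_real_, statistic = NA_real_,
                          sign = "none", significant = FALSE,
                          n_trials = n), class = "vm_resp"))
  set.seed(seed)
  d <- response_rates - baseline_rates
  obs <- mean(d)
  signs <- matrix(sample(c(-1, 1), n * n_shuffles, replace = TRUE),
                  nrow = n)
  null <- as.numeric(crossprod(d, signs)) / n
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_shuffles)
  sig <- p < alpha
  structure(list(p_value = p, statistic = obs,
                 sign = if (!sig) "none" else if (obs > 0) "positive"
                        else "negative",
                 significant = sig, n_trials = n),
            class = "vm_resp")
}

#' Detect the cortical surface channel from LFP correlations
#'
#' Channels left outside the brain at the top of the probe are mutually
#' correlated (shared ambient signal) and weakly correlated with in-brain
#' channels. Scanning boundaries from the top, the boundary maximizing
#' (mean correlation within the out-of-brain block) minus (mean correlation
#' between blocks) marks the surface; the first in-brain channel index is
#' returned. If no boundary achieves `min_contrast`, the result is `NA`
#' with a warning.
#'
#' @param lfp_corr symmetric channels-by-channels correlation matrix,
#'   channels ordered top (shallow) to bottom (deep).
#' @param min_contrast minimum contrast to accept a boundary (default 0.1).
#' @return list with `surface_channel` (first in-brain channel index, or
#'   `NA`), `contrast`, `profile` (contrast per candidate boundary).
#' @export
detect_surface_channel <- function(lfp_corr, min_contrast = 0.1) {
  C <- as.matrix(lfp_corr)
  if (nrow(C) != ncol(C)) stop("correlation matrix must be square")
  if (max(abs(C - t(C))) > 1e-6) stop("correlation matrix must be symmetric")
  nch <- nrow(C)
  prof <- rep(NA_real_, nch)
  for (b in 3:nch) {
    top <- seq_len(b - 1L)
    bot <- b:nch
    w <- C[top, top]
    within <- mean(w[upper.tri(w)])
    between <- mean(C[top, bot])
    prof[b] <- within - between
  }
  best <- which.max(prof)
  if (length(best) == 0 || is.na(prof[best]) ||
      prof[best] < min_contrast) {
    warning("no detectable surface boundary")
    return(list(surface_channel = NA_integer_, contrast = NA_real_,
                profile = prof))
  }
  list(surface_channel = as.integer(best), contrast = prof[best],
       profile = prof)
}
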