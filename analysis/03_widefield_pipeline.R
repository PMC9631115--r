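#!/usr/bin/env Rscript
# Full widefield chain on a synthetic trained-day session: hemodynamic
# correction, dF/F, SVD compression, deconvolution, hemisphere-weighted
# subtraction of the planted mPFC region, and retinotopic field-sign
# mapping of a two-area phantom. Writes summary tables under results/.

library(visuomotor)
dir.create("results", showWarnings = FALSE)

## stimulus-aligned hemispheric asymmetry --------------------------------
s <- simulate_session(behavior_regime("associated",
                                      response_probability = 0.95),
                      n_trials = 30, seed = 71)
st <- simulate_widefield(s, widefield_truth(noise_sd = 0.5), seed = 72)
ch <- split_channels(st)
hc <- hemodynamic_correct(ch$blue, ch$violet, ch$times_blue,
                          ch$times_violet, geometry = ch$geometry)
dff <- normalize_dff(hc$corrected, 35)
sv <- svd_compress(dff$dff, 20)
dec <- deconvolve(sv$SV, gcamp_kernel(35), lambda = 1e-4)
rois <- hemisphere_rois(st$geometry, c(round(st$geometry[1] * 0.25),
                                       round(st$geometry[2] / 2 * 0.85)), 3)
left <- roi_trace(sv$U, dec, rois$left)
right <- roi_trace(sv$U, dec, rois$right)
ep <- delay_movement_epochs(s)
hm <- fit_hemisphere_ratio(left, right, ep, 35)
asym <- hemisphere_subtract(left, right, hm)
eta <- event_triggered_average(asym, 35, s$trials$stim_onset,
                               window = c(-0.5, 0.5))
write.csv(data.frame(time_s = eta$time, asymmetry = eta$mean),
          "results/asymmetry_trace.csv", row.names = FALSE)
cat(sprintf("Hemisphere movement-gain ratio: %.3f (planted 0.8) from %d delay-period movements\n",
            hm$ratio, hm$n_epochs))
cat(sprintf("Stimulus-aligned asymmetry peaks at %+.0f ms (n = %d stimuli)\n",
            1000 * eta$time[which.max(eta$mean)], eta$n_events))

## in-band artifact attenuation ------------------------------------------
bandpow <- function(x, fs, lo, hi) {
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}
pix <- which.max(as.vector(st$truth$gain_map))
att <- 1 - bandpow(hc$corrected[pix, ], 35, 5, 15) /
  bandpow(ch$blue[pix, ], 35, 5, 15)
cat(sprintf("Heartbeat-band (5-15 Hz) power attenuation: %.1f%%\n", 100 * att))

## retinotopic field sign -------------------------------------------------
spec2 <- retinotopy_spec(rows = 30, cols = 60,
                         areas = list(list(cols = c(1, 30), mirror = FALSE),
                                      list(cols = c(31, 60), mirror = TRUE)))
r2 <- simulate_retinotopy(spec2, seed = 63)
fsm <- field_sign_map(r2$responses, r2$positions, n_boot = 10,
                      smooth_sigma = 1.5, seed = 64)
write.csv(data.frame(column = seq_len(ncol(fsm$sign)),
                     mean_sign = colMeans(fsm$sign[5:26, ], na.rm = TRUE)),
          "results/field_sign_profile.csv", row.names = FALSE)
cm <- colMeans(fsm$sign[5:26, ], na.rm = TRUE)
cat(sprintf("Field sign: area 1 mean %+.2f, mirrored area 2 mean %+.2f, border at column %d (planted 30/31)\n",
            mean(cm[5:20]), mean(cm[41:56]), which(diff(sign(cm)) != 0)[1]))
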