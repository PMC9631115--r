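#!/usr/bin/env Rscript
# Simulates a training cohort: three mice, six task days each, with the
# stimulus-movement association switched on at a mouse-specific day.
# Writes per-session trial tables and a cohort manifest under results/.

library(visuomotor)

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- data.frame(mouse = rep(c("m1", "m2", "m3"), each = 6),
                     day = rep(1:6, 3),
                     switch_day = rep(c(3, 4, 5), each = 6))
cohort$mode <- ifelse(cohort$day >= cohort$switch_day, "associated", "null")

grid <- delay_grid(c(4, 7), c(0.5, 2))
for (i in seq_len(nrow(cohort))) {
  reg <- if (cohort$mode[i] == "associated")
    behavior_regime("associated", response_probability = 0.9)
  else behavior_regime("null")
  s <- simulate_session(reg, grid, n_trials = 50,
                        seed = 1000 + 10 * i, mouse = cohort$mouse[i],
                        day = cohort$day[i])
  write_session(s, file.path(out_dir, sprintf("%s_day%d", cohort$mouse[i],
                                              cohort$day[i])))
  cohort$n_trials[i] <- nrow(s$trials)
  cohort$n_rewarded[i] <- sum(s$trials$outcome == "reward")
}
write.csv(cohort, file.path("results", "cohort_manifest.csv"),
          row.names = FALSE)
cat(sprintf("Simulated %d sessions (%d mice x 6 days); reward rates %0.2f-%0.2f\n",
            nrow(cohort), 3,
            min(cohort$n_rewarded / cohort$n_trials),
            max(cohort$n_rewarded / cohort$n_trials)))
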