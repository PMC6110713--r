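#!/usr/bin/env Rscript
# Stage 4 — eye-tracking analysis (fMRI cohort).
#
# Simulates 500 Hz gaze streams for the fMRI cohort (dwell on the
# larger-minimum option biased in the Self condition only), classifies
# fixations and saccades with the velocity/acceleration thresholds
# (30 deg/s, 9500 deg/s^2, 100 ms), assigns fixations to the two option
# AOIs, and tests per-subject dwell preferences for the larger-minimum
# option in each condition.

suppressPackageStartupMessages(library(proxyrisk))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 20260929)
src <- "results/synthetic"
out <- "results/gaze"

choices <- read_choices(file.path(src, "fmri_choices.tsv"))
layout <- gaze_layout()
set.seed(seed)

dwell_rows <- list()
for (s in unique(choices$subject_id)) {
  for (cond in c("Self", "Other")) {
    ch <- choices[choices$subject_id == s & choices$condition == cond, ]
    gain <- if (cond == "Self") 4e-4 else 0
    g <- simulate_gaze(ch, layout, gaze_min_gain = gain)
    ev <- classify_events(g$samples)
    fx <- assign_aoi(ev$fixations, layout)
    od <- option_dwell(fx, ch, g$sides)
    od$subject_id <- s
    od$condition <- cond
    dwell_rows[[length(dwell_rows) + 1L]] <- od
  }
}
dwell <- do.call(rbind, dwell_rows)
write_tsv(dwell, file.path(out, "option_dwell.tsv"))

per_sub <- stats::aggregate(dwell_diff ~ subject_id + condition,
                            dwell[!dwell$excluded, ], mean)
tests <- do.call(rbind, lapply(c("Self", "Other"), function(cc) {
  r <- one_sample_t(per_sub$dwell_diff[per_sub$condition == cc])
  data.frame(condition = cc, mean_dwell_diff_s = r$estimate,
             t = r$statistic, df = r$df, p = r$p)
}))
tests$p_bonferroni <- bonferroni(tests$p, 2)
write_tsv(tests, file.path(out, "dwell_preference_tests.tsv"))
for (i in seq_len(nrow(tests)))
  message(sprintf(
    "dwell on larger-minimum option, %s: mean diff %.3f s, t%d = %.2f, p(Bonf) = %.3f",
    tests$condition[i], tests$mean_dwell_diff_s[i], tests$df[i], tests$t[i],
    tests$p_bonferroni[i]))
message(sprintf("trials excluded for tied minima: %d of %d",
                sum(dwell$excluded), nrow(dwell)))
message("wrote ", out)
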