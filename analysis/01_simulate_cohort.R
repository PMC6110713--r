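#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emits a behavioral-scale cohort (60 participants, Mouselab view logs,
# 30 s deadline) and an fMRI-scale cohort (24 participants, 5 s deadline)
# with full ground truth, under one shared conflict-structured choice set
# per cohort. Downstream stages read only these TSVs.

suppressPackageStartupMessages(library(proxyrisk))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 20260928)

out <- "results/synthetic"
beh <- simulate_cohort(n_subjects = 60, views = TRUE, seed = seed)
write_tsv(beh$pairs, file.path(out, "behavioral_pairs.tsv"))
write_tsv(beh$choices, file.path(out, "behavioral_choices.tsv"))
write_tsv(beh$views, file.path(out, "behavioral_views.tsv"))
write_tsv(beh$truth, file.path(out, "behavioral_truth.tsv"))

fmri <- simulate_cohort(n_subjects = 24, task = "fmri", seed = seed + 1L)
write_tsv(fmri$pairs, file.path(out, "fmri_pairs.tsv"))
write_tsv(fmri$choices, file.path(out, "fmri_choices.tsv"))
write_tsv(fmri$truth, file.path(out, "fmri_truth.tsv"))

write_manifest(out, seed,
               c("behavioral_pairs.tsv", "behavioral_choices.tsv",
                 "behavioral_views.tsv", "behavioral_truth.tsv",
                 "fmri_pairs.tsv", "fmri_choices.tsv", "fmri_truth.tsv"))

pm <- pair_metrics(beh$pairs)
message(sprintf(
  "behavioral cohort: 60 subjects x 72 trials; %d/%d conflict pairs; |cor(dmin, dev)| = %.2f",
  sum(beh$pairs$conflict), nrow(beh$pairs), abs(cor(pm$dmin, pm$dev))))
message("fMRI cohort: 24 subjects x 72 trials (5 s deadline)")
message("wrote ", out)
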