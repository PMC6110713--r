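#!/usr/bin/env Rscript
# Stage 3 — Mouselab information-search analysis (behavioral cohort).
#
# Computes quartile-resolved view shares on the L/M/H amounts, models the
# bias to inspect the low amount first (random-intercept logit with
# condition and layout effects), and regresses the trial-level dwell
# difference between the larger- and smaller-minimum options on dmin and
# dev per condition (random-intercept linear mixed model).

suppressPackageStartupMessages(library(proxyrisk))
src <- "results/synthetic"
out <- "results/information_search"

views <- read_views(file.path(src, "behavioral_views.tsv"))
choices <- read_choices(file.path(src, "behavioral_choices.tsv"))

shares <- quartile_view_shares(views, choices, level = "group")
write_tsv(shares, file.path(out, "quartile_view_shares.tsv"))
q1L <- shares$share[shares$quartile == 1 & shares$cell == "L"]
q4L <- shares$share[shares$quartile == 4 & shares$cell == "L"]
message(sprintf("L-box view share: Q1 %.1f%% -> Q4 %.1f%% (group mean over %s conditions)",
                mean(q1L), mean(q4L), length(q1L)))

counts <- first_view_counts(views)$counts
write_tsv(counts, file.path(out, "first_view_counts.tsv"))
fv <- fit_first_view_model(views)
write_tsv(fv$coefficients, file.path(out, "first_view_glmm.tsv"))
cond <- fv$coefficients[fv$coefficients$term == "conditionSelf", ]
message(sprintf("first-view low bias, Self vs Other: log-OR %.2f, z = %.2f, p = %.2g (%s)",
                cond$estimate, cond$z, cond$p, fv$method))

dw <- dwell_differences(views, choices)
dm <- dwell_difference_model(dw)
coefs <- do.call(rbind, lapply(names(dm), function(cc)
  cbind(condition = cc, dm[[cc]]$coefficients)))
write_tsv(coefs, file.path(out, "dwell_difference_lmm.tsv"))
for (cc in names(dm)) {
  r <- dm[[cc]]$coefficients
  message(sprintf("dwell difference ~ dmin, %s: slope %.2g s/JPY, t = %.2f, p = %.2g",
                  cc, r$estimate[r$term == "dmin"], r$t[r$term == "dmin"],
                  r$p[r$term == "dmin"]))
}
message("wrote ", out)
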