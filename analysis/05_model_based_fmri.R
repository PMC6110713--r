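#!/usr/bin/env Rscript
# Stage 5 — model-based fMRI designs, simulated ROI series, and group
# inference.
#
# For every fMRI-cohort subject: lays out a scanning session from their
# trials, builds GLM1 (utility-difference modulator, evaluated at the
# group-mean maximin weight per condition) and GLM2 (dmin + dev
# modulators) design matrices, simulates ROI BOLD in which a
# "perspective-taking region" tracks dmin in Self and dev in Other and a
# "valuation region" tracks the utility difference in both conditions,
# then fits the GLMs and tests the modulation betas at the group level —
# including the condition-by-parameter repeated-measures ANOVA — and runs
# a gPPI analysis with a planted Self-specific seed-target coupling.

suppressPackageStartupMessages(library(proxyrisk))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 20260930)
src <- "results/synthetic"
out <- "results/fmri"

choices <- read_choices(file.path(src, "fmri_choices.tsv"))
fits <- utils::read.delim("results/choice_model/fmri_fits.tsv")
alpha_bar <- tapply(fits$alpha_hat, fits$condition, mean)
message(sprintf("group-mean maximin weights: Self %.2f, Other %.2f (define the dU modulator)",
                alpha_bar[["Self"]], alpha_bar[["Other"]]))

set.seed(seed)
# population means; each subject draws around them (between-subject SD half
# the mean effect), so group t values live on a realistic scale
true_mod <- c(Self_x_dmin = 0.004, Self_x_dev = 0.000,
              Other_x_dmin = 0.000, Other_x_dev = 0.004)
mod_sd <- 0.002
true_du <- 0.003
du_sd <- 0.0015
true_gamma <- 0.4
gamma_sd <- 0.2
subjects <- unique(choices$subject_id)
mod_betas <- matrix(NA_real_, length(subjects), 4,
                    dimnames = list(NULL, names(true_mod)))
du_betas <- matrix(NA_real_, length(subjects), 2,
                   dimnames = list(NULL, c("Self_x_du", "Other_x_du")))
ppi_betas <- matrix(NA_real_, length(subjects), 2,
                    dimnames = list(NULL, c("ppi_Self", "ppi_Other")))

for (i in seq_along(subjects)) {
  ch <- choices[choices$subject_id == subjects[i] &
                  choices$condition %in% c("Self", "Other"), ]
  ch$trial_id <- seq_len(nrow(ch))
  ses <- session_events(ch, alpha_by_cond = alpha_bar)
  d2 <- build_design(ses$events, ses$TR, ses$n_scans, model = "GLM2")
  b2 <- rep(0, ncol(d2$X)); names(b2) <- colnames(d2$X)
  b2[c("Self", "Other")] <- 1
  b2[names(true_mod)] <- rnorm(4, true_mod, mod_sd)
  y_tpj <- simulate_bold(d2, b2, noise_sd = 1)
  f2 <- fit_glm(y_tpj, d2)
  mod_betas[i, ] <- f2$beta[match(colnames(mod_betas), f2$term)]

  d1 <- build_design(ses$events, ses$TR, ses$n_scans, model = "GLM1")
  b1 <- rep(0, ncol(d1$X)); names(b1) <- colnames(d1$X)
  b1[c("Self", "Other")] <- 1
  b1[c("Self_x_du", "Other_x_du")] <- rnorm(2, true_du, du_sd)
  y_vs <- simulate_bold(d1, b1, noise_sd = 1)
  f1 <- fit_glm(y_vs, d1)
  du_betas[i, ] <- f1$beta[match(colnames(du_betas), f1$term)]

  # seed region: three noisy voxels around a common fluctuation
  common <- rnorm(ses$n_scans)
  seed_series <- roi_eigenvariate(sapply(1:3, function(v)
    common + rnorm(ses$n_scans, 0, 0.5)))
  gd <- gppi_design(seed_series, ses$events, ses$TR, ses$n_scans)
  target <- 0.5 * gd$X[, "Self"] + 0.5 * gd$X[, "Other"] +
    rnorm(1, true_gamma, gamma_sd) * gd$X[, "ppi_Self"] +
    rnorm(ses$n_scans, 0, 1)
  fp <- fit_glm(target, gd)
  ppi_betas[i, ] <- fp$beta[match(colnames(ppi_betas), fp$term)]
}

write_tsv(as.data.frame(cbind(subject_id = subjects, mod_betas, du_betas,
                              ppi_betas)),
          file.path(out, "subject_betas.tsv"))

# group tests on the modulation betas
an <- rm_anova_2x2(mod_betas[, c("Self_x_dmin", "Self_x_dev",
                                 "Other_x_dmin", "Other_x_dev")],
                   factor_names = c("condition", "parameter"))
write_tsv(an, file.path(out, "modulation_anova.tsv"))
message(sprintf("condition x parameter interaction: F(%d,%d) = %.2f, p = %.3f",
                an$df1[3], an$df2[3], an$F[3], an$p[3]))

du_t <- lapply(colnames(du_betas), function(cc) one_sample_t(du_betas[, cc]))
du_p <- bonferroni(vapply(du_t, `[[`, numeric(1), "p"), 2)
for (j in 1:2)
  message(sprintf("dU modulation (%s): t%d = %.2f, p(Bonf) = %.4f",
                  colnames(du_betas)[j], du_t[[j]]$df, du_t[[j]]$statistic,
                  du_p[j]))

ppi_t <- lapply(colnames(ppi_betas), function(cc) one_sample_t(ppi_betas[, cc]))
ppi_tab <- data.frame(
  term = c(colnames(du_betas), colnames(ppi_betas)),
  mean_beta = c(colMeans(du_betas), colMeans(ppi_betas)),
  t = c(vapply(du_t, `[[`, numeric(1), "statistic"),
        vapply(ppi_t, `[[`, numeric(1), "statistic")),
  p = c(vapply(du_t, `[[`, numeric(1), "p"),
        vapply(ppi_t, `[[`, numeric(1), "p")))
write_tsv(ppi_tab, file.path(out, "group_modulation_tests.tsv"))
for (j in 1:2)
  message(sprintf("gPPI interaction (%s): mean beta %.3f (true %s), t%d = %.2f",
                  colnames(ppi_betas)[j], mean(ppi_betas[, j]),
                  c(true_gamma, 0)[j], ppi_t[[j]]$df, ppi_t[[j]]$statistic))
message("wrote ", out)
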