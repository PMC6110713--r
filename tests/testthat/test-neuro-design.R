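fmri_session <- function(seed = 41, n_pairs = 24, alpha = c(Self = 0.4,
                                                            Other = 0.3)) {
  set.seed(seed)
  pairs <- generate_lottery_set(design_config(n_pairs = n_pairs))
  half <- n_pairs / 2
  ch <- rbind(
    simulate_choices(pairs[seq_len(half), ], alpha[["Self"]], 0.02, "Self",
                     rt_meanlog = log(2.5), rt_sdlog = 0.3, deadline = 5),
    simulate_choices(pairs[-seq_len(half), ], alpha[["Other"]], 0.02, "Other",
                     rt_meanlog = log(2.5), rt_sdlog = 0.3, deadline = 5))
  ch$trial_id <- seq_len(n_pairs)
  session_events(ch, alpha_by_cond = alpha)
}

test_that("canonical HRF has the double-gamma shape", {
  h <- hrf_kernel(2)
  expect_equal(h$values[1], 0)
  peak_t <- h$t[which.max(h$values)]
  expect_gte(peak_t, 4.5)
  expect_lte(peak_t, 6)
  expect_gt(sum(h$values) * h$dt, 0)
  expect_equal(max(h$values), 1)
  # the undershoot is present and small relative to the peak
  expect_lt(min(h$values), 0)
  expect_gt(min(h$values), -0.3)
})

test_that("design construction matches a brute-force convolution oracle", {
  ev <- data.frame(onset = 10, duration = 3, trial_type = "Self")
  TR <- 2; os <- 16L; n_scans <- 40
  d <- build_design(ev, TR, n_scans, hp_cutoff = NULL)
  h <- hrf_kernel(TR, os)
  dt <- TR / os
  u <- numeric(n_scans * os)
  a <- floor(10 / dt) + 1; b <- ceiling(13 / dt)
  u[a:b] <- 1
  conv <- numeric(length(u))
  for (s in seq_along(u)) {           # explicit discrete convolution
    kmax <- min(s, length(h$values))
    conv[s] <- sum(u[s - seq_len(kmax) + 1] * h$values[seq_len(kmax)])
  }
  oracle <- conv[(seq_len(n_scans) - 1) * os + 1]
  expect_lt(max(abs(d$X[, "Self"] - oracle)), 1e-10)
})

test_that("empty event sets leave only nuisance and intercept columns", {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   trial_type = character(0))
  d <- build_design(ev, 2, 64)
  expect_setequal(unique(d$column_type), c("nuisance", "intercept"))
  expect_equal(d$X[, "intercept"], rep(1, 64))
})

test_that("constant modulators vanish under within-condition centering", {
  ev <- data.frame(onset = c(5, 20, 35), duration = 2, trial_type = "Self",
                   du = 7)
  d <- build_design(ev, 2, 40, model = "GLM1")
  expect_true(all(abs(d$X[, "Self_x_du"]) < 1e-12))
})

test_that("design construction is linear in the event set", {
  e1 <- data.frame(onset = 5, duration = 2, trial_type = "Self")
  e2 <- data.frame(onset = 30, duration = 3, trial_type = "Self")
  d12 <- build_design(rbind(e1, e2), 2, 40, hp_cutoff = NULL)
  d1 <- build_design(e1, 2, 40, hp_cutoff = NULL)
  d2 <- build_design(e2, 2, 40, hp_cutoff = NULL)
  expect_equal(d12$X[, "Self"], d1$X[, "Self"] + d2$X[, "Self"],
               tolerance = 1e-12)
  expect_error(build_design(data.frame(onset = 100, duration = 2,
                                       trial_type = "Self"), 2, 40),
               "outside the scan window")
})

test_that("session layout respects cue/choice/response timing conventions", {
  ses <- fmri_session()
  ev <- ses$events
  expect_true(all(ev$duration[ev$trial_type == "cue"] == 1))
  expect_true(all(ev$duration[ev$trial_type == "response"] == 0))
  choice_ev <- ev[ev$trial_type %in% c("Self", "Other"), ]
  expect_true(all(choice_ev$duration > 0 & choice_ev$duration <= 5))
  expect_true(all(!is.na(choice_ev$du)))
  expect_true(all(diff(ev$onset[ev$trial_type == "cue"]) >= 8))
})

test_that("GLM recovers known betas exactly without noise", {
  ses <- fmri_session()
  d <- build_design(ses$events, ses$TR, ses$n_scans, model = "GLM2")
  beta <- rnorm(ncol(d$X), 0, 0.5)
  y <- simulate_bold(d, beta, noise_sd = 0)
  f <- fit_glm(y, d)
  expect_lt(max(abs(f$beta - beta)), 1e-8)
  expect_equal(f$term, colnames(d$X))
})

test_that("noisy-GLM modulator estimates are unbiased", {
  set.seed(42)
  ses <- fmri_session()
  d <- build_design(ses$events, ses$TR, ses$n_scans, model = "GLM2")
  beta <- rep(0, ncol(d$X))
  names(beta) <- colnames(d$X)
  beta[c("Self", "Other", "Self_x_dmin", "Other_x_dev")] <-
    c(1, 1, 0.003, 0.002)
  reps <- 120
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    y <- simulate_bold(d, beta, noise_sd = 1)
    f <- fit_glm(y, d)
    est[r, ] <- f$beta[match(c("Self_x_dmin", "Other_x_dev"), f$term)]
  }
  for (j in 1:2) {
    tv <- c(0.003, 0.002)[j]
    se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - tv), 3 * se + 1e-6)
  }
})

test_that("rank-deficient designs fail loudly with the offending column", {
  X <- cbind(a = rnorm(30), b = rnorm(30), intercept = 1)
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_glm(rnorm(30), X), "dup|collinear")
})

test_that("the ROI eigenvariate matches small-case oracles", {
  set.seed(43)
  y <- rnorm(40)
  expect_equal(roi_eigenvariate(y), y - mean(y), tolerance = 1e-12)
  Y3 <- cbind(y, y, y)
  expect_equal(roi_eigenvariate(Y3), y - mean(y), tolerance = 1e-12)
  # two-voxel oracle via explicit SVD of the centered matrix
  Y <- cbind(rnorm(40), rnorm(40))
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(Yc)
  oracle <- sv$u[, 1] * sv$d[1] / sqrt(2)
  e <- roi_eigenvariate(Y)
  expect_lt(min(max(abs(e - oracle)), max(abs(e + oracle))), 1e-10)
  expect_gte(sum(e * rowMeans(Yc)), 0)     # sign-aligned with the mean
  expect_error(roi_eigenvariate(matrix(1, 10, 2)), "zero-variance")
})

test_that("gPPI interaction columns behave under edge cases and planting", {
  set.seed(44)
  ses <- fmri_session()
  seed0 <- rep(0.7, ses$n_scans)          # constant seed -> centered to zero
  g0 <- gppi_design(seed0, ses$events, ses$TR, ses$n_scans)
  expect_true(all(abs(g0$X[, c("ppi_Self", "ppi_Other")]) < 1e-12))
  # permutation equivariance of condition labels
  seed_s <- rnorm(ses$n_scans)
  g1 <- gppi_design(seed_s, ses$events, ses$TR, ses$n_scans,
                    conditions = c("Self", "Other"))
  g2 <- gppi_design(seed_s, ses$events, ses$TR, ses$n_scans,
                    conditions = c("Other", "Self"))
  expect_equal(g1$X[, "ppi_Self"], g2$X[, "ppi_Self"], tolerance = 1e-12)
  # planted connectivity is recovered in the right condition only
  gamma <- 0.6
  target <- 0.4 * g1$X[, "Self"] + gamma * g1$X[, "ppi_Self"] +
    rnorm(ses$n_scans, 0, 0.4)
  f <- fit_glm(target, g1)
  est_self <- f$beta[f$term == "ppi_Self"]
  est_other <- f$beta[f$term == "ppi_Other"]
  se_self <- f$se[f$term == "ppi_Self"]
  se_other <- f$se[f$term == "ppi_Other"]
  expect_lt(abs(est_self - gamma), 3 * se_self)
  expect_lt(abs(est_other), 3 * se_other)
  expect_error(gppi_design(seed_s[-1], ses$events, ses$TR, ses$n_scans),
               "length")
})
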