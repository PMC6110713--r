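test_that("utility interpolates between minimum and expected value", {
  lot <- c(300, 600, 900)
  expect_equal(utility(lot, 0), 600)      # risk-neutral: EV
  expect_equal(utility(lot, 1), 300)      # pure maximin
  expect_equal(utility(lot, 0.5), 450)    # hand evaluation
  for (a in seq(0, 1, 0.1)) {
    u <- utility(lot, a)
    expect_gte(u, 300)
    expect_lte(u, 600)
  }
  m <- rbind(c(300, 600, 900), c(100, 100, 100))
  expect_equal(utility(m, 0.25), c(0.25 * 300 + 0.75 * 600, 100))
  expect_error(utility(lot, 1.2), "alpha")
  expect_error(utility(lot, -0.1), "alpha")
  expect_error(utility(c(300, 600), 0.5), "three")
  expect_error(utility(c(-10, 0, 10), 0.5), "non-negative")
})

test_that("softmax choice rule has the right limits and monotonicity", {
  lot <- c(300, 600, 900)
  expect_equal(choice_probability(lot, lot, 0.3, 0.05), 0.5)
  # hand evaluation: du = 100, lam = 0.01 -> logistic(1)
  expect_equal(softmax_prob(100, 0.01), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(softmax_prob(100, 1e6), 1)   # deterministic limit, no overflow
  expect_equal(softmax_prob(-100, 1e6), 0)
  p_du <- softmax_prob(seq(-50, 50, 10), 0.02)
  expect_true(all(diff(p_du) > 0))          # increasing in utility advantage
  p_lam <- softmax_prob(100, seq(0.001, 0.1, 0.001))
  expect_true(all(diff(p_lam) > 0))         # increasing in sensitivity
  expect_true(all(p_du > 0 & p_du < 1))
})

test_that("delta_u collapses to dEV and dMin at the alpha extremes", {
  a <- c(300, 600, 900); b <- c(450, 500, 550)
  expect_equal(delta_u(a, b, 0), abs(mean(a) - mean(b)))
  expect_equal(delta_u(a, b, 1), abs(300 - 450))
  expect_equal(delta_u(a, b, 0.5), 25)      # |450 - 475|
  expect_equal(delta_u(a, b, 0.3), delta_u(b, a, 0.3))  # symmetric
})

test_that("pair_metrics derives signed and absolute differences", {
  pm <- pair_metrics(tiny_choices())
  expect_equal(pm$dmin, c(150, 100))
  expect_equal(pm$dev, c(100, 66.66667), tolerance = 1e-6)
  expect_equal(pm$min_adv, c("b", "a"))
  expect_true(all(pm$dmin >= 0 & pm$dev >= 0))
})

test_that("negative log-likelihood is additive and correct at limits", {
  ch <- agent_choices(0.4, 0.02)
  # lam = 0: every trial contributes log 2
  expect_equal(negative_log_likelihood(ch, 0.4, 0), 36 * log(2))
  # single-trial value: -log P(observed)
  one <- tiny_choices()[1, ]
  pm <- pair_metrics(one)
  du <- 0.5 * pm$sdmin + 0.5 * pm$sdev
  expect_equal(negative_log_likelihood(one, 0.5, 0.01),
               -log(plogis(0.01 * du)))
  # additivity over trials
  total <- negative_log_likelihood(ch, 0.3, 0.015)
  parts <- vapply(seq_len(nrow(ch)), function(i)
    negative_log_likelihood(ch[i, ], 0.3, 0.015), numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-12)
  expect_gte(total, 0)
  expect_error(negative_log_likelihood(ch[0, ], 0.3, 0.01), "at least one")
})

test_that("fit_subject recovers generating parameters from rich data", {
  set.seed(101)
  ch <- agent_choices(0.4, 0.02, reps = 10)   # 360 trials
  f <- fit_subject(ch)
  expect_s3_class(f, "qm_fit")
  expect_lt(abs(f$alpha_hat - 0.4), 0.1)
  expect_gte(f$alpha_hat, 0)
  expect_lte(f$alpha_hat, 1)
  expect_gt(f$lam_hat, 0)
})

test_that("uninformative data drive lam to its lower bound", {
  set.seed(102)
  pairs <- generate_lottery_set()
  ch <- simulate_choices(pairs, 0.5, 0.02)
  ch$choice <- sample(c("a", "b"), nrow(ch), replace = TRUE)  # pure noise
  f <- fit_subject(ch)
  expect_lt(f$lam_hat, 1e-3)
  expect_equal(f$nll, 36 * log(2), tolerance = 0.05 * 36 * log(2))
})

test_that("a deterministic maximin agent is flagged at the lam bound", {
  set.seed(103)
  pairs <- generate_lottery_set(design_config(conflict_fraction = 1))
  pm <- pair_metrics(pairs)
  ch <- pm
  ch$choice <- ifelse(pm$min_adv == "a", "a", "b")  # always larger minimum
  ch$rt_s <- 2
  ch$condition <- "Self"
  f <- fit_subject(ch)
  expect_gt(f$alpha_hat, 0.9)
  expect_true(f$lam_at_bound)
  # grid oracle agrees that alpha = 1 region wins
  g <- grid_fit_oracle(ch, seq(0, 1, 0.01), c(0.01, 0.1, 1))
  expect_gt(g$alpha_hat, 0.9)
})

test_that("optimizer never does worse than the exhaustive grid oracle", {
  set.seed(104)
  alpha_grid <- seq(0, 1, 0.01)
  lam_grid <- exp(seq(log(1e-4), log(1), length.out = 40))
  for (i in 1:8) {
    ch <- agent_choices(runif(1), 0.02)
    f <- fit_subject(ch)
    g <- grid_fit_oracle(ch, alpha_grid, lam_grid)
    expect_lte(f$nll, g$nll + 1e-6)
    expect_lte(abs(f$alpha_hat - g$alpha_hat), 0.02)
  }
})

test_that("grid oracle handles single-point grids and noiseless truth", {
  ch <- tiny_choices()
  g <- grid_fit_oracle(ch, 0.3, 0.02)
  expect_equal(g$nll, negative_log_likelihood(ch, 0.3, 0.02))
  # near-deterministic agent: grid containing the generating point finds it
  set.seed(105)
  pairs <- generate_lottery_set(design_config(conflict_fraction = 1))
  ch2 <- simulate_choices(pairs, 0.6, 100)   # effectively noiseless
  g2 <- grid_fit_oracle(ch2, c(0.2, 0.6, 0.9), c(0.01, 100))
  expect_equal(g2$alpha_hat, 0.6)
  expect_error(grid_fit_oracle(ch, numeric(0), 0.1), "non-empty")
})

test_that("likelihood prefers the generating alpha over its mirror image", {
  set.seed(106)
  wins <- 0L
  for (i in 1:20) {
    a <- runif(1, 0.05, 0.45)   # keep alpha and 1 - alpha distinct
    ch <- agent_choices(a, 0.02)
    if (negative_log_likelihood(ch, a, 0.02) <=
        negative_log_likelihood(ch, 1 - a, 0.02)) wins <- wins + 1L
  }
  expect_gt(wins, 15)
})

test_that("fit_cohort returns one row per subject-condition cell", {
  coh <- simulate_cohort(n_subjects = 4, seed = 7)
  fits <- fit_cohort(coh$choices)
  expect_equal(nrow(fits), 8)
  expect_setequal(names(fits),
                  c("subject_id", "condition", "alpha_hat", "lam_hat", "nll",
                    "converged", "lam_at_bound", "n_trials"))
  expect_true(all(fits$alpha_hat >= 0 & fits$alpha_hat <= 1))
  expect_true(all(fits$n_trials == 36))
})
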