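one_trial_views <- function(cells, onsets, offsets, rt, layout = "LMH") {
  list(views = data.frame(trial_id = 1L, condition = "Self",
                          option = "a", cell = cells,
                          onset_s = onsets, offset_s = offsets,
                          layout = layout, stringsAsFactors = FALSE),
       choices = data.frame(trial_id = 1L, condition = "Self", rt_s = rt,
                            stringsAsFactors = FALSE))
}

test_that("a view spanning the whole trial gives 100% in every quartile", {
  f <- one_trial_views("L", 0, 8, rt = 8)
  sh <- quartile_view_shares(f$views, f$choices, level = "trial")
  expect_equal(nrow(sh), 4)
  expect_true(all(sh$cell == "L"))
  expect_true(all(sh$share == 100))
})

test_that("views exactly covering Q1 and Q4 leave Q2/Q3 empty", {
  f <- one_trial_views(c("L", "H"), c(0, 6), c(2, 8), rt = 8)
  sh <- quartile_view_shares(f$views, f$choices, level = "trial")
  get <- function(q, cell) sh$share[sh$quartile == q & sh$cell == cell]
  expect_equal(get(1, "L"), 100)
  expect_equal(get(4, "H"), 100)
  expect_true(all(is.na(sh$share[sh$quartile %in% 2:3])))
})

test_that("analytic quartile apportionment matches per-ms discretization", {
  set.seed(21)
  ch <- agent_choices(0.4, 0.02, n_pairs = 6)
  v <- simulate_mouselab(ch)
  sh <- quartile_view_shares(v, ch, level = "trial")
  for (id in unique(v$trial_id)) {
    rt <- ch$rt_s[ch$trial_id == id]
    vt <- v[v$trial_id == id, ]
    grid <- seq(0, rt, by = 1e-3)
    cell_at <- rep(NA_character_, length(grid))
    for (j in seq_len(nrow(vt)))
      cell_at[grid >= vt$onset_s[j] & grid < vt$offset_s[j]] <- vt$cell[j]
    q_at <- pmin(4, floor(grid / (rt / 4)) + 1)
    for (q in 1:4) for (cc in c("L", "M", "H")) {
      tot <- sum(!is.na(cell_at) & q_at == q)
      if (tot == 0) next
      brute <- 100 * sum(cell_at == cc & q_at == q, na.rm = TRUE) / tot
      ana <- sh$share[sh$trial_id == id & sh$quartile == q & sh$cell == cc]
      if (length(ana) == 0) ana <- 0
      expect_equal(ana, brute, tolerance = 0.1)
    }
  }
})

test_that("quartile shares are invariant to uniform time rescaling", {
  set.seed(22)
  ch <- agent_choices(0.4, 0.02, n_pairs = 4)
  v <- simulate_mouselab(ch)
  sh1 <- quartile_view_shares(v, ch, level = "trial")
  v2 <- v; v2$onset_s <- 3 * v2$onset_s; v2$offset_s <- 3 * v2$offset_s
  ch2 <- ch; ch2$rt_s <- 3 * ch2$rt_s
  sh2 <- quartile_view_shares(v2, ch2, level = "trial")
  expect_equal(sh1$share, sh2$share, tolerance = 1e-9)
})

test_that("first views depend on order only and account for every trial", {
  set.seed(23)
  ch <- agent_choices(0.4, 0.02)
  ch$subject_id <- 1L
  v <- simulate_mouselab(ch)
  v$subject_id <- 1L
  fc <- first_view_counts(v)
  expect_equal(fc$counts$n_low + fc$counts$n_high + fc$counts$n_mid,
               fc$counts$n_trials)
  # stretching durations does not change first-view identity
  v2 <- v; v2$offset_s <- v2$onset_s + 0.5 * (v2$offset_s - v2$onset_s)
  expect_identical(first_view_counts(v2)$counts, fc$counts)
  # forced all-L first views
  vL <- simulate_mouselab(ch, first_view_low_bias = 1, first_view_m_rate = 0)
  vL$subject_id <- 1L
  expect_equal(first_view_counts(vL)$counts$n_high, 0)
})

test_that("empirical first-view share matches the generating bias", {
  set.seed(24)
  ch <- agent_choices(0.4, 0.02, reps = 28)   # ~1000 trials
  v <- simulate_mouselab(ch, first_view_low_bias = 0.7)
  fv <- first_view_counts(v)$first_views
  fv <- fv[fv$cell != "M", ]
  expect_equal(mean(fv$cell == "L"), 0.7, tolerance = 0.03)
})

test_that("first-view GLMM detects a Self > Other bias difference", {
  set.seed(25)
  coh <- simulate_cohort(n_subjects = 30, views = TRUE, seed = 251)
  m <- fit_first_view_model(coh$views)
  expect_equal(m$method, "glmm")
  cond <- m$coefficients[m$coefficients$term == "conditionSelf", ]
  expect_gt(cond$z, 2)          # injected 0.75 vs 0.60 low bias
  lay <- m$coefficients[grepl("^layout", m$coefficients$term), ]
  expect_lt(abs(lay$z), 3)      # layout carries no injected effect
})

test_that("first-view GLMM is near-null when conditions share one bias", {
  set.seed(26)
  pop <- population_spec(first_view_low_bias = c(Self = 0.65, Other = 0.65))
  coh <- simulate_cohort(n_subjects = 30, views = TRUE, population = pop,
                         seed = 261)
  m <- fit_first_view_model(coh$views)
  cond <- m$coefficients[m$coefficients$term == "conditionSelf", ]
  expect_lt(abs(cond$z), 3)
})

test_that("dwell-difference LMM recovers a Self-only dmin slope", {
  set.seed(27)
  coh <- simulate_cohort(n_subjects = 30, views = TRUE, seed = 271)
  dm <- dwell_difference_model(dwell_differences(coh$views, coh$choices))
  self_dmin <- dm$Self$coefficients[dm$Self$coefficients$term == "dmin", ]
  other_dmin <- dm$Other$coefficients[dm$Other$coefficients$term == "dmin", ]
  expect_gt(self_dmin$t, 2)
  expect_equal(self_dmin$estimate, 4e-4, tolerance = 0.5)
  expect_lt(abs(other_dmin$t), 3)
  expect_error(dwell_difference_model(
    transform(dwell_differences(coh$views, coh$choices), dmin = 100)),
    "constant")
})

test_that("with no between-subject variance the LMM collapses to OLS", {
  set.seed(28)
  n_sub <- 12
  d <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    dmin <- runif(30, 50, 500); dev <- runif(30, 20, 300)
    data.frame(subject_id = s, condition = "Self", layout = "LMH",
               dmin = dmin, dev = dev,
               dwell_diff = 5e-4 * dmin + rnorm(30, 0, 0.2))
  }))
  fit <- dwell_difference_model(d)$Self
  ols <- coef(lm(dwell_diff ~ dmin + dev, data = d))
  est <- fit$coefficients$estimate[match(c("(Intercept)", "dmin", "dev"),
                                         fit$coefficients$term)]
  expect_equal(est, unname(ols), tolerance = 1e-3)
})

test_that("option relabeling flips or preserves dwell signs as it should", {
  set.seed(29)
  ch <- agent_choices(0.4, 0.02, n_pairs = 8)
  v <- simulate_mouselab(ch)
  d1 <- dwell_differences(v, ch)
  swap <- function(x, i, j) { tmp <- x[[i]]; x[[i]] <- x[[j]]; x[[j]] <- tmp; x }
  ch2 <- ch
  for (k in c("low", "mid", "high"))
    ch2 <- swap(ch2, paste0("a_", k), paste0("b_", k))
  ch2$choice <- ifelse(ch$choice == "a", "b", "a")
  v2 <- v; v2$option <- ifelse(v$option == "a", "b", "a")
  d2 <- dwell_differences(v2, ch2)
  # consistent relabeling of views and outcomes leaves the difference alone
  expect_equal(d1$dwell_diff, d2$dwell_diff, tolerance = 1e-12)
  # relabeling the views alone flips which option holds the dwell, so the
  # larger-minimum-minus-smaller difference flips sign exactly
  d3 <- dwell_differences(v2, ch)
  expect_equal(d3$dwell_diff, -d1$dwell_diff, tolerance = 1e-12)
})
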