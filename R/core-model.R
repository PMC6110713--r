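#' Quasi-maximin utility of a three-outcome lottery
#'
#' Utility of a lottery with three equiprobable monetary outcomes under the
#' quasi-maximin model: a convex combination of the worst outcome and the
#' expected value, `U = alpha * min + (1 - alpha) * EV`. `alpha = 0` is a
#' fully risk-neutral (expected-value) evaluator; `alpha = 1` evaluates an
#' option purely by its minimum outcome.
#'
#' @param outcomes Numeric vector of length 3 (one lottery), or an n x 3
#'   matrix (one lottery per row). Amounts in JPY; must be finite and >= 0.
#' @param alpha Maximin weight in `[0, 1]`.
#' @return Utility in JPY (scalar, or length-n vector for a matrix input).
#'   Always lies between the lottery's minimum and its expected value.
#' @examples
#' utility(c(300, 600, 900), alpha = 0)    # 600 (EV)
#' utility(c(300, 600, 900), alpha = 1)    # 300 (minimum)
#' utility(c(300, 600, 900), alpha = 0.5)  # 450
#' @export
utility <- function(outcomes, alpha) {
  check_alpha(alpha)
  if (is.matrix(outcomes)) {
    if (ncol(outcomes) != 3L) stop("lottery matrix must have 3 columns")
    check_outcomes(outcomes)
    mn <- do.call(pmin, lapply(seq_len(3L), function(j) outcomes[, j]))
    ev <- rowMeans(outcomes)
  } else {
    if (length(outcomes) != 3L) stop("a lottery has exactly three outcomes")
    check_outcomes(outcomes)
    mn <- min(outcomes)
    ev <- mean(outcomes)
  }
  alpha * mn + (1 - alpha) * ev
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]")
  invisible(alpha)
}

check_outcomes <- function(x) {
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop("lottery outcomes must be finite and non-negative")
  invisible(x)
}

#' Softmax probability of choosing option A
#'
#' Logit (softmax over two options) choice rule: the probability of choosing
#' option A increases logistically in its utility advantage,
#' `P(A) = 1 / (1 + exp(-lam * (U_A - U_B)))`. The sensitivity `lam`
#' (inverse temperature, units 1/JPY) absorbs the currency scale; `lam -> 0`
#' gives random choice, `lam -> Inf` deterministic maximization.
#'
#' @param option_a,option_b Lotteries as length-3 vectors or n x 3 matrices.
#' @param alpha Maximin weight in `[0, 1]`.
#' @param lam Choice sensitivity, > 0, in 1/JPY.
#' @return Probability (vector) of choosing `option_a`, strictly in (0, 1).
#' @seealso [softmax_prob()] for the low-level rule on utility differences.
#' @export
choice_probability <- function(option_a, option_b, alpha, lam) {
  softmax_prob(utility(option_a, alpha) - utility(option_b, alpha), lam)
}

#' @param du Utility difference `U_A - U_B` in JPY.
#' @rdname choice_probability
#' @export
softmax_prob <- function(du, lam) {
  if (any(lam < 0)) stop("lam must be non-negative")
  stats::plogis(lam * du)   # plogis is overflow-safe for extreme arguments
}

#' Absolute model-utility difference of a choice pair
#'
#' `|U(A) - U(B)|` at a given maximin weight, the trial-level quantity used
#' as a parametric modulator in the utility-comparison analysis. At
#' `alpha = 0` it equals the absolute expected-value difference; at
#' `alpha = 1` the absolute minimum difference.
#'
#' @inheritParams choice_probability
#' @return Non-negative utility difference(s) in JPY, symmetric in option
#'   order.
#' @export
delta_u <- function(option_a, option_b, alpha) {
  abs(utility(option_a, alpha) - utility(option_b, alpha))
}

#' Derive pair-level model quantities for a choice table
#'
#' Adds per-trial minimum/EV summaries and their signed and absolute
#' differences to a choice table in the standard schema (columns `a_low`,
#' `a_mid`, `a_high`, `b_low`, `b_mid`, `b_high`, amounts in JPY).
#'
#' @param choices Data frame with the six outcome columns.
#' @return The input with columns `min_a`, `min_b`, `ev_a`, `ev_b`,
#'   `sdmin` (`min_a - min_b`), `sdev` (`ev_a - ev_b`), `dmin` (`|sdmin|`,
#'   the minimum-difference modulator), `dev` (`|sdev|`), and `min_adv`
#'   (`"a"`, `"b"` or `"tie"`: which option holds the larger minimum).
#' @export
pair_metrics <- function(choices) {
  need <- c("a_low", "a_mid", "a_high", "b_low", "b_mid", "b_high")
  miss <- setdiff(need, names(choices))
  if (length(miss)) stop("missing outcome columns: ", paste(miss, collapse = ", "))
  a <- as.matrix(choices[, c("a_low", "a_mid", "a_high")])
  b <- as.matrix(choices[, c("b_low", "b_mid", "b_high")])
  choices$min_a <- pmin(a[, 1], a[, 2], a[, 3])
  choices$min_b <- pmin(b[, 1], b[, 2], b[, 3])
  choices$ev_a <- rowMeans(a)
  choices$ev_b <- rowMeans(b)
  choices$sdmin <- choices$min_a - choices$min_b
  choices$sdev <- choices$ev_a - choices$ev_b
  choices$dmin <- abs(choices$sdmin)
  choices$dev <- abs(choices$sdev)
  choices$min_adv <- ifelse(choices$sdmin > 0, "a",
                            ifelse(choices$sdmin < 0, "b", "tie"))
  choices
}

# signed utility difference U_a - U_b for every trial, given alpha
signed_du <- function(choices, alpha) {
  alpha * choices$sdmin + (1 - alpha) * choices$sdev
}

#' Negative log-likelihood of observed choices
#'
#' Sum over trials of `-log P(observed choice)` under the quasi-maximin +
#' softmax model. Additive over trials; at `lam = 0` every trial contributes
#' `log 2`. Ties (identical utilities) contribute `log 2` regardless of the
#' choice made.
#'
#' @param choices Choice table with outcome columns and a `choice` column
#'   (`"a"` or `"b"`). Pair metrics are derived if absent.
#' @param alpha Maximin weight in `[0, 1]`.
#' @param lam Choice sensitivity (1/JPY), >= 0.
#' @return Negative log-likelihood in nats (>= 0).
#' @export
negative_log_likelihood <- function(choices, alpha, lam) {
  check_alpha(alpha)
  if (lam < 0) stop("lam must be non-negative")
  if (nrow(choices) < 1L) stop("need at least one choice record")
  if (is.null(choices$sdmin)) choices <- pair_metrics(choices)
  q <- ifelse(choices$choice == "a", 1, -1)
  if (anyNA(q)) stop("choice column must be 'a' or 'b'")
  -sum(stats::plogis(q * lam * signed_du(choices, alpha), log.p = TRUE))
}

# NLL and its gradient wrt (alpha, lam) on precomputed signed differences;
# used by the optimizer. y = +1 when 'a' was chosen.
nll_fast <- function(par, sdmin, sdev, q) {
  du <- par[1] * sdmin + (1 - par[1]) * sdev
  -sum(stats::plogis(q * par[2] * du, log.p = TRUE))
}

nll_grad <- function(par, sdmin, sdev, q) {
  du <- par[1] * sdmin + (1 - par[1]) * sdev
  z <- q * par[2] * du
  w <- -q * stats::plogis(-z)          # d(-log sigma(z))/dz * q-chain
  c(sum(w * par[2] * (sdmin - sdev)), sum(w * du))
}

#' Estimation settings for the choice model
#'
#' @param alpha_bounds,lam_bounds Box constraints on the maximin weight and
#'   the softmax sensitivity. The `lam` lower bound keeps the likelihood
#'   defined for uninformative data; the upper bound caps perfectly
#'   separable (deterministic) choice patterns.
#' @param n_starts Length-2 integer: size of the multi-start grid over
#'   (alpha, lam); `lam` starts are log-spaced.
#' @param refine_top How many of the best grid starts to refine with
#'   bound-constrained quasi-Newton (L-BFGS-B).
#' @param maxit,factr Passed to [stats::optim()]'s L-BFGS-B control.
#' @return A list of class `qm_fit_config`.
#' @export
fit_config <- function(alpha_bounds = c(0, 1),
                       lam_bounds = c(1e-6, 1),
                       n_starts = c(5L, 5L),
                       refine_top = 3L,
                       maxit = 200L,
                       factr = 1e7) {
  stopifnot(length(alpha_bounds) == 2L, length(lam_bounds) == 2L,
            alpha_bounds[1] >= 0, alpha_bounds[2] <= 1,
            lam_bounds[1] > 0, diff(alpha_bounds) > 0, diff(lam_bounds) > 0)
  structure(list(alpha_bounds = alpha_bounds, lam_bounds = lam_bounds,
                 n_starts = as.integer(n_starts),
                 refine_top = as.integer(refine_top),
                 maxit = as.integer(maxit), factr = factr),
            class = "qm_fit_config")
}

start_grid <- function(config) {
  ab <- config$alpha_bounds
  lb <- config$lam_bounds
  a <- seq(ab[1] + 0.05 * diff(ab), ab[2] - 0.05 * diff(ab),
           length.out = config$n_starts[1])
  l <- exp(seq(log(lb[1] * 2), log(lb[2] / 2), length.out = config$n_starts[2]))
  expand.grid(alpha = a, lam = l)
}

#' Maximum-likelihood fit of the quasi-maximin choice model for one subject
#'
#' Estimates the maximin weight and softmax sensitivity from one subject's
#' choices in a single condition by minimizing the negative log-likelihood
#' under box constraints. The NLL is first evaluated on a multi-start grid;
#' L-BFGS-B refinement then runs from the best starts with an analytic
#' gradient, so the reported NLL never exceeds the NLL at any start point.
#'
#' A sensitivity estimate on the upper bound (perfectly separable,
#' near-deterministic data) is returned capped and flagged via
#' `lam_at_bound` rather than treated as an error.
#'
#' @param choices Choice table for one subject and condition (columns
#'   `a_low` ... `b_high`, `choice`); at least 2 trials, with at least one
#'   pair whose options differ.
#' @param config A [fit_config()].
#' @param condition Optional condition label stored in the result (taken
#'   from the data when absent).
#' @return A list of class `qm_fit`: `alpha_hat`, `lam_hat`, `nll`,
#'   `converged`, `lam_at_bound`, `n_trials`, `condition`.
#' @export
fit_subject <- function(choices, config = fit_config(), condition = NULL) {
  if (nrow(choices) < 2L) stop("need at least 2 trials to fit")
  if (is.null(choices$sdmin)) choices <- pair_metrics(choices)
  if (all(choices$dmin == 0 & choices$dev == 0))
    stop("all pairs identical: model unidentifiable")
  if (is.null(condition))
    condition <- if (!is.null(choices$condition))
      as.character(choices$condition[1]) else NA_character_
  sdmin <- choices$sdmin
  sdev <- choices$sdev
  q <- ifelse(choices$choice == "a", 1, -1)

  grid <- start_grid(config)
  gnll <- vapply(seq_len(nrow(grid)),
                 function(i) nll_fast(c(grid$alpha[i], grid$lam[i]), sdmin, sdev, q),
                 numeric(1))
  ord <- order(gnll)
  lower <- c(config$alpha_bounds[1], config$lam_bounds[1])
  upper <- c(config$alpha_bounds[2], config$lam_bounds[2])

  best <- list(par = c(grid$alpha[ord[1]], grid$lam[ord[1]]),
               value = gnll[ord[1]], convergence = 1L)
  for (i in ord[seq_len(min(config$refine_top, nrow(grid)))]) {
    res <- tryCatch(
      stats::optim(c(grid$alpha[i], grid$lam[i]), nll_fast, nll_grad,
                   sdmin = sdmin, sdev = sdev, q = q,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = config$maxit, factr = config$factr)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  structure(list(
    alpha_hat = best$par[1],
    lam_hat = best$par[2],
    nll = best$value,
    converged = identical(best$convergence, 0L),
    lam_at_bound = best$par[2] >= upper[2] - 1e-9,
    n_trials = nrow(choices),
    condition = condition), class = "qm_fit")
}

#' @export
print.qm_fit <- function(x, ...) {
  cat(sprintf(
    "quasi-maximin fit (%s, %d trials): alpha = %.3f, lam = %.4g, NLL = %.3f%s%s\n",
    ifelse(is.na(x$condition), "?", x$condition), x$n_trials,
    x$alpha_hat, x$lam_hat, x$nll,
    if (!x$converged) " [not converged]" else "",
    if (x$lam_at_bound) " [lam at bound]" else ""))
  invisible(x)
}

#' Brute-force grid oracle for the choice-model fit
#'
#' Exhaustive negative-log-likelihood evaluation over supplied parameter
#' grids; returns the grid minimizer. Serves as an independent check of
#' [fit_subject()]: the optimizer's NLL must not exceed the grid minimum.
#'
#' @inheritParams fit_subject
#' @param alpha_grid,lam_grid Non-empty numeric grids.
#' @return A list of class `qm_fit` (with `converged = TRUE`,
#'   `lam_at_bound` relative to the grid maximum).
#' @export
grid_fit_oracle <- function(choices, alpha_grid, lam_grid, condition = NULL) {
  if (!length(alpha_grid) || !length(lam_grid)) stop("grids must be non-empty")
  if (is.null(choices$sdmin)) choices <- pair_metrics(choices)
  if (is.null(condition))
    condition <- if (!is.null(choices$condition))
      as.character(choices$condition[1]) else NA_character_
  q <- ifelse(choices$choice == "a", 1, -1)
  # n_trials x n_alpha matrix of signed utility differences
  du <- outer(choices$sdmin, alpha_grid) +
    outer(choices$sdev, 1 - alpha_grid)
  best <- list(nll = Inf, alpha = NA_real_, lam = NA_real_)
  for (l in lam_grid) {
    nll <- -colSums(stats::plogis(q * l * du, log.p = TRUE))
    j <- which.min(nll)
    if (nll[j] < best$nll) best <- list(nll = nll[j], alpha = alpha_grid[j], lam = l)
  }
  structure(list(alpha_hat = best$alpha, lam_hat = best$lam, nll = best$nll,
                 converged = TRUE,
                 lam_at_bound = best$lam >= max(lam_grid) - 1e-12,
                 n_trials = nrow(choices), condition = condition),
            class = "qm_fit")
}

#' Fit every subject-by-condition cell of a cohort
#'
#' @param choices Cohort choice table with `subject_id` and `condition`
#'   columns in addition to the single-subject schema.
#' @param config A [fit_config()].
#' @return Data frame: `subject_id`, `condition`, `alpha_hat`, `lam_hat`,
#'   `nll`, `converged`, `lam_at_bound`, `n_trials` (the `fits.tsv` schema).
#' @export
fit_cohort <- function(choices, config = fit_config()) {
  stopifnot(!is.null(choices$subject_id), !is.null(choices$condition))
  choices <- pair_metrics(choices)
  cells <- unique(choices[, c("subject_id", "condition")])
  cells <- cells[order(cells$subject_id, cells$condition), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- choices[choices$subject_id == cells$subject_id[i] &
                     choices$condition == cells$condition[i], , drop = FALSE]
    f <- fit_subject(sub, config, condition = cells$condition[i])
    data.frame(subject_id = cells$subject_id[i], condition = f$condition,
               alpha_hat = f$alpha_hat, lam_hat = f$lam_hat, nll = f$nll,
               converged = f$converged, lam_at_bound = f$lam_at_bound,
               n_trials = f$n_trials, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
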