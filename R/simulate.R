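#' Choice-set design settings
#'
#' Controls the generated lottery pairs. The defaults mirror the task
#' structure the analyses assume: 36 pairs per condition, three equiprobable
#' integer outcomes per option, and a majority of "conflict" pairs in which
#' the option with the larger minimum has the smaller expected value —
#' without such min-vs-EV trade-offs the maximin weight is unidentifiable.
#'
#' @param n_pairs Pairs per condition (default 36).
#' @param outcome_range JPY interval outcomes are drawn from.
#' @param rounding JPY granularity of outcomes.
#' @param conflict_fraction Fraction of pairs with a min-vs-EV conflict.
#' @param min_dmin,min_dev Smallest admissible absolute minimum / EV
#'   difference (JPY), keeping the two modulators non-degenerate.
#' @param max_corr Largest admissible `|cor(dmin, dev)|` across the set, so
#'   the two parametric modulators remain separable downstream.
#' @return List of class `design_config`.
#' @export
design_config <- function(n_pairs = 36L, outcome_range = c(0, 2000),
                          rounding = 10, conflict_fraction = 0.75,
                          min_dmin = 30, min_dev = 10, max_corr = 0.5) {
  stopifnot(n_pairs >= 1, conflict_fraction >= 0, conflict_fraction <= 1,
            diff(outcome_range) > 0, rounding > 0)
  structure(list(n_pairs = as.integer(n_pairs), outcome_range = outcome_range,
                 rounding = rounding, conflict_fraction = conflict_fraction,
                 min_dmin = min_dmin, min_dev = min_dev, max_corr = max_corr),
            class = "design_config")
}

draw_lottery <- function(config) {
  sort(round(stats::runif(3, config$outcome_range[1], config$outcome_range[2]) /
               config$rounding) * config$rounding)
}

# TRUE if one option is at least as good on all three rank-ordered outcomes
# and strictly better on one (first-order dominance for equiprobable triples)
is_dominated_pair <- function(a, b) {
  sa <- sort(a); sb <- sort(b)
  (all(sa >= sb) && any(sa > sb)) || (all(sb >= sa) && any(sb > sa))
}

#' Generate a conflict-structured lottery choice set
#'
#' Rejection-samples pairs of three-outcome lotteries subject to: no pair is
#' stochastically dominated; the requested fraction of pairs places the
#' larger minimum and the larger expected value on opposite options; both
#' absolute differences exceed a floor and are not collinear across the set.
#' Deterministic given the RNG state.
#'
#' @param config A [design_config()].
#' @return Data frame: `pair_id`, sorted outcome columns `a_low` ...
#'   `b_high` (low = minimum), and a logical `conflict` flag.
#' @export
generate_lottery_set <- function(config = design_config()) {
  n_conf <- round(config$conflict_fraction * config$n_pairs)
  for (attempt in 1:25) {
    conf <- vector("list", n_conf)
    nonc <- vector("list", config$n_pairs - n_conf)
    got_c <- 0L; got_n <- 0L
    for (try in 1:20000) {
      if (got_c >= n_conf && got_n >= config$n_pairs - n_conf) break
      a <- draw_lottery(config); b <- draw_lottery(config)
      if (is_dominated_pair(a, b)) next
      dmin <- a[1] - b[1]; dev <- mean(a) - mean(b)
      if (abs(dmin) < config$min_dmin || abs(dev) < config$min_dev) next
      if (dmin * dev < 0) {
        if (got_c < n_conf) { got_c <- got_c + 1L; conf[[got_c]] <- c(a, b) }
      } else {
        if (got_n < length(nonc)) { got_n <- got_n + 1L; nonc[[got_n]] <- c(a, b) }
      }
    }
    if (got_c < n_conf || got_n < config$n_pairs - n_conf)
      stop("could not satisfy conflict_fraction/min-difference constraints ",
           "within the sampling budget")
    m <- do.call(rbind, c(conf, nonc))
    ord <- sample.int(config$n_pairs)
    m <- m[ord, , drop = FALSE]
    set <- data.frame(pair_id = seq_len(config$n_pairs),
                      a_low = m[, 1], a_mid = m[, 2], a_high = m[, 3],
                      b_low = m[, 4], b_mid = m[, 5], b_high = m[, 6],
                      conflict = c(rep(TRUE, n_conf),
                                   rep(FALSE, config$n_pairs - n_conf))[ord])
    pm <- pair_metrics(set)
    if (config$n_pairs < 3 ||
        abs(stats::cor(pm$dmin, pm$dev)) < config$max_corr)
      return(set)
  }
  stop("could not achieve |cor(dmin, dev)| < ", config$max_corr,
       " after repeated set generation")
}

# inverse-CDF truncated lognormal in [lo, hi]
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  p <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

#' Simulate one agent's choices over a lottery set
#'
#' Choices are Bernoulli draws from the quasi-maximin + softmax rule at the
#' agent's condition-specific maximin weight; response times are truncated
#' lognormal within the trial deadline.
#'
#' @param pairs Lottery set from [generate_lottery_set()] (or any table in
#'   the outcome-column schema).
#' @param alpha,lam Generating maximin weight and softmax sensitivity.
#' @param condition Condition label attached to every trial.
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (seconds).
#' @param deadline Trial deadline in seconds (30 s behavioral, 5 s fMRI).
#' @param rt_min Lower truncation of response times.
#' @return Choice table: `trial_id`, `condition`, outcome columns, `choice`
#'   (`"a"`/`"b"`), `rt_s`.
#' @export
simulate_choices <- function(pairs, alpha, lam, condition = "Self",
                             rt_meanlog = log(9), rt_sdlog = 0.4,
                             deadline = 30, rt_min = 0.3) {
  pm <- pair_metrics(pairs)
  p_a <- softmax_prob(signed_du(pm, alpha), lam)
  n <- nrow(pm)
  data.frame(trial_id = seq_len(n), condition = condition,
             a_low = pm$a_low, a_mid = pm$a_mid, a_high = pm$a_high,
             b_low = pm$b_low, b_mid = pm$b_mid, b_high = pm$b_high,
             choice = ifelse(stats::runif(n) < p_a, "a", "b"),
             rt_s = rtrunc_lnorm(n, rt_meanlog, rt_sdlog, rt_min, deadline),
             stringsAsFactors = FALSE)
}

# cumulative sums within equal-sized blocks of a trial-major vector
block_cumsum <- function(v, block) {
  cs <- cumsum(v)
  base <- rep(c(0, cs[seq_along(cs) %% block == 0]), each = block,
              length.out = length(v))
  cs - base
}

#' Simulate Mouselab view-event logs for a set of trials
#'
#' Emits, per trial, an ordered non-overlapping sequence of six box views
#' (each option x cell L/M/H) inside `[0, rt]`. The first view's cell
#' follows the configured low-box bias (`M` first with a small independent
#' rate, so the bias is exactly the probability of L among L-or-H first
#' views); total dwell on the larger-minimum option exceeds the other
#' option's by `dwell_min_gain * dmin` in expectation.
#'
#' @param choices Choice table with positive `rt_s` (pair metrics derived if
#'   absent). A `subject_id` column, if present, is carried through.
#' @param first_view_low_bias P(first view is L | first view is L or H).
#' @param first_view_m_rate Independent probability that the first view is M.
#' @param dwell_min_gain Seconds of extra dwell on the larger-minimum option
#'   per JPY of `dmin`.
#' @param dwell_noise_sd SD (s) of trial-level noise on the dwell difference.
#' @param view_fraction Fraction of the response time spent with a box open.
#' @return View-event table: `trial_id`, `condition`, `option`, `cell`,
#'   `onset_s`, `offset_s`, `layout` (`"LMH"`/`"HML"`, alternating every 6
#'   trials).
#' @export
simulate_mouselab <- function(choices, first_view_low_bias = 0.75,
                              first_view_m_rate = 0.1,
                              dwell_min_gain = 4e-4, dwell_noise_sd = 0.3,
                              view_fraction = 0.8) {
  stopifnot(all(choices$rt_s > 0))
  pm <- if (is.null(choices$dmin)) pair_metrics(choices) else choices
  n <- nrow(pm)
  total_view <- view_fraction * pm$rt_s

  # dwell difference (larger-min minus smaller-min option), clipped so both
  # option totals stay positive
  d <- dwell_min_gain * pm$dmin + stats::rnorm(n, 0, dwell_noise_sd)
  d[pm$min_adv == "tie"] <- 0
  d <- pmax(pmin(d, 0.8 * total_view), -0.8 * total_view)
  adv_is_a <- ifelse(pm$min_adv == "tie", stats::runif(n) < 0.5,
                     pm$min_adv == "a")
  dwell_adv <- (total_view + d) / 2
  dwell_a <- ifelse(adv_is_a, dwell_adv, total_view - dwell_adv)
  dwell_b <- total_view - dwell_a

  # six views per trial: (a,b) x (L,M,H); durations split by weighted gamma
  trial <- rep(seq_len(n), each = 6L)
  option <- rep(rep(c("a", "b"), each = 3L), n)
  cell <- rep(c("L", "M", "H"), 2L * n)
  w <- c(L = 0.5, M = 0.15, H = 0.35)[cell] * stats::rgamma(6L * n, shape = 4)
  gsum <- rep(colSums(matrix(w, nrow = 3L)), each = 3L)   # per trial-option
  opt_dwell <- as.vector(rbind(matrix(rep(dwell_a, each = 3), nrow = 3),
                               matrix(rep(dwell_b, each = 3), nrow = 3)))
  dur <- w / gsum * opt_dwell

  # first view: option uniform; cell M at m_rate, else L with the bias
  first_opt <- sample(c("a", "b"), n, replace = TRUE)
  is_m <- stats::runif(n) < first_view_m_rate
  first_cell <- ifelse(is_m, "M",
                       ifelse(stats::runif(n) < first_view_low_bias, "L", "H"))
  first_idx <- (seq_len(n) - 1L) * 6L +
    ifelse(first_opt == "a", 0L, 3L) +
    match(first_cell, c("L", "M", "H"))
  key <- stats::runif(6L * n)
  key[first_idx] <- -1
  ord <- order(trial, key)

  dur_o <- dur[ord]
  # seven inter-view gaps absorb the non-viewing time
  gap_w <- matrix(stats::rgamma(7L * n, shape = 1), nrow = 7L)
  gaps <- t(t(gap_w) / colSums(gap_w) * (pm$rt_s - total_view))
  gap_cum <- apply(gaps, 2, cumsum)
  prev_dur <- block_cumsum(dur_o, 6L) - dur_o
  onset <- gap_cum[cbind(rep(1:6, n), rep(seq_len(n), each = 6L))] + prev_dur

  out <- data.frame(trial_id = pm$trial_id[trial],
                    condition = if (!is.null(pm$condition))
                      pm$condition[trial] else NA_character_,
                    option = option[ord], cell = cell[ord],
                    onset_s = onset, offset_s = onset + dur_o,
                    layout = ifelse(((trial - 1L) %/% 6L) %% 2L == 0L,
                                    "LMH", "HML"),
                    stringsAsFactors = FALSE)
  if (!is.null(pm$subject_id)) out$subject_id <- pm$subject_id[trial]
  out
}

#' Screen layout for gaze simulation and AOI assignment
#'
#' Two non-overlapping rectangles in degrees of visual angle, one per
#' lottery option (left/right of a central fixation cross), each covering
#' its option's three amounts.
#'
#' @param centers Named list of `c(x, y)` centers for `left` and `right`.
#' @param half_width,half_height Rectangle half-extents in degrees.
#' @return List of class `gaze_layout` with `left`/`right` rectangles
#'   (`xmin`, `xmax`, `ymin`, `ymax`) and centers.
#' @export
gaze_layout <- function(centers = list(left = c(-6, 0), right = c(6, 0)),
                        half_width = 4, half_height = 3) {
  rect <- function(c2) c(xmin = c2[1] - half_width, xmax = c2[1] + half_width,
                         ymin = c2[2] - half_height, ymax = c2[2] + half_height)
  l <- rect(centers$left); r <- rect(centers$right)
  if (l["xmax"] > r["xmin"] && r["xmax"] > l["xmin"] &&
      l["ymax"] > r["ymin"] && r["ymax"] > l["ymin"])
    stop("AOI rectangles overlap")
  structure(list(left = l, right = r, centers = centers), class = "gaze_layout")
}

#' Simulate raw gaze samples with ground-truth events
#'
#' Builds, per trial, a piecewise trajectory of fixations on the two option
#' areas joined by bell-shaped-velocity (raised-cosine displacement)
#' saccades, sampled uniformly at `rate`. Fixation time on the side holding
#' the larger-minimum option exceeds the other side by
#' `gaze_min_gain * dmin` in expectation. Ground-truth event boundaries are
#' emitted alongside the samples so classifiers can be validated
#' sample-by-sample.
#'
#' @param choices Choice table with positive `rt_s`.
#' @param layout A [gaze_layout()].
#' @param gaze_min_gain Seconds of extra dwell on the larger-minimum side
#'   per JPY of `dmin`.
#' @param gaze_noise_sd SD (s) of trial-level noise on the dwell difference.
#' @param rate Sampling rate in Hz (eye-tracker nominal 500).
#' @param fix_jitter_sd Per-sample fixational position noise, degrees
#'   (0 gives noiseless traces).
#' @param saccade_dur Saccade duration in seconds.
#' @param n_fix_range Range of fixation counts per trial.
#' @param min_fix_dur Smallest generated fixation duration (s).
#' @return List: `samples` (`trial_id`, `t_s`, `x_deg`, `y_deg`, `valid`),
#'   `events` (ground truth: `trial_id`, `type`, `onset_s`, `offset_s`,
#'   `side`), `sides` (`trial_id`, `side_of_a`).
#' @export
simulate_gaze <- function(choices, layout = gaze_layout(),
                          gaze_min_gain = 4e-4, gaze_noise_sd = 0.2,
                          rate = 500, fix_jitter_sd = 0.004,
                          saccade_dur = 0.04, n_fix_range = c(3L, 6L),
                          min_fix_dur = 0.15) {
  stopifnot(all(choices$rt_s > 0), rate > 0)
  pm <- if (is.null(choices$dmin)) pair_metrics(choices) else choices
  dt <- 1 / rate
  ns_sac <- max(3L, round(saccade_dur * rate) - 1L)  # moving samples
  samples <- vector("list", nrow(pm))
  events <- vector("list", nrow(pm))
  side_of_a <- ifelse(stats::runif(nrow(pm)) < 0.5, "left", "right")

  for (i in seq_len(nrow(pm))) {
    n_fix <- sample(seq(n_fix_range[1], n_fix_range[2]), 1L)
    sides <- rep(c("left", "right"),
                 length.out = n_fix + 1L)[seq_len(n_fix) +
                                            (stats::runif(1) < 0.5)]
    fix_time <- pm$rt_s[i] - (n_fix - 1L) * ns_sac * dt
    if (fix_time < n_fix * min_fix_dur) {
      n_fix <- max(2L, floor(pm$rt_s[i] / (min_fix_dur + saccade_dur)))
      sides <- rep(c("left", "right"), length.out = n_fix)
      fix_time <- pm$rt_s[i] - (n_fix - 1L) * ns_sac * dt
    }
    adv_side <- if (pm$min_adv[i] == "tie") sample(c("left", "right"), 1L)
      else if ((pm$min_adv[i] == "a") == (side_of_a[i] == "left")) "left"
      else "right"
    d <- gaze_min_gain * pm$dmin[i] + stats::rnorm(1, 0, gaze_noise_sd)
    if (pm$min_adv[i] == "tie") d <- 0
    d <- max(min(d, 0.6 * fix_time), -0.6 * fix_time)
    t_adv <- (fix_time + d) / 2
    t_per_side <- c(left = 0, right = 0)
    t_per_side[adv_side] <- t_adv
    t_per_side[setdiff(c("left", "right"), adv_side)] <- fix_time - t_adv
    dur <- numeric(n_fix)
    for (s in c("left", "right")) {
      k <- which(sides == s)
      if (!length(k)) next
      w <- stats::rgamma(length(k), shape = 4)
      dur[k] <- pmax(min_fix_dur, w / sum(w) * t_per_side[s])
    }
    nd <- pmax(round(dur * rate), ceiling(min_fix_dur * rate))

    x <- y <- numeric(0)
    ev <- list()
    t0 <- 0
    for (k in seq_len(n_fix)) {
      ctr <- layout$centers[[sides[k]]]
      fx <- ctr[1] + stats::rnorm(nd[k], 0, fix_jitter_sd)
      fy <- ctr[2] + stats::rnorm(nd[k], 0, fix_jitter_sd)
      x <- c(x, fx); y <- c(y, fy)
      ev[[length(ev) + 1L]] <- data.frame(
        type = "fixation", onset_s = t0, offset_s = t0 + nd[k] * dt,
        side = sides[k], stringsAsFactors = FALSE)
      t0 <- t0 + nd[k] * dt
      if (k < n_fix) {
        from <- layout$centers[[sides[k]]]
        to <- layout$centers[[sides[k + 1L]]]
        frac <- (1 - cos(pi * seq_len(ns_sac) / (ns_sac + 1L))) / 2
        x <- c(x, from[1] + (to[1] - from[1]) * frac)
        y <- c(y, from[2] + (to[2] - from[2]) * frac)
        ev[[length(ev) + 1L]] <- data.frame(
          type = "saccade", onset_s = t0, offset_s = t0 + ns_sac * dt,
          side = NA_character_, stringsAsFactors = FALSE)
        t0 <- t0 + ns_sac * dt
      }
    }
    nsamp <- length(x)
    samples[[i]] <- data.frame(trial_id = pm$trial_id[i],
                               t_s = (seq_len(nsamp) - 1L) * dt,
                               x_deg = x, y_deg = y, valid = TRUE)
    evd <- do.call(rbind, ev)
    evd$trial_id <- pm$trial_id[i]
    events[[i]] <- evd
  }
  list(samples = do.call(rbind, samples),
       events = do.call(rbind, events)[, c("trial_id", "type", "onset_s",
                                           "offset_s", "side")],
       sides = data.frame(trial_id = pm$trial_id, side_of_a = side_of_a,
                          stringsAsFactors = FALSE))
}

#' Simulate a BOLD series from a design matrix
#'
#' `y = X beta + e`, `e ~ N(0, noise_sd^2)` i.i.d. With `noise_sd = 0` the
#' series is the exact linear prediction, so GLM fitting must recover the
#' generating coefficients to machine precision.
#'
#' @param design A design matrix (numeric matrix, or [build_design()]
#'   result).
#' @param betas Coefficient vector conformable with the design columns.
#' @param noise_sd Gaussian noise SD.
#' @return Numeric vector of length `n_scans`.
#' @export
simulate_bold <- function(design, betas, noise_sd = 1) {
  X <- if (is.list(design) && !is.null(design$X)) design$X else design
  if (ncol(X) != length(betas))
    stop("betas (", length(betas), ") do not match design columns (",
         ncol(X), ")")
  as.vector(X %*% betas) + stats::rnorm(nrow(X), 0, noise_sd)
}

#' Population-level settings for cohort simulation
#'
#' Defaults emulate the study conditions the analyses assume: maximin
#' weights well above zero with wide between-subject spread; an
#' empathic-concern score whose correlation with the Other-minus-Self
#' maximin contrast is `rho_empathy` in the generating (Gaussian-copula)
#' model; a stronger low-box first-view bias and a positive dwell gain for
#' the larger-minimum option in the Self condition only; and Self response
#' times slower than Other.
#'
#' @param alpha_self_mean,alpha_self_sd Self-condition maximin weight
#'   distribution (truncated to `[0.02, 0.98]`).
#' @param contrast_sd SD of the Other-minus-Self maximin contrast.
#' @param rho_empathy Generating correlation between empathic concern and
#'   the maximin contrast.
#' @param lam_meanlog,lam_sdlog Lognormal softmax-sensitivity distribution
#'   (1/JPY), shared across conditions within subject.
#' @param empathy_mean,empathy_sd Empathic-concern score distribution
#'   (7-point scale, clipped to `[1, 7]`).
#' @param first_view_low_bias,first_view_m_rate,dwell_min_gain,dwell_noise_sd
#'   Process-tracing generation parameters, named per condition where
#'   applicable (see [simulate_mouselab()]).
#' @param rt_mean Mean response times (s) per condition.
#' @param rt_sdlog Lognormal RT shape parameter.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(alpha_self_mean = 0.42, alpha_self_sd = 0.28,
                            contrast_sd = 0.12, rho_empathy = 0.4,
                            lam_meanlog = log(0.02), lam_sdlog = 0.3,
                            empathy_mean = 4, empathy_sd = 1,
                            first_view_low_bias = c(Self = 0.75, Other = 0.60),
                            first_view_m_rate = 0.1,
                            dwell_min_gain = c(Self = 4e-4, Other = 0),
                            dwell_noise_sd = 0.3,
                            rt_mean = c(Self = 9.49, Other = 8.41),
                            rt_sdlog = 0.4) {
  structure(as.list(environment()), class = "population_spec")
}

#' Simulate a full cohort with ground truth
#'
#' Draws per-subject agent parameters from [population_spec()] (inducing
#' the target empathy/maximin-contrast correlation through a Gaussian
#' copula), generates one shared lottery set, and simulates choices — and
#' optionally Mouselab view logs — for every subject in the Self and Other
#' conditions. Deterministic given `seed`.
#'
#' @param n_subjects Number of simulated participants (behavioral study
#'   scale 60; fMRI scale 24).
#' @param design A [design_config()].
#' @param population A [population_spec()].
#' @param task `"behavioral"` (30 s deadline, Mouselab) or `"fmri"` (5 s
#'   deadline; RT means shrunk to the scanner task's scale).
#' @param views Also generate Mouselab view events?
#' @param seed Optional integer seed.
#' @return List: `pairs`, `choices`, `views` (or NULL), `truth` (per-subject
#'   generating parameters incl. realized `contrast = alpha_other -
#'   alpha_self` and `empathic_concern`).
#' @export
simulate_cohort <- function(n_subjects = 60L, design = design_config(),
                            population = population_spec(),
                            task = c("behavioral", "fmri"),
                            views = FALSE, seed = NULL) {
  task <- match.arg(task)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  p <- population
  deadline <- if (task == "behavioral") 30 else 5
  rt_mean <- if (task == "behavioral") p$rt_mean else c(Self = 2.59, Other = 2.51)
  rt_meanlog <- log(rt_mean) - p$rt_sdlog^2 / 2

  pairs <- generate_lottery_set(design)

  z1 <- stats::rnorm(n_subjects)
  z2 <- p$rho_empathy * z1 + sqrt(1 - p$rho_empathy^2) * stats::rnorm(n_subjects)
  empathy <- pmin(7, pmax(1, p$empathy_mean + p$empathy_sd * z1))
  alpha_self <- pmin(0.98, pmax(0.02,
    stats::rnorm(n_subjects, p$alpha_self_mean, p$alpha_self_sd)))
  alpha_other <- pmin(1, pmax(0, alpha_self + p$contrast_sd * z2))
  lam <- stats::rlnorm(n_subjects, p$lam_meanlog, p$lam_sdlog)

  choices <- vector("list", 2L * n_subjects)
  view_l <- if (views) vector("list", 2L * n_subjects) else NULL
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (cond in c("Self", "Other")) {
      k <- k + 1L
      a <- if (cond == "Self") alpha_self[s] else alpha_other[s]
      ch <- simulate_choices(pairs, a, lam[s], condition = cond,
                             rt_meanlog = rt_meanlog[[cond]],
                             rt_sdlog = p$rt_sdlog, deadline = deadline)
      ch$subject_id <- s
      choices[[k]] <- ch
      if (views) {
        v <- simulate_mouselab(ch,
          first_view_low_bias = p$first_view_low_bias[[cond]],
          first_view_m_rate = p$first_view_m_rate,
          dwell_min_gain = p$dwell_min_gain[[cond]],
          dwell_noise_sd = p$dwell_noise_sd)
        v$subject_id <- s
        view_l[[k]] <- v
      }
    }
  }
  list(pairs = pairs,
       choices = do.call(rbind, choices),
       views = if (views) do.call(rbind, view_l) else NULL,
       truth = data.frame(subject_id = seq_len(n_subjects),
                          alpha_self = alpha_self, alpha_other = alpha_other,
                          contrast = alpha_other - alpha_self, lam = lam,
                          empathic_concern = empathy))
}
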