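# Mouselab information-search analysis: quartile view shares, first-view
# bias, dwell-difference mixed models.

view_keys <- function(views, choices) {
  keys <- intersect(c("subject_id", "condition", "trial_id"),
                    intersect(names(views), names(choices)))
  if (!"trial_id" %in% keys) stop("views and choices must share trial_id")
  keys
}

#' Quartile shares of viewing time on L/M/H cells
#'
#' Splits each trial's decision time (option onset to response) into four
#' equal quartiles and apportions every box view to quartiles by temporal
#' overlap, yielding the percentage of within-quartile viewing time spent
#' on the low, middle and high amounts. A view spanning a quartile boundary
#' is split proportionally. Shares are computed per trial, then averaged
#' across trials (and subjects for `level = "group"`); quartiles with no
#' viewing contribute nothing to the average.
#'
#' @param views View-event table (`trial_id`, `cell`, `onset_s`,
#'   `offset_s`, plus `subject_id`/`condition` when present).
#' @param choices Choice table supplying each trial's decision time `rt_s`.
#' @param level `"trial"`, `"subject"` (average over trials) or `"group"`.
#' @return Long data frame with `quartile` (1-4), `cell` and `share`
#'   (percent; shares over cells sum to 100 within any quartile that has
#'   viewing time), at the requested level of aggregation.
#' @export
quartile_view_shares <- function(views, choices,
                                 level = c("subject", "trial", "group")) {
  level <- match.arg(level)
  keys <- view_keys(views, choices)
  v <- merge(views, choices[, c(keys, "rt_s")], by = keys)
  if (any(v$rt_s <= 0)) stop("zero or negative decision time")
  if (any(v$offset_s <= v$onset_s)) stop("view offsets must exceed onsets")

  q <- lapply(1:4, function(k) {
    lo <- (k - 1) / 4 * v$rt_s
    hi <- k / 4 * v$rt_s
    pmax(0, pmin(v$offset_s, hi) - pmax(v$onset_s, lo))
  })
  long <- do.call(rbind, lapply(1:4, function(k) {
    d <- v[, c(keys, "cell")]
    d$quartile <- k
    d$time <- q[[k]]
    d
  }))
  # per-trial share of each cell within each quartile
  gkey <- c(keys, "quartile")
  tot <- stats::aggregate(time ~ ., data = long[, c(gkey, "time")], sum)
  names(tot)[names(tot) == "time"] <- "total"
  cellt <- stats::aggregate(time ~ ., data = long[, c(gkey, "cell", "time")], sum)
  sh <- merge(cellt, tot, by = gkey)
  sh$share <- ifelse(sh$total > 0, 100 * sh$time / sh$total, NA_real_)
  sh <- sh[, c(gkey, "cell", "share")]
  if (level == "trial") return(sh[order_df(sh, gkey), , drop = FALSE])

  skey <- c(setdiff(keys, "trial_id"), "quartile", "cell")
  sub <- stats::aggregate(share ~ ., data = sh[, c(skey, "share")], mean,
                          na.action = stats::na.omit)
  if (level == "subject") return(sub[order_df(sub, skey), , drop = FALSE])
  gkey2 <- c(setdiff(skey, "subject_id"))
  grp <- stats::aggregate(share ~ ., data = sub[, c(gkey2, "share")], mean)
  grp[order_df(grp, gkey2), , drop = FALSE]
}

order_df <- function(d, cols) do.call(order, d[, cols, drop = FALSE])

#' First-view identity per trial and per-subject counts
#'
#' The earliest view in each trial defines the first-inspected cell. Counts
#' of first views on the low (L) versus high (H) amounts are tallied per
#' subject and condition; first views on the middle amounts (M) are
#' excluded from the L/H comparison but counted, so
#' `n_low + n_high + n_mid = n_trials`.
#'
#' @param views View-event table.
#' @return List: `first_views` (one row per trial with `cell`, `layout`)
#'   and `counts` (per subject x condition: `n_low`, `n_high`, `n_mid`,
#'   `n_trials`).
#' @export
first_view_counts <- function(views) {
  keys <- intersect(c("subject_id", "condition", "trial_id"), names(views))
  o <- do.call(order, c(views[, keys, drop = FALSE], list(views$onset_s)))
  v <- views[o, , drop = FALSE]
  first <- !duplicated(v[, keys, drop = FALSE])
  fv <- v[first, c(keys, "cell",
                   intersect("layout", names(views))), drop = FALSE]
  ckey <- setdiff(keys, "trial_id")
  if (!length(ckey)) ckey <- NULL
  tab <- stats::aggregate(cbind(n_low = fv$cell == "L",
                                n_high = fv$cell == "H",
                                n_mid = fv$cell == "M",
                                n_trials = rep(1L, nrow(fv))),
                          by = fv[, ckey, drop = FALSE], FUN = sum)
  list(first_views = fv, counts = tab)
}

#' Mixed-effects model of the first-view low bias
#'
#' Random-intercept logistic regression (one intercept per subject) of the
#' probability that the first-inspected amount is the low (L) rather than
#' the high (H) one, with fixed effects for condition and display layout;
#' M-first trials are excluded. Estimated by Laplace approximation via
#' lme4; if the random-effect fit fails, a fixed-effects logit is used with
#' a warning. Reported p-values are Wald-z approximations.
#'
#' @param views View-event table covering at least 2 subjects and both
#'   conditions.
#' @param ref_condition Reference level; the condition coefficient is the
#'   log-odds difference of the other condition relative to it.
#' @return List: `coefficients` (term, estimate, se, z, p), `method`
#'   (`"glmm"` or `"glm_fallback"`), `model`.
#' @export
fit_first_view_model <- function(views, ref_condition = "Other") {
  fv <- first_view_counts(views)$first_views
  fv <- fv[fv$cell != "M", , drop = FALSE]
  if (length(unique(fv$subject_id)) < 2L) stop("need >= 2 subjects")
  if (length(unique(fv$condition)) < 2L) stop("need both conditions")
  fv$is_low <- as.integer(fv$cell == "L")
  fv$condition <- stats::relevel(factor(fv$condition), ref = ref_condition)
  fv$layout <- factor(fv$layout)
  fv$subject_id <- factor(fv$subject_id)

  # trials sharing a subject x condition x layout cell have identical
  # covariates, so the binary logit aggregates exactly to a binomial one
  agg <- stats::aggregate(cbind(n_low = fv$is_low, n_trials = rep(1L, nrow(fv))),
                          by = fv[, c("subject_id", "condition", "layout")],
                          FUN = sum)
  fit <- tryCatch(
    lme4::glmer(cbind(n_low, n_trials - n_low) ~ condition + layout +
                  (1 | subject_id),
                data = agg, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    method <- "glmm"
  } else {
    warning("random-intercept logit failed; falling back to fixed-effects logit")
    fit <- stats::glm(cbind(n_low, n_trials - n_low) ~ condition + layout,
                      data = agg, family = stats::binomial())
    co <- summary(fit)$coefficients
    method <- "glm_fallback"
  }
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             z = co[, 3], p = 2 * stats::pnorm(-abs(co[, 3])),
             row.names = NULL) -> tab
  list(coefficients = tab, method = method, model = fit)
}

#' Per-trial dwell difference between larger- and smaller-minimum options
#'
#' @param views View-event table.
#' @param choices Choice table (pair metrics derived if absent).
#' @return One row per trial: total dwell on the larger-minimum option
#'   minus the smaller-minimum option (`dwell_diff`, seconds), `dmin`,
#'   `dev`, `layout`; tie trials (no larger-minimum option) are dropped.
#' @export
dwell_differences <- function(views, choices) {
  pm <- if (is.null(choices$dmin)) pair_metrics(choices) else choices
  keys <- view_keys(views, pm)
  views$dur <- views$offset_s - views$onset_s
  by_opt <- stats::aggregate(dur ~ ., data = views[, c(keys, "option", "dur")],
                             sum)
  wide <- stats::reshape(by_opt, direction = "wide", idvar = keys,
                         timevar = "option")
  wide$dur.a[is.na(wide$dur.a)] <- 0
  wide$dur.b[is.na(wide$dur.b)] <- 0
  layout <- unique(views[, c(keys, "layout"), drop = FALSE])
  d <- merge(wide, pm[, c(keys, "dmin", "dev", "min_adv")], by = keys)
  d <- merge(d, layout, by = keys)
  d <- d[d$min_adv != "tie", , drop = FALSE]
  d$dwell_diff <- ifelse(d$min_adv == "a", d$dur.a - d$dur.b,
                         d$dur.b - d$dur.a)
  d[, c(keys, "layout", "dmin", "dev", "dwell_diff")]
}

#' Mixed-effects regression of dwell differences on pair parameters
#'
#' Random-intercept (per subject) linear model of the trial-level dwell
#' difference (larger-minimum minus smaller-minimum option, seconds) on the
#' absolute minimum difference, the absolute expected-value difference and
#' the display layout, fitted separately per condition. A positive `dmin`
#' slope means larger minimum gaps draw extra viewing to the safer option.
#' p-values are normal approximations on the Wald t; with degenerate
#' between-subject variance the estimates coincide with OLS.
#'
#' @param dwell Output of [dwell_differences()] (or a table with
#'   `subject_id`, `condition`, `dwell_diff`, `dmin`, `dev`, `layout`).
#' @return Named list (one element per condition): `coefficients` (term,
#'   estimate, se, t, p), `method` (`"lmm"` or `"ols_fallback"`), `model`.
#' @export
dwell_difference_model <- function(dwell) {
  if (length(unique(dwell$subject_id)) < 2L) stop("need >= 2 subjects")
  out <- list()
  for (cond in sort(unique(dwell$condition))) {
    d <- dwell[dwell$condition == cond, , drop = FALSE]
    if (stats::var(d$dmin) == 0) stop("dmin is constant: slope unidentifiable")
    d$subject_id <- factor(d$subject_id)
    d$layout <- factor(d$layout)
    form <- if (nlevels(d$layout) > 1L)
      dwell_diff ~ dmin + dev + layout + (1 | subject_id)
    else dwell_diff ~ dmin + dev + (1 | subject_id)
    fit <- tryCatch(
      suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- summary(fit)$coefficients
      method <- "lmm"
    } else {
      fit <- stats::lm(stats::update(stats::formula(
        dwell_diff ~ dmin + dev + layout), . ~ . ), data = d)
      co <- summary(fit)$coefficients[, 1:3, drop = FALSE]
      method <- "ols_fallback"
    }
    out[[cond]] <- list(
      coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                se = co[, 2], t = co[, 3],
                                p = 2 * stats::pnorm(-abs(co[, 3])),
                                row.names = NULL),
      method = method, model = fit)
  }
  out
}
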