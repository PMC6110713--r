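# Velocity/acceleration-threshold classification of gaze samples and
# option-level dwell statistics.

#' Event-classification thresholds
#'
#' Defaults follow the recording setup the analyses assume: a sample
#' belongs to a saccade when its (optionally smoothed) velocity exceeds
#' 30 deg/s or its acceleration exceeds 9500 deg/s^2; runs of non-saccade
#' samples must last more than 100 ms to count as fixations.
#'
#' @param saccade_velocity Velocity threshold, deg/s.
#' @param saccade_acceleration Acceleration threshold, deg/s^2.
#' @param min_fixation Minimum fixation duration, seconds (events of
#'   exactly this duration are discarded: the threshold is strict).
#' @param smooth_window Odd moving-average window (samples) applied to
#'   positions before differentiation; 1 = no smoothing. Smoothing trades
#'   boundary sharpness for noise robustness.
#' @param max_gap Invalid-sample gaps up to this long (s) are linearly
#'   interpolated; longer gaps split the trial into separate segments.
#' @return List of class `event_thresholds`.
#' @export
event_thresholds <- function(saccade_velocity = 30,
                             saccade_acceleration = 9500,
                             min_fixation = 0.1,
                             smooth_window = 1L,
                             max_gap = 0.075) {
  stopifnot(saccade_velocity > 0, saccade_acceleration > 0, min_fixation > 0,
            smooth_window >= 1L, smooth_window %% 2L == 1L)
  structure(list(saccade_velocity = saccade_velocity,
                 saccade_acceleration = saccade_acceleration,
                 min_fixation = min_fixation,
                 smooth_window = as.integer(smooth_window),
                 max_gap = max_gap), class = "event_thresholds")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  sm <- stats::filter(x, k, sides = 2)
  sm <- as.numeric(sm)
  # shrink the window at the ends instead of dropping samples
  h <- (w - 1L) %/% 2L
  for (i in seq_len(h)) {
    sm[i] <- mean(x[1:(i + h)])
    sm[n - i + 1L] <- mean(x[(n - i + 1L - h):n])
  }
  sm
}

central_diff <- function(v, t) {
  n <- length(v)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  d[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  d
}

classify_segment <- function(t, x, y, th) {
  n <- length(t)
  dt <- stats::median(diff(t))
  xs <- moving_average(x, th$smooth_window)
  ys <- moving_average(y, th$smooth_window)
  vel <- sqrt(central_diff(xs, t)^2 + central_diff(ys, t)^2)
  acc <- abs(central_diff(vel, t))
  sacc <- vel > th$saccade_velocity | acc > th$saccade_acceleration

  r <- rle(sacc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fix <- list(); sac <- list()
  for (j in seq_along(r$lengths)) {
    on <- t[starts[j]]
    off <- t[ends[j]] + dt
    if (r$values[j]) {
      sac[[length(sac) + 1L]] <- data.frame(onset_s = on, offset_s = off)
    } else if (r$lengths[j] * dt > th$min_fixation + 1e-9) {
      fix[[length(fix) + 1L]] <- data.frame(
        onset_s = on, offset_s = off,
        centroid_x = mean(x[starts[j]:ends[j]]),
        centroid_y = mean(y[starts[j]:ends[j]]))
    }
  }
  list(fixations = if (length(fix)) do.call(rbind, fix) else
         data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    centroid_x = numeric(0), centroid_y = numeric(0)),
       saccades = if (length(sac)) do.call(rbind, sac) else
         data.frame(onset_s = numeric(0), offset_s = numeric(0)))
}

#' Classify gaze samples into fixations and saccades
#'
#' Velocity/acceleration threshold classification. Positions are optionally
#' smoothed, differentiated by central finite differences, and a sample is
#' marked saccadic when speed or absolute acceleration exceeds its
#' threshold; maximal runs of non-saccadic samples longer than the minimum
#' fixation duration become fixations (shorter runs are discarded), so
#' emitted events are time-ordered and non-overlapping. Invalid samples in
#' gaps up to `max_gap` are interpolated linearly; longer invalid gaps
#' split the recording into independently classified segments. The
#' procedure is deterministic and idempotent.
#'
#' @param samples Data frame `t_s`, `x_deg`, `y_deg`, optional `valid`
#'   flag, and optional `trial_id` (classified per trial when present).
#' @param thresholds An [event_thresholds()].
#' @return List of data frames `fixations` (`onset_s`, `offset_s`,
#'   `centroid_x`, `centroid_y`) and `saccades` (`onset_s`, `offset_s`),
#'   each with `trial_id` when the input had one.
#' @export
classify_events <- function(samples, thresholds = event_thresholds()) {
  if (!is.null(samples$trial_id) && length(unique(samples$trial_id)) > 1L) {
    parts <- lapply(split(samples, samples$trial_id), classify_events,
                    thresholds = thresholds)
    fx <- do.call(rbind, lapply(names(parts), function(id) {
      f <- parts[[id]]$fixations
      if (nrow(f)) f$trial_id <- utils::type.convert(id, as.is = TRUE)
      f
    }))
    sc <- do.call(rbind, lapply(names(parts), function(id) {
      s <- parts[[id]]$saccades
      if (nrow(s)) s$trial_id <- utils::type.convert(id, as.is = TRUE)
      s
    }))
    return(list(fixations = fx, saccades = sc))
  }
  valid <- if (is.null(samples$valid)) rep(TRUE, nrow(samples)) else
    as.logical(samples$valid)
  if (sum(valid) < 3L) {
    warning("fewer than 3 valid samples: no events classified")
    return(list(fixations = data.frame(onset_s = numeric(0),
                                       offset_s = numeric(0),
                                       centroid_x = numeric(0),
                                       centroid_y = numeric(0)),
                saccades = data.frame(onset_s = numeric(0),
                                      offset_s = numeric(0))))
  }
  t <- samples$t_s; x <- samples$x_deg; y <- samples$y_deg
  tv <- t[valid]
  # segment at invalid gaps longer than max_gap, interpolate shorter ones
  gap_after <- c(diff(tv) > thresholds$max_gap +
                   stats::median(diff(tv)) / 2, FALSE)
  seg_id <- cumsum(c(0L, utils::head(gap_after, -1L)))
  fx <- list(); sc <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 3L) next
    ts <- tv[idx]
    # re-grid interpolated samples onto the uniform clock within the segment
    dt <- stats::median(diff(ts))
    grid <- seq(ts[1], ts[length(idx)], by = dt)
    xi <- stats::approx(tv, x[valid], xout = grid, rule = 2)$y
    yi <- stats::approx(tv, y[valid], xout = grid, rule = 2)$y
    ev <- classify_segment(grid, xi, yi, thresholds)
    fx[[length(fx) + 1L]] <- ev$fixations
    sc[[length(sc) + 1L]] <- ev$saccades
  }
  f <- do.call(rbind, fx); s2 <- do.call(rbind, sc)
  if (!is.null(samples$trial_id) && nrow(samples)) {
    if (nrow(f)) f$trial_id <- samples$trial_id[1]
    if (nrow(s2)) s2$trial_id <- samples$trial_id[1]
  }
  list(fixations = f, saccades = s2)
}

#' Assign fixations to option areas of interest
#'
#' Centroid-in-rectangle labeling against the two option AOIs; fixations
#' outside both (including on the central gap) get `"none"`.
#'
#' @param fixations Fixation table from [classify_events()].
#' @param layout A [gaze_layout()].
#' @return The fixation table with an `aoi` column (`"left"`, `"right"`,
#'   `"none"`).
#' @export
assign_aoi <- function(fixations, layout) {
  stopifnot(inherits(layout, "gaze_layout"))
  inside <- function(r) fixations$centroid_x >= r["xmin"] &
    fixations$centroid_x <= r["xmax"] &
    fixations$centroid_y >= r["ymin"] & fixations$centroid_y <= r["ymax"]
  fixations$aoi <- ifelse(inside(layout$left), "left",
                          ifelse(inside(layout$right), "right", "none"))
  fixations
}

#' Option-level dwell from labeled fixations
#'
#' Sums fixation durations per option AOI inside the analysis window
#' (option display onset to the response), clipping fixations that
#' straddle the response time, and maps sides to the larger- and
#' smaller-minimum options of each trial's pair. Trials with equal minima
#' are excluded (flagged), since no larger-minimum option exists.
#'
#' @param fixations AOI-labeled fixation table with `trial_id`.
#' @param choices Choice table (supplies `rt_s` and pair metrics).
#' @param sides Data frame `trial_id`, `side_of_a` mapping option `a` to a
#'   screen side (as emitted by [simulate_gaze()]).
#' @return One row per trial: `dwell_larger_min`, `dwell_smaller_min`
#'   (seconds), `dwell_diff`, `dmin`, `dev`, `excluded` (tie flag).
#' @export
option_dwell <- function(fixations, choices, sides) {
  pm <- if (is.null(choices$dmin)) pair_metrics(choices) else choices
  out <- merge(pm[, c("trial_id", "rt_s", "dmin", "dev", "min_adv",
                      intersect(c("subject_id", "condition"), names(pm)))],
               sides, by = "trial_id")
  out$dwell_left <- 0; out$dwell_right <- 0
  for (i in seq_len(nrow(out))) {
    f <- fixations[fixations$trial_id == out$trial_id[i] &
                     fixations$aoi != "none", , drop = FALSE]
    if (!nrow(f)) next
    dur <- pmax(0, pmin(f$offset_s, out$rt_s[i]) - pmax(f$onset_s, 0))
    out$dwell_left[i] <- sum(dur[f$aoi == "left"])
    out$dwell_right[i] <- sum(dur[f$aoi == "right"])
  }
  adv_side <- ifelse(out$min_adv == "tie", NA_character_,
                     ifelse((out$min_adv == "a") == (out$side_of_a == "left"),
                            "left", "right"))
  out$excluded <- is.na(adv_side)
  out$dwell_larger_min <- ifelse(out$excluded, NA_real_,
                                 ifelse(adv_side == "left", out$dwell_left,
                                        out$dwell_right))
  out$dwell_smaller_min <- ifelse(out$excluded, NA_real_,
                                  ifelse(adv_side == "left", out$dwell_right,
                                         out$dwell_left))
  out$dwell_diff <- out$dwell_larger_min - out$dwell_smaller_min
  out[, c("trial_id", intersect(c("subject_id", "condition"), names(out)),
          "dmin", "dev", "dwell_larger_min", "dwell_smaller_min",
          "dwell_diff", "excluded")]
}
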