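# Model-based fMRI design construction on 1-D series: canonical HRF,
# RT-duration boxcars, mean-centered parametric modulators, discrete-cosine
# high-pass basis, OLS GLM, ROI eigenvariate and gPPI interaction columns.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak 6 s, undershoot 16 s,
#' peak-to-undershoot ratio 6, 32 s support), sampled on the microtime
#' grid `TR / oversampling` and normalized to unit peak. The kernel is 0 at
#' t = 0 and its maximum falls near 5 s.
#'
#' @param TR Repetition time in seconds.
#' @param oversampling Microtime bins per TR.
#' @param length_s Kernel support in seconds.
#' @param peak,undershoot Gamma shape parameters (unit rate) of the
#'   response and undershoot lobes.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return List of class `hrf`: `t` (s), `values`, `dt`.
#' @export
hrf_kernel <- function(TR, oversampling = 16L, length_s = 32,
                       peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(TR > 0, oversampling >= 1)
  dt <- TR / oversampling
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  structure(list(t = t, values = h / max(h), dt = dt), class = "hrf")
}

# discrete-cosine high-pass basis (cutoff in seconds), excluding the
# constant term
dct_highpass <- function(n_scans, TR, cutoff = 128) {
  K <- floor(2 * n_scans * TR / cutoff)
  if (K < 1L) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  s <- seq_len(n_scans)
  X <- sapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * s - 1) * k / (2 * n_scans)))
  colnames(X) <- paste0("hp_", seq_len(K))
  X
}

# convolve a microtime series with the HRF and sample at scan onsets
convolve_downsample <- function(u, hrf, n_scans, oversampling) {
  full <- stats::convolve(u, rev(hrf$values), type = "open")
  full[((seq_len(n_scans) - 1L) * oversampling) + 1L]
}

# microtime boxcar for a set of events (duration 0 -> single-bin impulse)
event_boxcar <- function(onset, duration, weight, dt, n_bins) {
  u <- numeric(n_bins)
  for (i in seq_along(onset)) {
    a <- floor(onset[i] / dt) + 1L
    b <- if (duration[i] > 0) ceiling((onset[i] + duration[i]) / dt) else a
    b <- min(b, n_bins)
    u[a:b] <- u[a:b] + weight[i]
  }
  u
}

#' Build a model-based fMRI design matrix
#'
#' Constructs condition regressors as microtime boxcars (choice conditions
#' carry each trial's response time as duration; the cue condition 1 s; the
#' response condition duration 0) convolved with the canonical HRF and
#' downsampled to the scan grid. Under `model = "GLM1"` a `du`
#' (utility-difference) parametric modulator is added for every event type
#' carrying non-missing `du` values; under `"GLM2"` `dmin` and `dev`
#' modulators likewise. Modulators are mean-centered within their parent
#' condition before convolution (no serial orthogonalization). A
#' discrete-cosine high-pass basis (default cutoff 128 s) and an intercept
#' complete the matrix.
#'
#' @param events Event table: `onset`, `duration`, `trial_type`, and
#'   modulator columns (`du`, `dmin`, `dev`) as required by `model`.
#' @param TR Repetition time (s).
#' @param n_scans Number of volumes.
#' @param model `"none"`, `"GLM1"` (du) or `"GLM2"` (dmin + dev).
#' @param hrf An [hrf_kernel()] (built at `TR` if omitted).
#' @param oversampling Microtime bins per TR.
#' @param hp_cutoff High-pass cutoff in seconds (NULL disables).
#' @return List of class `fmri_design`: `X` (n_scans x p named matrix),
#'   `TR`, `n_scans`, `column_type` (condition / modulator / nuisance /
#'   intercept).
#' @export
build_design <- function(events, TR, n_scans,
                         model = c("none", "GLM1", "GLM2"),
                         hrf = hrf_kernel(TR, oversampling),
                         oversampling = 16L, hp_cutoff = 128) {
  model <- match.arg(model)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  total <- n_scans * TR
  bad <- which(events$onset < 0 | events$onset + events$duration > total)
  if (length(bad))
    stop("events outside the scan window (rows ",
         paste(bad, collapse = ", "), ")")
  dt <- TR / oversampling
  n_bins <- n_scans * oversampling

  mods <- switch(model, none = character(0), GLM1 = "du",
                 GLM2 = c("dmin", "dev"))
  for (m in mods) if (is.null(events[[m]]))
    stop("model ", model, " needs a '", m, "' column")

  cols <- list(); types <- character(0)
  for (tt in unique(events$trial_type)) {
    ev <- events[events$trial_type == tt, , drop = FALSE]
    u <- event_boxcar(ev$onset, ev$duration, rep(1, nrow(ev)), dt, n_bins)
    cols[[tt]] <- convolve_downsample(u, hrf, n_scans, oversampling)
    types <- c(types, "condition")
    for (m in mods) {
      if (anyNA(ev[[m]])) next
      w <- ev[[m]] - mean(ev[[m]])
      um <- event_boxcar(ev$onset, ev$duration, w, dt, n_bins)
      cols[[paste0(tt, "_x_", m)]] <-
        convolve_downsample(um, hrf, n_scans, oversampling)
      types <- c(types, "modulator")
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n_scans, ncol = 0)
  if (!is.null(hp_cutoff)) {
    hp <- dct_highpass(n_scans, TR, hp_cutoff)
    X <- cbind(X, hp)
    types <- c(types, rep("nuisance", ncol(hp)))
  }
  X <- cbind(X, intercept = rep(1, n_scans))
  types <- c(types, "intercept")
  structure(list(X = X, TR = TR, n_scans = n_scans, column_type = types),
            class = "fmri_design")
}

#' Ordinary least-squares GLM fit of a BOLD series
#'
#' @param bold Numeric series of length `n_scans`.
#' @param design An [build_design()] result (or plain named matrix).
#' @return Data frame per column: `term`, `beta`, `se`, `t`, `p`
#'   (two-sided, residual df `n - p`); the residual `sigma` and `df` are
#'   attached as attributes. Rank-deficient designs are an error naming
#'   the collinear columns.
#' @export
fit_glm <- function(bold, design) {
  X <- if (inherits(design, "fmri_design")) design$X else design
  if (length(bold) != nrow(X)) stop("bold length does not match design rows")
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    dropped <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qd, bold)
  res <- bold - as.vector(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qd))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  out <- data.frame(term = colnames(X), beta = as.numeric(beta), se = se,
                    t = tval, p = 2 * stats::pt(-abs(tval), df),
                    row.names = NULL)
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "df") <- df
  out
}

#' First eigenvariate of an ROI's voxel time series
#'
#' First principal component of the column-centered time-by-voxel matrix,
#' scaled so a single-voxel (or identical-voxel) ROI returns its own
#' centered series, and sign-aligned with the ROI mean series.
#'
#' @param Y Numeric matrix, time points x voxels (a vector is treated as
#'   one voxel).
#' @return Numeric summary series of length `nrow(Y)`.
#' @export
roi_eigenvariate <- function(Y) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (all(abs(Yc) < .Machine$double.eps * 100))
    stop("zero-variance ROI time series")
  sv <- svd(Yc, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1] / sqrt(ncol(Y))
  m <- rowMeans(Yc)
  if (sum(e * m) < 0) e <- -e
  e
}

#' Generalized psychophysiological-interaction (gPPI) design
#'
#' Extends the task design with the centered seed (physiological) series
#' and one interaction column per requested condition: the elementwise
#' product of the centered seed and that condition's HRF-convolved,
#' centered task regressor. Interactions are formed at the BOLD level
#' (no neural-level deconvolution). Regressing a target series on this
#' design yields the per-condition connectivity estimates as the
#' interaction betas.
#'
#' @param seed Seed-region summary series (e.g. [roi_eigenvariate()]),
#'   length `n_scans`.
#' @param events Event table as in [build_design()].
#' @param TR,n_scans,oversampling,hp_cutoff As in [build_design()].
#' @param conditions Event types receiving interaction columns.
#' @return An `fmri_design` whose columns append `seed` and
#'   `ppi_<condition>` to the task design.
#' @export
gppi_design <- function(seed, events, TR, n_scans,
                        conditions = c("Self", "Other"),
                        oversampling = 16L, hp_cutoff = 128) {
  if (length(seed) != n_scans) stop("seed length must equal n_scans")
  base <- build_design(events, TR, n_scans, model = "none",
                       oversampling = oversampling, hp_cutoff = hp_cutoff)
  missing_c <- setdiff(conditions, colnames(base$X))
  if (length(missing_c))
    stop("conditions absent from events: ", paste(missing_c, collapse = ", "))
  phys <- seed - mean(seed)
  inter <- sapply(conditions, function(cc) {
    task <- base$X[, cc]
    phys * (task - mean(task))
  })
  colnames(inter) <- paste0("ppi_", conditions)
  keep <- base$column_type != "intercept"
  X <- cbind(base$X[, keep, drop = FALSE], seed = phys, inter,
             intercept = rep(1, n_scans))
  structure(list(X = X, TR = TR, n_scans = n_scans,
                 column_type = c(base$column_type[keep], "physiological",
                                 rep("interaction", ncol(inter)),
                                 "intercept")),
            class = "fmri_design")
}

#' Lay out a scanning session for a set of choice trials
#'
#' Serializes trials into an event table: a 1 s condition cue, a jittered
#' cue-to-option interval, the option display (the choice event, with the
#' trial's response time as duration), a zero-duration response event, and
#' a jittered inter-trial interval. Choice events carry the pair's `dmin`
#' and `dev`, and — when condition-level maximin weights are supplied —
#' the model utility difference `du` evaluated at that condition's weight.
#'
#' @param choices Choice table (pair metrics derived if absent).
#' @param alpha_by_cond Optional named vector of maximin weights per
#'   condition (e.g. group means) used to compute `du`.
#' @param cue_dur Cue duration (s).
#' @param soa,iti Candidate cue-to-option and inter-trial intervals (s),
#'   sampled uniformly per trial.
#' @param display_dur Option display duration (s); the trial advances after
#'   the full display regardless of the response time.
#' @param TR Repetition time used to report the scan count.
#' @return List: `events` (onset, duration, trial_type, du, dmin, dev,
#'   trial_id), `n_scans`, `TR`.
#' @export
session_events <- function(choices, alpha_by_cond = NULL, cue_dur = 1,
                           soa = c(2, 4, 6), iti = c(2, 4, 6),
                           display_dur = 5, TR = 2) {
  pm <- if (is.null(choices$dmin)) pair_metrics(choices) else choices
  n <- nrow(pm)
  rows <- vector("list", 3L * n)
  t <- 0
  for (i in seq_len(n)) {
    cond <- as.character(pm$condition[i])
    du <- if (!is.null(alpha_by_cond) && cond %in% names(alpha_by_cond))
      abs(alpha_by_cond[[cond]] * pm$sdmin[i] +
            (1 - alpha_by_cond[[cond]]) * pm$sdev[i]) else NA_real_
    rows[[3L * i - 2L]] <- data.frame(
      onset = t, duration = cue_dur, trial_type = "cue",
      du = NA_real_, dmin = NA_real_, dev = NA_real_,
      trial_id = pm$trial_id[i], stringsAsFactors = FALSE)
    opt_on <- t + cue_dur + sample(soa, 1L)
    rows[[3L * i - 1L]] <- data.frame(
      onset = opt_on, duration = pm$rt_s[i], trial_type = cond,
      du = du, dmin = pm$dmin[i], dev = pm$dev[i],
      trial_id = pm$trial_id[i], stringsAsFactors = FALSE)
    rows[[3L * i]] <- data.frame(
      onset = opt_on + pm$rt_s[i], duration = 0, trial_type = "response",
      du = NA_real_, dmin = NA_real_, dev = NA_real_,
      trial_id = pm$trial_id[i], stringsAsFactors = FALSE)
    t <- opt_on + display_dur + sample(iti, 1L)
  }
  events <- do.call(rbind, rows)
  n_scans <- ceiling((t + 16) / TR)   # trailing window for the HRF tail
  list(events = events, n_scans = n_scans, TR = TR)
}
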