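---
title: "Modeling risky choices for self and for others: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risky choices for self and for others: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

proxyrisk is a pipeline for studying how people make risky monetary
decisions on behalf of another person, using decisions for oneself as the
benchmark. It covers four measurement levels — binary lottery choices,
Mouselab-style information search, eye movements, and model-based fMRI
regressors — plus the group statistics that tie them together, and ships a
synthetic-data generator that emulates the whole experiment so every stage
can be validated by parameter recovery. This vignette explains the models,
the generator, the numerical choices, and what the validation does and does
not establish.

## The choice model

Each trial offers two lotteries, each with three equiprobable outcomes
(JPY). The quasi-maximin utility of a lottery mixes its worst outcome with
its expected value,

$$U(x) = \alpha \min(\pi_1, \pi_2, \pi_3) + (1 - \alpha)\,\mathrm{EV}(x),
\qquad \alpha \in [0, 1],$$

so $\alpha = 0$ is a risk-neutral expected-value maximizer and $\alpha = 1$
cares only about the worst case. Choices follow a softmax (logit) rule on
the utility difference, $P(A) = \mathrm{logistic}(\lambda\,(U_A - U_B))$,
with sensitivity $\lambda$ in 1/JPY. `fit_subject()` estimates
$(\alpha, \lambda)$ per participant and condition by maximum likelihood.

Choices the estimator makes where the model statement leaves room:

* **Softmax parameterization.** Only "a softmax of the option utilities"
  is fixed by the design; we adopt the standard binary logit with a single
  inverse-temperature $\lambda$ that absorbs the currency scale. Utilities
  stay in raw JPY — rescaling money would only re-parameterize $\lambda$.
* **Per-condition sensitivity.** $\alpha$ is always estimated separately
  for the Self and Other conditions. $\lambda$ is too, as the simplest
  symmetric reading; nothing downstream assumes a shared $\lambda$.
* **Optimization.** Bound-constrained quasi-Newton (L-BFGS-B) on
  $\alpha \in [0, 1]$, $\lambda \in [10^{-6}, 1]$, with an analytic
  gradient. The negative log-likelihood is first scanned on a 5 × 5
  multi-start grid ($\lambda$ log-spaced) and refinement runs from the best
  three starts, so the reported optimum never exceeds any start value.
  `grid_fit_oracle()` provides the brute-force check used throughout the
  tests.
* **Degenerate data.** Uninformative (random) choices drive $\lambda$ to
  its lower bound with NLL $\approx n \log 2$; perfectly separable
  (deterministic) choices cap $\lambda$ at the upper bound and set a
  `lam_at_bound` flag instead of erroring — deterministic simulated agents
  are legitimate test inputs. Tie trials contribute $\log 2$ regardless of
  the response.

Trial-level quantities derived from a pair — $\Delta$Min (absolute
difference of the two minima), $\Delta$EV, and $\Delta U$ at a given
$\alpha$ — feed the information-search regressions and the fMRI
modulators. For $\Delta U$ the convention is to evaluate at the group-mean
$\alpha$ of each condition, mirroring how the utility-comparison analysis
is defined.

## The synthetic cohort: what it emulates

No raw data accompany the study design, so `simulate_cohort()` *is* the
study for validation purposes. Its defaults encode the conditions the
analyses assume:

* **Choice set.** 36 pairs per condition, integer outcomes in
  [0, 2000] JPY rounded to 10 JPY, no stochastically dominated pair, and
  75% "conflict" pairs in which the larger-minimum option has the smaller
  expected value. The conflict fraction is the identifiability engine: with
  no min-vs-EV trade-offs, $\alpha$ drops out of the likelihood. The
  generator also enforces $|\mathrm{cor}(\Delta\mathrm{Min},
  \Delta\mathrm{EV})| < 0.5$ across the set so the two fMRI modulators are
  separable. The actual outcome magnitudes are conventions, configurable in
  `design_config()`.
* **Agents.** Self-condition $\alpha$ is drawn around 0.42 (SD 0.28,
  truncated), matching a cohort whose mean weight sits many standard
  errors above zero; $\lambda$ is lognormal around 0.02/JPY, which puts
  typical $\lambda \Delta U$ values in the informative 0.5–3 range for
  this currency scale.
* **Empathy linkage.** A Gaussian copula couples the empathic-concern
  score (7-point scale) to the Other-minus-Self $\alpha$ contrast at
  $\rho = 0.4$ by default. Because $\alpha$ is clipped to $[0, 1]$ after
  adding the contrast, the realized correlation is exact only before
  clipping; at the default spread the attenuation is small.
* **Information search.** Six box views per trial (option × L/M/H). The
  first view is Low with probability 0.75 (Self) / 0.60 (Other) among
  Low-or-High first views — Middle-first views occur at an independent 10%
  rate, so the bias parameter is exactly the quantity the first-view
  analysis estimates. Dwell on the larger-minimum option exceeds the other
  option by `dwell_min_gain` × $\Delta$Min on average (4 × 10⁻⁴ s/JPY in
  Self, 0 in Other), a linear mean shift with Gaussian trial noise — the
  simplest structure the mixed model can recover.
* **Response times.** Truncated lognormal, Self slower than Other
  (9.49 vs 8.41 s means at the 30 s behavioral deadline; 2.59 vs 2.51 s at
  the 5 s scanner deadline).
* **Gaze.** Fixations alternate between the two option regions with the
  same $\Delta$Min-dependent side bias, joined by 40 ms saccades with a
  raised-cosine (bell-shaped-velocity) displacement profile sampled at
  500 Hz. The raised-cosine profile was chosen over a strict minimum-jerk
  polynomial deliberately: its first and last moving samples already
  exceed the 30°/s threshold, so a threshold classifier can in principle
  agree with the generative boundaries to within one sample, which is the
  standard the classifier is held to. Fixational jitter is white noise
  with 0.004° per-sample SD (≈ 3.5°/s velocity scale, far below
  threshold); it can be set to 0 for noiseless traces.
* **BOLD.** `simulate_bold()` is exactly `y = Xβ + ε` with i.i.d.
  Gaussian noise. Autocorrelated noise is out of scope; the GLM assumes
  white residuals and the calibration tests verify nominal behavior only
  under that assumption.

What passing recovery tests therefore shows: the estimators are correct
for data generated by their own assumed models at realistic scales. What
it does not show: robustness to model misspecification — real RT-dwell
coupling, saccade dynamics, scanner noise spectra, or empathy scales are
all richer than the generator.

## Information-search analysis

`quartile_view_shares()` splits each trial's decision time into four equal
quartiles and apportions every view to quartiles by temporal overlap (a
view spanning a boundary is split proportionally — the natural continuous
rule). Shares are computed per trial, then averaged over trials within
subject, then over subjects; quartiles without viewing are excluded from
averaging rather than treated as zero.

`fit_first_view_model()` is a random-intercept-per-subject logistic model
of P(first view = Low), Low vs High only, with fixed effects for condition
and display layout. Middle-first trials are excluded because the middle
amount is rarely inspected first and the hypothesis concerns the
worst-vs-best contrast. Estimation is by Laplace approximation (lme4);
binary trials are aggregated to binomial counts per subject × condition ×
layout cell first, which leaves the likelihood unchanged and speeds the
fit by an order of magnitude. p-values are Wald-z approximations, named as
such in the output; exact integration and finite-sample df corrections are
not attempted. If the random-effect fit fails the function falls back to a
fixed-effects logit with a warning.

`dwell_difference_model()` regresses the trial-level dwell difference
(larger-minimum minus smaller-minimum option) on $\Delta$Min, $\Delta$EV
and layout, per condition, with subjects as random intercepts — the only
random effect, matching the analysis design. With degenerate
between-subject variance the estimates coincide with OLS (tested). Tie
trials, which have no larger-minimum option, are dropped.

## Gaze-event classification

`classify_events()` implements threshold classification at the recording
parameters: a sample is saccadic when its speed exceeds 30°/s **or** its
absolute acceleration exceeds 9500°/s²; non-saccadic runs longer than
100 ms (strictly) become fixations, shorter runs are discarded.
Differentiation is by central finite differences on position. A
moving-average pre-smooth is available (`smooth_window`) but defaults to
off: smoothing spreads saccade energy into the flanking fixations by
roughly half the window, which destroys sample-level boundary agreement on
clean traces; it is there for genuinely noisy recordings, where boundary
sharpness is already lost. Run durations are computed from sample counts
with a small epsilon so a run of exactly 100 ms (a floating-point knife
edge at 500 Hz) is reliably excluded.

Invalid-sample gaps up to 75 ms are linearly interpolated; longer gaps
split the recording into independently classified segments. Both numbers
are conventions (vendor parsers do not document theirs); the thresholds
themselves are the documented recording parameters.

AOIs are two option-level rectangles with a central gap
(`gaze_layout()`); fixation centroids on the gap map to neither option.
Dwell is fixation time only — saccade samples are never assigned — and
`option_dwell()` clips fixations at the response time, flags tied-minimum
trials, and reports dwell for the larger- and smaller-minimum options.

## Model-based fMRI design

`hrf_kernel()` is the canonical double-gamma (peak 6 s, undershoot 16 s,
ratio 6, 32 s support), peak-normalized, sampled on a microtime grid of 16
bins per TR (TR = 2 s by default). `build_design()` builds boxcars at
microtime — choice conditions with each trial's RT as duration, the cue
condition at 1 s, the response condition as a zero-duration impulse —
convolves with the HRF, and samples at scan onsets. Parametric modulators
($\Delta U$ for GLM1; $\Delta$Min and $\Delta$EV for GLM2) are
mean-centered within their parent condition *before* convolution and are
not serially orthogonalized, matching modern practice; centering alone
makes a constant modulator vanish and keeps the modulator orthogonal to
its parent's mean. High-pass filtering is implemented as a discrete-cosine
nuisance basis with a 128 s cutoff. `fit_glm()` is OLS with t-statistics
on residual df and an explicit rank check that names collinear columns.

`roi_eigenvariate()` summarizes a multi-voxel ROI by the first principal
component of the centered time-by-voxel matrix, scaled so a single-voxel
ROI returns its own centered series and sign-aligned with the ROI mean.
`gppi_design()` forms one interaction column per condition as the
elementwise product of the centered seed series and that condition's
convolved, centered task regressor. This is a BOLD-level interaction
without neural-level deconvolution — a documented simplification of the
generalized PPI approach; with the block-ish designs used here the planted
couplings are recovered without visible bias (tested against ground
truth).

## Group statistics

t-tests wrap the standard implementations with explicit zero-variance
errors. The robust correlation is the percentage-bend correlation
(Wilcox, 1994) with bend 0.2 — the default robust correlation of the R
package named in the analysis design, reimplemented here from the
published algorithm and verified against an independent implementation to
six decimals. Note the percentage-bend *population* functional under
bivariate normality sits slightly below the Pearson $\rho$ (clipping
attenuates extreme standardized scores): at $\rho = 0.5$ it is ≈ 0.47, so
tests compare it to Pearson on the same data rather than to $\rho$ at
sampling precision.

`rm_anova_2x2()` handles the condition × parameter design for the
modulation betas. Both factors are within-subject, so every effect has one
numerator df and is algebraically a squared paired t on the corresponding
per-subject contrast; the implementation computes it that way, which makes
the interaction-equals-squared-t identity exact to rounding. The reported
interaction df are (1, n − 1). A published analysis of this design prints
an interaction with df (2, 46) for n = 24, which is not the df a 2 × 2
within design yields; this package reports its own df and flags the
discrepancy here rather than emulating it. Bonferroni correction is
min(1, m·p). All p-values are two-sided.

## Problem sizes and reproducibility

The validation suite runs the full loops at the study's own scales: 60
subjects × 72 trials for behavioral recovery, 24 for fMRI-style analyses,
200 replicate cohorts for power/calibration claims, 200–500 replicates for
GLM and gPPI calibration. These sizes make the recovery claims meaningful
(power ≥ 80% checks are claims about the *method at that n*, not about a
lucky draw) while keeping a laptop run in minutes. Every generator is
deterministic given a seed, emits its ground truth alongside the data, and
the analysis scripts under `analysis/` record seeds in a run manifest.

## Known limitations

* Estimation is per-subject maximum likelihood; no hierarchical shrinkage
  of $\alpha$, by design.
* The mixed models use Wald-z / normal-approximation p-values; for the
  cell counts used here the approximation is benign, but small-sample df
  corrections are not provided.
* The gPPI columns are formed at the BOLD level; with rapid event-related
  designs and strong HRF nonlinearity a deconvolution-based formulation
  can differ.
* The generator's RT, dwell and gaze processes are mutually independent
  given the trial parameters; real data couple them.
* Alternative utility families (prospect theory, mean-variance) and model
  comparison are out of scope.
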