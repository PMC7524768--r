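---
title: "Estimating the weight human forecasters place on machine advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the weight human forecasters place on machine advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hybridcast analyses hybrid forecasting tournaments: geopolitical-style
questions with 2–5 answer options, a *control* condition forecasting from
historical data alone, and a *treatment* condition that additionally sees a
time-series model's probabilistic forecast. The quantity of interest is the
weight forecasters place on their own prior beliefs versus the machine
advice, and what cognitive factors move that weight.

```{r, message = FALSE}
library(hybridcast)
library(dplyr)
```

## The model

Belief updating follows a DeGroot (convex-combination) rule. A treatment
forecast at time $t$ is

$$y_{i,t} = \alpha\, x_{i,t} + (1-\alpha)\, m_t,$$

where $x_{i,t}$ is the forecaster's unobserved prior, $m_t$ the machine
forecast current that day, and $\alpha \in (0,1]$ the weight on the prior
($\alpha = 1$: machine ignored; $\alpha \to 0$: machine copied). Priors are
not observed, so the control group stands in for them: assuming a
homogeneous population with $X_{i,t} \sim N(\mu_t, \sigma_t^2)$, whose
moments are estimated from the realized control forecasts, the treatment
forecasts are distributed

$$Y_{i,t} \sim N\big(\alpha \mu_t + (1-\alpha) m_t,\; \alpha^2 \sigma_t^2\big).$$

Exposure therefore shifts the mean toward the machine *and* shrinks the
variance by $\alpha^2$ — both effects carried by a single parameter.

Multi-option forecasts are first collapsed onto the probability assigned to
the correct option (a binary projection, only possible retrospectively,
after resolution), which makes the likelihood univariate and avoids
singular covariance matrices on sparse data. $\alpha$ is then estimated per
(question, window, skill stratum) by maximising

$$\ell(\alpha) = \sum_i \log \phi\!\big(y_i;\, \alpha\mu + (1-\alpha) m_i,\,
\alpha^2\sigma^2\big)$$

over $[\varepsilon, 1]$, each treatment forecast paired with the machine
forecast of its own day, and the plug-in prior $(\mu, \sigma^2)$ held fixed
from the control window. The optimizer is a coarse 0.005 grid to locate the
basin followed by bounded scalar optimization, with both bounds checked
explicitly; a 0.001-step grid search is the tested fallback and oracle.

Three modelling choices deserve flagging:

* **The normal model is used on $[0,1]$ data without truncation.** Control
  draws near the boundary are clipped, not re-drawn; the plug-in model
  ignores boundedness. This is a known misspecification, mild as long as
  the group prior stays away from the boundaries.
* **$\alpha$ is bounded below at $\varepsilon = 0.01$**, because the
  likelihood is singular at $\alpha = 0$ (the model variance collapses),
  and above at 1: anti-machine contrarianism ($\alpha > 1$) is outside the
  model.
* **Estimation is population-level**: one $\alpha$ per question-window
  (-stratum), not per individual.

## Windows, filtering, skill

Questions differ enormously in length (the generator draws durations from
$N(53, 33^2)$ days, truncated to $[7, 160]$), so three trailing-window
rules are supported: weekly, a quarter of the question's duration (rounded
up), and their maximum — the default, which keeps short questions on
weekly windows and long sparse ones on quarter windows. Windows advance by
a 7-day stride (non-overlapping for the default weekly length) and any
window with fewer than four forecasts in either condition is discarded.

Skill is assessed on a separate set of machine-free questions (126 in the
generator's default design). Per-question scores are z-scored across users
— the normalization is the package's choice; "rank" and "raw" variants are
exposed — averaged per user, and the better half labelled high-skill, ties
broken by user id. When estimates are stratified, both the prior and the
treatment forecasts are restricted to the stratum.

## Scoring

Accuracy is the Brier score, time-averaged over a question's forecast days.
For ordinal questions the cumulative variant
$\sum_i (P_i - O_i)^2$ on cumulative probabilities is used, so a miss into
an adjacent bin costs less than a distant one; for binary questions it
equals exactly half the density score. Density scores live in $[0,2]$,
ordinal scores in $[0, n-1]$, and both vanish iff the forecast is the
outcome's one-hot.

## The machine forecaster

Machine forecasts come from an automatically selected ARIMA model on each
question's daily historical series. No auto-selection package is assumed:
the differencing order is chosen by a KPSS level-stationarity test (5%
critical value), then $p, q$ by exhaustive corrected-AIC search over a
small grid ($p,q \le 3$ in the standalone module; the tournament generator
uses $p,q \le 2$ because its pre-open histories are 45 points), with ties
resolved toward the smaller model. `stats::arima` is the fitting engine.

Forecasts target the question's resolution day, so the horizon shrinks as
the question ages. Orders and coefficients are selected once on the
pre-open history; the daily update then comes from a single
fixed-coefficient filtering pass over the accrued series plus the standard
ARIMA forecast recursion, with analytic $\psi$-weight variance growth for
the horizon — numerically equivalent to daily refits with frozen
parameters at a fraction of the cost. The predictive normal is discretized
into the answer bins by its CDF mass between bin edges (open tails
outside); a constant series degenerates to a point mass on the containing
bin. The reported 95% interval is `point ± 1.96 sd`.

## The synthetic tournament

The study's raw data is not deposited, so the generator is a first-class
module: it produces the statistical structure the analysis assumes, with
known ground truth, making every downstream stage testable.

* **Questions**: AR(1)-increment series with drift around a random level;
  bins cut at quantiles of the last 30 pre-open days (with an evenly-spaced
  fallback when quantiles collide); resolution by the series value at
  close.
* **Control**: each user-day with Bernoulli(0.5) activity draws its
  correct-option probability from $N(\mu_t, 0.1^2)$ clipped to
  $[0.01, 0.99]$, remaining mass spread uniformly over incorrect options.
  The group mean $\mu_t$ drifts linearly from roughly 0.45 at open toward
  roughly 0.72 at close — priors sharpening toward the truth. Clipping
  rather than truncated sampling mirrors the estimation model's own
  disregard of boundedness.
* **Treatment**: an independent prior draw from the same distribution,
  combined with the same-day machine forecast componentwise — a convex
  combination of simplex points, so treatment forecasts are simplex points
  by construction. The planted weight is either a constant $\alpha^*$
  (default 0.86, a realistic population mean) or linear in planted
  per-question covariates.
* **Machine**: the ARIMA forecaster applied to a noise-corrupted copy of
  the truth series; `noise_frac` and a persistent per-question `bias_sd`
  are the quality knobs, and an `"oracle"` machine (one-hot on the
  resolved option) provides the perfect-advisor limit.
* **Skill questions**: binary, machine-free; each user's correct-option
  probability is drawn around a latent accuracy in $[0.5, 0.9]$.

What the generator does *not* emulate: forecaster attrition and arrival
patterns (activity is a memoryless Bernoulli schedule), per-individual
heterogeneity in $\alpha$, strategic/herding behaviour, and real
geopolitical series pathologies (regime changes, zero inflation). Passing
tests therefore demonstrate that the estimator recovers the model's
parameters when the model holds — not that real forecasters obey the
model.

Within a rolling window the group prior drifts while the plug-in prior is
a single $(\mu, \sigma^2)$; the drift inflates both conditions' pooled
variances comparably, and with the default geometry (≤ 0.3 probability
drift over ~53 days, windows ≤ 14 days, $\sigma = 0.1$) the induced bias
in $\hat\alpha$ is well inside the 0.05 recovery tolerance the tests
enforce.

The variance-comparison validation uses *within-day* variances averaged
per question, so prior drift does not masquerade as dispersion; the model
predicts Var(treatment)/Var(control) $= \alpha^2$. (The source narrative's
prose inverts this relation once and reports a treatment variance larger
than control; the implementation follows the generative model, under which
exposure can only shrink within-day variance.)

## Covariates and regressions

Each retained (question, window, stratum) yields one regression row:
$\hat\alpha$ plus

* **uncertainty** — mean per-option variance of the window's control
  forecasts (sample variance by default);
* **difficulty** — mean per-forecast Brier of the window's control
  forecasts;
* **confirming** — 1 iff the window-mean machine forecast is at least as
  close to the reference group's nearest one-hot "extreme" as the
  reference itself (reference = treatment mean by default, switchable to
  control; ties in the extreme go to the lowest option index);
* **helpfulness** — fraction of control users the machine's window Brier
  beats, ties counting half;
* **lifetime** — elapsed fraction of the question's open period;
* **distance** — mean cumulative-probability Euclidean distance between
  control forecasts and their same-day machine forecast;
* **reputation** — negative mean machine Brier over questions resolved
  before this question opened (no look-ahead; the first questions are
  imputed with the tournament mean and flagged).

Continuous predictors are z-scored over the regression sample; `confirming`
and `skill` stay dummies. The fits are OLS without a global intercept: the
two skill strata enter as cell means, which is the only coding under which
both stratum baselines appear as coefficients. Model 1 is the main-effects
model; Model 2 splits the helpfulness, uncertainty and confirming slopes
by stratum (nested slopes — one coefficient per stratum, replacing those
mains, which is the structure the reported tables imply); Model 3 adds the
distance-by-confirming interaction. Standard errors are classical by
default; window-level cluster-robust errors are a flag. $R^2$ is computed
about the response mean (the uncentered no-intercept $R^2$ would be
misleading).

`simulate_covariate_table()` plants known coefficients in a synthetic
covariate table, building $\alpha$ from the *sample*-z-scored predictors so
the no-noise case is an exact linear model in the regression's own design
matrix: noiseless fits recover the planted coefficients exactly with
$R^2 = 1$, and noisy fits exercise standard-error calibration.

## Counterfactual sweeps

`predict_alpha()` turns a fitted regression into predicted weights (linear
predictor clamped to $[\varepsilon, 1]$); `simulate_exposure()` maps each
*realized* control forecast through the DeGroot rule with those weights —
transforming realized forecasts rather than redrawing priors removes all
Monte-Carlo noise from the comparison. `sweep_coefficient()` perturbs one
coefficient across a grid (default: learned value ± 3 SE in 13 steps; the
grid always contains the learned value, where the change is identically
zero), re-predicts, re-simulates, re-scores, and reports the per-question
percent change in Brier score — positive means less accurate — summarized
by median and IQR within machine-quality strata (question-mean helpfulness
above vs at most 0.5; stratum membership is fixed by the unmodified
helpfulness values, so curves are continuous in the grid). Covariates are
not re-standardized during a sweep.

Two directional properties anchor the framework's sanity: with wrong-leaning
priors and a confidently-wrong (hence confirming, unhelpful) machine,
increasing trust in confirming machines can only worsen the median score;
with a perfect machine, increasing baseline trust in the machine can only
improve it. One wrinkle: a perfect machine has identically-zero reputation
variance, so that covariate drops out of its regression; the baseline
(cell-mean) coefficient then carries the "trust the machine more"
counterfactual.

## Problem sizes and numerical choices

Defaults used by the test-suite studies: tournaments of 50 questions and
30 users per condition (8-question tournaments for fixtures), 20-seed
replications for the variance tests, 100 replicates of 500 rows for
regression calibration. Tolerances: simplex membership 1e-6 on input
(renormalized only when drift exceeds 1e-12, keeping file round trips
bit-exact), 1e-9 for machine bin probabilities, prior variance floored at
1e-6 with a degeneracy flag, optimizer-versus-grid agreement within 0.002.
CSV writers render doubles with 17 significant digits and readers parse
through R's `strtod`, so reader/writer pairs are lossless.

## Limitations

The estimator inherits the model's assumptions: homogeneous priors within
a stratum, normality on a bounded scale, a single population $\alpha$ per
window, and control forecasts as a valid stand-in for treatment priors
(randomization is what licenses this). High estimated $\alpha$ cannot
distinguish confidence in one's prior from distrust of the machine. The
generator's clean structure means test results bound implementation
correctness, not real-world validity.
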