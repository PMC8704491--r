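---
title: "Locating molt-cycle milestones from daily measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating molt-cycle milestones from daily measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltstage)
```

## The problem

In the final (fifth) nymphal instar of locusts, a pulse of ecdysteroid
hormone in the hemolymph initiates the molt to the adult. Measuring that
pulse requires hemolymph sampling, which is invasive and impractical for
scheduling experiments on individual animals. Two externally visible
characteristics change in a stereotyped way over the same days: body
weight rises to a peak and then falls shortly before ecdysis, and the
inter-wing distance (the gap between the wing primordia) grows linearly
and then plateaus. If the timing of these external changes can be
anchored to the timing of the hormone pulse, they become non-invasive
proxies for molt-cycle position.

`moltstage` implements that anchoring as a reusable pipeline: parametric
trajectory models are fitted to daily cohort measurements, milestone time
points are extracted from the fitted curves with propagated
uncertainties, milestones are correlated by subtraction of their fitted
locations, and individual nymphs are classified into stages by simple
threshold rules. Raw longitudinal molt-cycle cohorts of this kind are
rarely deposited publicly, so the package also ships a seeded
synthetic-cohort generator with exactly the parametric structure the
analysis assumes, making every stage of the pipeline testable end to
end.

## The three trajectory models

**Ecdysteroid titer** (pg/µL) over days prior to ecdysis is modeled as a
Lorentzian (area-scaled Cauchy) pulse

$$f(x; A, \mu, \sigma) = \frac{A}{\pi}\,
  \frac{\sigma}{(x-\mu)^2 + \sigma^2},$$

with peak value $A/(\pi\sigma)$ at $x=\mu$ and half width at half maximum
$\sigma$. The hormone-peak milestone is the fitted $\mu$.

**Body weight gain** (g) over the day of instar $x>0$ is modeled as an
area-scaled lognormal density

$$f(x; A, \mu, \sigma) = \frac{A}{\sigma\sqrt{2\pi}}\,
  \frac{\exp\!\left(-\frac{(\ln x - \mu)^2}{2\sigma^2}\right)}{x},$$

which rises from zero, peaks at the lognormal mode
$m=\exp(\mu-\sigma^2)$, and decays. The weight-peak milestone is $m$,
converted to days prior to ecdysis via the (observed) ecdysis day.

**Inter-wing distance** (mm) grows linearly and then stays constant. A
linear branch $b_0+b_1x$ and a plateau $A$ are blended by a logistic
weight $L(x)=1/(1+e^{-a})$, $a=(x-\mu)/\sigma$:

$$f(x) = (b_0 + b_1 x)\,(1-L(x)) + A\,L(x),$$

so $f\to b_0+b_1x$ as $x\to-\infty$ and $f\to A$ as $x\to+\infty$. The
link width $\sigma$ (`sigma_link`) is *fixed*, not fitted: it encodes how
sharp the transition is relative to the measurement cadence, and with
daily sampling there is no information in the data to estimate it. The
default is 0.25 days, configurable. Setting $b_0=b_1=0$ recovers the pure
logistic step $A\,L(x)$ as a special case. The milestone is the fitted
midpoint $\mu$, the time of the shift between the two regimes.

### Time-axis conventions

Two axes coexist. Measurements are taken on the *day-of-instar* axis;
analysis aligns nymphs on the *days-prior-to-ecdysis* axis (positive
before the molt), which removes between-nymph variation in instar
duration for curves tied to the molt date. The Lorentzian is fitted
directly on days prior to ecdysis. The lognormal needs a positive
argument that starts at the instar's origin, so it is fitted on the
day-of-instar axis and converted. The linked model must have its linear
branch *before* the plateau in real time, so the pipeline fits it on
signed time relative to ecdysis, $t=-(\text{days prior})$, and reports
the milestone as $-\hat\mu$ on the days-prior axis. The model functions
themselves are axis-agnostic; only the pipeline fixes these conventions.

### The weight channel is fitted as gain, not absolute weight

Absolute weight contains a baseline (the weight at the start of the
instar) that the lognormal has no parameter for. The pipeline therefore
fits the *gain relative to the first sampled day*, and does so
self-consistently: `model_spec("lognorm", fixed = c(x0 = 4))` makes the
fitted mean $f(x)-f(x_0)$, exactly the model for a series recorded as
increase since day $x_0$. The anchor day itself, whose gain is
identically zero, is dropped from the fit. The peak location
$\exp(\mu-\sigma^2)$ is unaffected by the anchoring.

## Fitting machinery

`fit_model()` minimizes $\sum_i \big((y_i - f(x_i;\theta))/\epsilon_i\big)^2$
with the Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`), with unit
weights when no measurement errors are supplied. The parameter covariance
is $(J^\top J)^{-1}$ from a central-difference Jacobian of the weighted
residuals at the optimum, scaled by the reduced chi-square
$\chi^2_{\rm red}=\chi^2/\mathrm{dof}$ when errors are absent (noise
scale estimated from residuals) and unscaled when they are given.
Non-convergence is reported through an honest `converged` flag, never an
exception; downstream milestone extraction refuses unconverged fits.

Numerical choices worth knowing:

* **Starting values** are data-driven. Lorentzian: peak location at the
  observed maximum (earliest wins on ties), width from the half-maximum
  span. Lognormal: method of moments treating the curve as a density
  over $x$. Linked model: for fixed link width the model is *linear* in
  $(A, b_0, b_1)$, so candidate shift points on a 201-point grid over
  the observation window are each scored by an exact weighted linear
  solve, and optimization starts from the global profile optimum. This
  matters: with daily sampling and a sharp link the likelihood in $\mu$
  is multimodal and nearly flat between sampling days, and a single
  local start occasionally wandered far outside the data window.
* **Bounds.** Scale parameters are bounded positive. The linked model's
  shift point is bounded to the observation window by default: a
  breakpoint outside the sampled days is not estimable from them.
* **Logistic overflow** is avoided by evaluating the link through the
  branch that never exponentiates a positive argument.
* **Tolerances**: `ftol = ptol = 1e-12`, `maxfev = 5000`, so noiseless
  synthetic data are recovered to better than $10^{-6}$ in every
  parameter.
* **Degenerate weights.** Cohort-mean SEMs of zero (noise-free data) or
  undefined SEMs (single-nymph time points) cannot serve as weights; the
  pipeline falls back to unit weights unless every point has a positive
  SEM.

## Milestones, uncertainties and offsets

The hormone peak and the inter-wing midpoint are fitted parameters, so
their standard errors come straight from the fit covariance. The weight
peak is a *function* of fitted parameters, $m = \exp(\mu-\sigma^2)$, and
its standard error follows from the $(\mu,\sigma)$ covariance by the
delta method with gradient $(m, -2\sigma m)$; the package verifies this
first-order propagation against direct Monte-Carlo sampling from the fit
covariance in its test suite. The ecdysis day used in the conversion to
days prior is treated as exactly observed, not estimated.

Milestones are correlated by subtraction: $\Delta = t_a - t_b$ on the
days-prior axis, positive when $a$ precedes $b$. The three fits use
disjoint response variables (titer, weight, inter-wing distance), so
their uncertainties are treated as independent and combine in
quadrature, $\mathrm{se}(\Delta)=\sqrt{\mathrm{se}_a^2+\mathrm{se}_b^2}$.
Nothing is rounded during computation; the reporting layer prints one
decimal day ("2.9 ± 0.1 days prior to ecdysis") and renders offsets with
explicit before/after language.

## Rule-based staging of individual nymphs

Three observable milestones per nymph:

* **N5IW** — first day the inter-wing distance reaches at least 1.8 mm
  (default threshold).
* **N5WD** — first day the weight has dropped by at least 0.1 g below
  the reference. The reference defaults to the *running maximum* of all
  earlier weights, which is robust to a single noisy plateau day; a
  previous-day reference is available as a configuration switch because
  the verbal rule ("weight decreased with at least 0.1 g") does not
  disambiguate the two.
* **N5WP** — the day of maximum weight strictly before the N5WD day;
  ties go to the latest qualifying day, since the peak is understood to
  immediately precede the decrease. N5WP is only assigned when a
  decrease was actually observed.

A day with a missing measurement cannot fire a rule but does not abort
staging; a rule that never fires yields an absent milestone, and cohort
summaries report means only over nymphs where the rule fired, with the
count. Raising the inter-wing threshold can only delay N5IW
(monotonicity), which the test suite checks property-style.

## The synthetic cohort generator

`generate_cohort()` emulates the sampling design the analysis targets: a
cohort of 14 female nymphs measured daily from day 4 of the fifth instar
until the adult molt. Each nymph draws an integer ecdysis day from a
normal distribution (default mean 9, SD 0.8 days, floored at the start
day + 2 so every series has at least three points); noiseless means
follow the three generative curves on their own axes; independent
Gaussian noise is added per measurement (defaults: 0.05 g, 0.1 mm,
4 pg/µL) and values are truncated at zero; missingness is an independent
Bernoulli draw per measurement field. Generation is fully deterministic
given the config and seed, and leaves the caller's RNG state untouched.

Default generative truths place the ecdysteroid peak 2.9 days before
ecdysis (area 130 pg·days/µL, half-width 0.7 days, peak titer
≈ 59 pg/µL), the weight-gain mode at instar day 7.2 — 1.8 days prior at
the mean duration — over a 1.3 g baseline with ≈ 0.9 g peak gain, and
the inter-wing shift 3.1 days prior with a 2.0 mm plateau reached from a
0.25 mm/day rise. These are one consistent, biologically plausible
scenario for a gregarious locust's final instar, chosen once; they are
configuration, not conclusions.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: attrition (a study may synchronize more
nymphs than it follows to ecdysis), assay-specific error structure of
enzyme immunoassays (calibration-curve heteroscedasticity), within-nymph
autocorrelation of measurement errors, diurnal feeding effects on
weight, or any deviation of the true trajectories from the three
parametric families. Results on synthetic cohorts validate the
*machinery* — estimator correctness, calibration, error propagation —
not the biological adequacy of the models.

## The simulation study

`milestone_recovery_study()` repeats the whole estimation chain over
replicate cohorts (200 by default) at the study design and compares each
milestone estimate with its generative truth. Two conventions matter:

* **Weights.** Fits are weighted by the *true* sampling error of each
  cohort mean (configured noise SD over $\sqrt{n}$; the weight-gain
  channel carries $\sqrt{2}\times$ the weight SD because each gain is a
  difference of two noisy weights). Weighting by the estimated SEM at
  $n=14$ would make the weighted mean residual $t$-distributed with
  $E[\chi^2_{\rm red}]\approx (n-1)/(n-3) \approx 1.18$ — a property of
  the plug-in weight, not of the estimator — so calibration is assessed
  where weighting can actually be correct.
* **Truths.** The ecdysteroid and inter-wing truths are the configured
  peak and shift locations. The weight-peak truth of each cohort is its
  *realized* mean ecdysis day minus the lognormal mode: ecdysis days are
  observed data, so the estimator is judged on locating the curve mode,
  not on the cohort's luck in drawing ecdysis days.

Only the inter-wing channel has exactly Gaussian, independent, correctly
weighted errors, so only its reduced chi-square is expected to sit near
1. The ecdysteroid channel's zero-truncated noise makes the nominal SD
an overestimate in the curve tails while the truncated mean sits above
the Lorentzian, and the weight-gain errors are correlated through the
shared day-4 anchor; both per-channel means are still reported, and
their departure from 1 is expected, not a defect. Even the inter-wing
mean tends to fall slightly below 1, because scoring every candidate
breakpoint and keeping the global optimum gives the fit somewhat more
effective flexibility than its nominal parameter count.

The inter-wing midpoint deserves a caveat: with daily sampling and a
0.25-day link the shift point is weakly identified (typical standard
errors near half a day), and cohorts whose transition falls awkwardly
between sampling days can yield very large reported standard errors —
honest Wald uncertainty in a flat likelihood direction, and the reason
the observed-window bound on $\mu$ exists.

Problem sizes used throughout the package's own checks — 200 replicate
cohorts for recovery, $10^5$ draws for Monte-Carlo propagation oracles,
1000 replicate fits for interval-coverage checks — were chosen as the
smallest sizes at which Monte-Carlo error is comfortably below the
effect sizes being checked.

## Known limitations

* The three parametric families are assumptions; no goodness-of-fit
  model selection is offered, only $\chi^2_{\rm red}$ reporting.
* Milestone uncertainties ignore uncertainty in the ecdysis day and any
  correlation between channels measured on the same animals.
* The inter-wing midpoint is intrinsically poorly localized by daily
  sampling when the link is sharp; sub-daily sampling or a wider
  configured link would be needed for tighter inference.
* Staging thresholds (1.8 mm, 0.1 g) are instrument- and
  population-specific conventions, exposed as configuration.
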