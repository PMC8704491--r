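# moltstage

Molt-cycle milestone estimation and staging for fifth-instar locust
nymphs.

In the final nymphal instar of locusts, a pulse of ecdysteroid hormone in
the hemolymph initiates the molt to the adult, roughly three days before
ecdysis. Measuring that pulse is invasive; two external characteristics —
body weight and the inter-wing distance (the gap between the wing
primordia) — change in a stereotyped way over the same days and can serve
as non-invasive proxies, *if* their timing can be anchored to the hormone
pulse. `moltstage` does that anchoring for cohort data and is aimed at
insect physiologists who need to schedule dissections, gland explants or
injections at defined molt-cycle positions.

## What it computes

Three trajectory models are fitted by weighted nonlinear least squares
(Levenberg–Marquardt, with reduced chi-square reporting):

* ecdysteroid titer vs. days prior to ecdysis, as a Lorentzian
  `f(x) = (A/π) σ / ((x−µ)² + σ²)` — the hormone peak is `µ`;
* body-weight gain vs. day of instar, as an area-scaled lognormal
  `f(x) = A/(σ√(2π)) · exp(−(ln x − µ)²/(2σ²)) / x` — the weight peak is
  the mode `exp(µ − σ²)`;
* inter-wing distance, as a linear branch and a constant plateau blended
  by a logistic link of fixed width — the milestone is the sigmoid
  midpoint `µ` of the shift.

Milestone uncertainties are propagated from the fit covariances (delta
method for the lognormal mode); milestones are correlated by subtraction
of the fitted `µ` values with quadrature-combined standard errors.
Individual nymphs are additionally staged by threshold rules: N5IW
(inter-wing distance ≥ 1.8 mm), N5WP (weight peak) and N5WD (weight drop
≥ 0.1 g). A seeded synthetic-cohort generator reproduces the sampling
design (14 female nymphs measured daily from day 4 of the instar until
the adult molt), so the whole pipeline is testable without deposited raw
data; `read_cohort()` runs the identical pipeline on measured CSV data.

See `vignettes/milestone-estimation.Rmd` for the models, conventions and
design choices in full.

## Worked example

```r
library(moltstage)

run <- run_pipeline(run_config(cohort_config(seed = 17)))
cat(render_report(run), sep = "\n")
```

```
Molt-cycle milestone report
  mode: simulated | seed: 17 | config: ff5bfbce | moltstage 0.1.0

Fits:
  ecdysteroid  lorentzian             chi2_red = 0.759, dof = 4
  inter_wing   linked_linear_constant chi2_red = 0.292, dof = 3
  weight       lognorm                chi2_red = 0.94, dof = 3

Milestones (days prior to ecdysis):
  ecdysteroid_peak  2.9 ± 0.0 days prior to ecdysis
  weight_peak       2.1 ± 0.0 days prior to ecdysis
  iw_midpoint       3.4 ± 0.4 days prior to ecdysis

Offsets:
  ecdysteroid_peak 0.8 ± 0.0 days before weight_peak
  iw_midpoint 0.4 ± 0.4 days before ecdysteroid_peak
  iw_midpoint 1.3 ± 0.4 days before weight_peak

Staging summary (rule-based, per nymph):
  N5IW  n = 14  3.6 ± 0.1 days prior to ecdysis
  N5WP  n = 12  2.3 ± 0.2 days prior to ecdysis
  N5WD  n = 12  1.0 ± 0.2 days prior to ecdysis
```

Reading this: the fitted Lorentzian locates the hormone peak 2.9 days
before the molt in this simulated cohort; the fitted weight-gain curve
peaks 2.1 days before the molt, i.e. 0.8 days *after* the hormone peak;
the inter-wing shift point is localized only to ±0.4 days (daily sampling
resolves a sharp transition poorly — see the vignette). The staging block
shows, per rule, how many of the 14 nymphs fired it and the mean timing:
e.g. 12 nymphs showed a ≥ 0.1 g weight drop, on average 1.0 days before
ecdysis. Reduced chi-square values near 1 indicate fits consistent with
the measurement scatter. Passing `out_dir =` to `run_config()` writes
`cohort.csv`, per-axis means, per-fit JSON, `milestones.json`,
`offsets.tsv`, `staging.tsv` and `report.txt`.

A thin command-line wrapper is included at `inst/cli/moltstage.R`
(`simulate`, `run`, `stage` subcommands).

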