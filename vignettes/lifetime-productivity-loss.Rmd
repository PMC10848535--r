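---
title: "Estimating lifetime employment and productivity loss: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime employment and productivity loss: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeprod)
```

## The estimand

For a cohort `c` observed from diagnosis (month `t = 0`), let `S(t|c)` be the
probability of surviving beyond month `t`, `E(t|c)` the employed fraction of
members alive at `t` (the conditional EMRATIO), and `N(t|c)` the mean insured
monthly wage of members alive at `t`, with unemployed survivors contributing
zero. Over a horizon `L` long enough that survival is exhausted,

$$\mathrm{ELED}_c = \sum_{t=0}^{L} S(t|c)\,E(t|c), \qquad
  \mathrm{ELN}_c = \sum_{t=0}^{L} S(t|c)\,N(t|c),$$

are the expected lifetime employment duration (months) and expected lifetime
earnings. Both are algebraic identities of the corresponding individual-level
means on a fully observed cohort: `ELED` equals the average number of
employed person-months per patient, which is what makes the decomposition
into survival and conditional curves useful — each factor can be estimated
and extrapolated separately. The losses of a diseased index cohort `i`
against its matched reference cohort `r` are
`LLED = ELED_r - ELED_i` and `LLEP = ELN_r - ELN_i`, reported per stratum
both absolutely and relative to the reference. The annual-earnings ratio,
`(ELN_i/ELED_i) / (ELN_r/ELED_r)`, compares productivity *per employed
year*; a value below 100% among survivors who do work is the package's
wage-based proxy for presenteeism.

Employment and wages are defined to be zero from the statutory retirement
age (default 65) onward, for both cohorts: the estimand is working-life
production, not post-retirement income.

### Conventions on the monthly grid

A patient dying in month `m` has a trajectory record at `t = m`, but the
alive set at month `t` contains only patients who *survive* month `t`
(deaths leave in their event month; censored patients remain through their
last observed month — the usual deaths-before-censorings tie-break). With
this convention the Kaplan–Meier step function evaluated at `t` equals
`M_t/N` exactly in the absence of censoring, and the survival-weighted sums
above reproduce the individual-level means to machine precision (this is
asserted in the test suite at `1e-9` relative error). Life expectancy is
`sum_{t>=1} S(t) + 0.5` months; the half-month centres the discrete sum,
matching the expectation of a death occurring mid-month.

## Reference cohort

Each index patient is matched to one deterministic referent of the same sex
`s`, onset age `a` (whole years), and diagnosis year `y`. The referent's
survival comes from the national life table: the annual death probability
`q(y + floor(t/12), a + floor(t/12), s)` is converted to a constant monthly
hazard `-log(1-q)/12` within each life-table year — the standard actuarial
choice — and cumulated. The referent's life expectancy `T_i` is the sum of
its monthly survival probabilities over the horizon.

The reference conditional EMRATIO at month `t` averages the employment-table
lookups `e(y + floor(t/12), a + floor(t/12), s)` over referents with
`t <= T_i`; the denominator counts exactly those referents. This
life-expectancy cutoff is the construction the framework prescribes; a
survival-weighted alternative (each referent weighted by `S_i(t)` instead of
the hard `T_i` cutoff) is available via `alive_rule = "survival"` in the
configuration. The two agree closely for homogeneous strata; the cutoff rule
is the default because it is the documented construction.

The wage table is a *population-average* wage (total salary over the
civilian population), so it already embeds the employment ratio and is
averaged as-is — it is **not** multiplied by `e(y,a,s)`. This makes the
reference earnings curve directly comparable to the index cohort's
conditional earnings, which likewise average zeros for unemployed survivors.

Referents are expected-value constructs, not Monte-Carlo individuals: the
reference curves are deterministic functions of the tables, which removes
simulation noise from every comparison.

## Survival extrapolation

Within follow-up the index survival is the weighted product-limit estimate
on the monthly grid (via `survival::survfit`, so bootstrap case weights are
exact). Beyond the end of follow-up `F` the curve is extended through the
relative survival ratio `W(t) = S(t|i)/S(t|r)`:

1. clip `W` into `[eps, 1 - ratio_ceiling]` and take logits;
2. for each `t > F` in turn, fit a straight line in `t` to the most recent
   `window` months of logit `W` (observed or previously extrapolated),
   predict one month ahead, invert the logit, multiply by `S(t|r)`;
3. enforce monotone non-increase by capping at `S(t-1)`.

The rationale: under proportional excess mortality the logit of the relative
survival ratio is smooth and asymptotically linear in `t`, so a local linear
trend extrapolates it stably, while multiplication by the reference curve
re-imposes the background mortality structure.

### Numerical safeguards, and why they matter

Two parameters deserve explanation because naive choices fail in a way only
visible in null calibration:

- **`ratio_ceiling` (default `1e-3`)** — the upper clip of `W` is
  `1 - ratio_ceiling`, separate from the numerical guard `eps = 1e-6` used
  for logit/log transforms elsewhere. An excess-mortality cohort cannot
  outlive its reference, so `W > 1` is sampling noise; if it were clipped at
  `1 - 1e-6`, months where the Kaplan–Meier estimate wobbles above the
  reference produce logit values of `±13.8` sitting next to typical values
  around 6, and the fitted window slope becomes erratic enough to collapse
  the extrapolated curve. A ceiling on the model's own scale flattens that
  noise instead.
- **`window` (default `NULL` = `max(24, F/4)` months)** — under the null
  (index identical to reference) logit `W` is a random walk, and a fixed
  24-month local slope at `F = 210` months is noise-dominated; because the
  one-step-ahead recursion reproduces its own line, whatever slope is fitted
  at `F` persists across the entire extrapolation. Scaling the window with
  the observed history makes the fitted trend an average over a quarter of
  follow-up, which suppresses spurious drift while leaving genuinely sloped
  (excess-hazard) ratios intact. With a short follow-up the window stays at
  the conventional 24 months, which is also what the closed-form
  exponential oracle in the test suite uses.

Both are configurable; `window = 24` reproduces the fixed-window variant.

## Hazard ratio and the link regressions

Monthly hazards `h(t) = -log(S(t)/S(t-1))` of the (extrapolated) index and
reference curves are smoothed with a centred moving average
(`smooth_width = 12` months, partial windows at the edges) and their
quotient, clipped into `[eps_hr, 1/eps_hr]` with `eps_hr = 1e-3`, is the
hazard-ratio curve `HR(t)`. Raw monthly hazards of a cohort of a few
thousand are far too noisy for a stable quotient, hence the smoothing; a
single proportional-hazards constant (cumulative-hazard ratio at `F`) is
available via `hr_single = TRUE` for users who prefer a scalar summary. The
quotient-of-smoothed-hazards estimator was chosen over a Cox fit because the
downstream regression needs `HR` as a *curve* over all `t`, including the
extrapolated region where no individual-level data exist.

The Cox-type derivation linking mortality and employment motivates a linear
relation between the transformed difference of conditional curves and the
log hazard ratio,

$$E_d(t) = g(E(t|i)) - g(E(t|r)) = \beta_0 + \beta_1 \log HR(t) + \varepsilon_t,$$

with `g = logit` for the EMRATIO and `g = log` for earnings. Average-age and
sex-composition covariates of the underlying hazard model are absorbed into
the intercept, i.e. treated as approximately time-constant over the fitting
window — the model offers no way to estimate them separately from aggregate
curves, and within a single sex-by-age stratum their variation is second
order. Ordinary least squares, unweighted (no rationale exists for
differential month weights), over the unmasked months of `[a, F]` with
`a = ceiling(F/2)` by default: the later half of follow-up reflects the
mature relation between the curves, while early months mix in short-term
post-diagnosis dynamics. `reg_start` overrides `a`. Months where the
reference value is structurally zero (post-retirement) are excluded; a
regressor with (numerically) zero variance triggers an intercept-only fit
with a warning. Beyond `F`,

$$\hat E(t|i) = \mathrm{expit}\{\mathrm{logit}(\hat E(t|r)) + \hat\beta_0 +
  \hat\beta_1 \log \widehat{HR}(t)\},$$

and the log-link analogue for earnings; the links guarantee the extrapolated
EMRATIO stays in `[0,1]` and earnings stay non-negative, and months where
the reference is zero are forced to zero.

**Masked months.** Months within follow-up whose at-risk count falls below
`min_at_risk` (default 50, a published registry convention for suppressing
unstable tail ratios) carry no observed value. They never enter the
regression. In the assembled lifetime curve they are *filled with the model
prediction* — the same formula used beyond `F` — and flagged
`source = "filled"`: leaving them empty would make the lifetime sums
undefined, and carrying the unstable raw ratio forward would defeat the
purpose of the mask.

## Uncertainty

Intervals are nonparametric patient-level bootstrap percentiles
(`boot_b = 200` by default, level 95%): patients are resampled with
replacement, and the entire pipeline — referent weighting, weighted
Kaplan–Meier, extrapolation, link fits, lifetime sums — is re-run per
resample as a weighted computation on precompiled per-stratum matrices.
Rate tables are treated as fixed external quantities. The reported point
estimate is always the full-sample estimate. Percentile intervals from
skewed resampling distributions can, in edge cases, exclude the point
estimate; this is detected and warned about rather than hidden. Replicates
in which a stratum loses all members or the link regression becomes
infeasible are dropped and counted. Analytic (delta-method) variances are
out of scope: the pipeline is far too nonlinear for them to be honest.

## The cohort simulator

The simulator generates what the estimators consume, with known truth:

- **Reference tables**: Gompertz annual mortality per sex
  (`b exp(g (a - 25))`, defaults `b = 6e-4, g = 0.085` for men and
  `3e-4, 0.090` for women — population-scale, not disease-scale, hazards)
  with a mild 0.5%/year calendar improvement; a hump-shaped employment
  ratio peaking at age 52 (0.85 men / 0.78 women, Gaussian widths 30 rising
  / 10 falling), zero from 65; a hump-shaped population-average wage peaking
  at 44 (TWD 42,000) for men and 50 (TWD 31,950) for women. Shapes and
  peaks echo the published registry profiles (employment maximal in the
  51–55 band; wages peaking at 44/50); the levels are round numbers of the
  right magnitude, not transcriptions.
- **Index cohort**: death months drawn from the reference hazard times a
  proportional excess multiplier `theta` (default 2.5), with certain death
  by age 100. Monthly employment follows a two-state chain whose marginal
  equals the reference profile deflated by an employment penalty (default
  0.7) *exactly*: each month the patient follows, with probability
  `persistence = 0.9`, the maximal coupling toward the new target marginal,
  and otherwise an independent redraw — both branches preserve the
  marginal, so the estimand is known in closed form while employment spells
  remain serially correlated. Wages of employed months are the per-worker
  reference wage (population-average over employment ratio) times a wage
  penalty (default 0.8) and an individual lognormal frailty (mean 1, log-sd
  0.5). Employment and wages are zero in the death month and from age 65.
- **Truth**: index-side truth is the exact mean over the generated full
  lifetimes; reference-side truth is the exact expectation over the matched
  life-table survival curves. `truncate_followup()` then creates the
  estimation problem by cutting trajectories at an administrative `F`
  (default 210 months, the span of an 18-year registry window) and marking
  survivors censored.

What the simulator does *not* emulate: heterogeneous individual mortality
frailty, employment-dependent death hazards (employment and survival are
independent given the profile), wage growth over calendar time, re-entry
dynamics richer than a first-order chain, and enrolment gaps. Passing the
end-to-end tests therefore demonstrates that the estimators recover the
declared generative quantities under proportional excess mortality — not
that every feature of real registry data is captured.

Diagnosis years are uniform on 2000–2017 and the simulated life tables stop
in 2017, as registry tables do; estimation therefore runs with
`carry_forward = TRUE`, which reuses the last covered calendar year (and the
last covered age row) for lookups beyond the table. With carry-forward off,
out-of-range lookups are an error — the appropriate default for real data,
where silently reusing old tables should be a conscious choice.

## Validation experiments and problem sizes

The test suite and acceptance script validate, among unit-level oracles:

- the survival-weighted-sum identity on a fully observed cohort
  (N = 2,000, relative error below `1e-9`);
- a closed-form exponential oracle (index hazard 0.03/month vs reference
  0.01/month, `F = 60`, horizon 600): extrapolated life expectancy within
  5% of `1/0.03` months;
- an identity-cohort null (`theta = 1`, no penalties, N = 5,000 in the
  25–34 male stratum, `F = 210`): estimated relative LLED and LLEP within
  ±5 percentage points of zero, per seed and on average over 20 seeds;
- parameter recovery under the default disease scenario (`theta = 2.5`,
  penalties 0.7/0.8, N = 5,000, `F` at the 40th percentile of death times):
  mean absolute relative error at most 10% for ELED/ELN and 15% for
  LLED/LLEP over 20 seeds — and a harder variant with `F = 210`, where most
  of the pre-retirement employment curve is extrapolated;
- bootstrap coverage: 95% intervals cover the true index ELED in at least
  90% of 50 simulation replicates at N = 1,000, B = 200.

Single-stratum scenarios are used so each experiment isolates one regime:
the youngest band (25–34) maximises the extrapolated span, the middle band
(46–50) is used where follow-up should largely cover working life. These
sizes are the package's validation design; larger runs only tighten the
Monte-Carlo error around the same conclusions.

## Known limitations

- The link regressions assume the intercept absorbs slowly varying
  composition effects; strata mixing very different ages would violate this,
  which is one reason the stratification is part of the method.
- Insured wages exclude bonuses and non-market output, so productivity
  levels are conservative; relative losses are the robust quantities.
- The `T_i`-cutoff alive-set rule makes the reference conditional curves
  slightly blocky for small strata; the survival-weighted alternative is
  smoother but is not the documented default.
- No discounting is applied to future earnings, by design; users wanting
  present values should discount the monthly products before summation.
- Extrapolation quality degrades when follow-up contains almost no deaths
  (the hazard-ratio curve is then noise); the null-calibration safeguards
  above bound, but cannot eliminate, this.
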