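---
title: "Noncompartmental PK analysis and bioanalytical validation with ncaval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noncompartmental PK analysis and bioanalytical validation with ncaval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncaval)
```

## What the package computes

`ncaval` analyses intravenous-bolus plasma concentration–time data by
noncompartmental analysis (NCA) and computes the full set of statistics used
to validate a chromatographic bioanalytical assay. The motivating setting is
a small-rodent pharmacokinetic study of doxorubicin: a 5 mg/kg IV bolus,
serial micro-volume plasma samples at 5 min, 0.25, 0.5, 1, 2, 4, 6, 8, 10,
12, 24 and 48 h, six animals, an HPLC assay with a 5–1000 ng/mL calibration
range, a 5 ng/mL lower limit of quantification (LLOQ) and 10-fold dilution of
above-range samples. No raw data from such a study are shipped; a synthetic
generator reproduces the statistical structure the analysis assumes, so that
every stage is testable.

## The noncompartmental model

For a profile with usable observations $(t_i, C_i)$ the package computes:

* **Terminal rate constant** $\lambda_z$ (the elimination constant $K$):
  ordinary least squares of $\ln C$ on $t$ over the terminal log-linear
  region; $\lambda_z = -\text{slope}$.
* **Half-life** $t_{1/2} = 0.693 / \lambda_z$. The literal constant 0.693 is
  used rather than $\ln 2 = 0.693147\ldots$, matching the conventional
  reporting formula; the difference is below 0.03 % and is documented here
  deliberately.
* **AUC** by the trapezoidal rule, with the tail $C_\mathrm{last}/\lambda_z$
  extrapolating to infinity: $AUC_{0-\infty} = AUC_{0-t_\mathrm{last}} +
  C_\mathrm{last}/\lambda_z$.
* **AUMC**, the area under $C \cdot t$ versus $t$, with tail
  $C_\mathrm{last} t_\mathrm{last}/\lambda_z + C_\mathrm{last}/\lambda_z^2$.
* **MRT** $= AUMC / AUC_{0-\infty}$, **clearance** $= \mathrm{Dose} /
  AUC_{0-\infty}$, and the steady-state volume of distribution (below).

Concentrations enter in ng/mL and times in hours; concentrations are divided
by 1000 before integration so AUC is reported in µg·h/mL, and with the dose
in µg/kg clearance comes out in mL·kg⁻¹·h⁻¹.

### Terminal-window selection

Which points form "the terminal log-linear region" is a modelling decision
that source reports rarely state. The default is the de-facto pharmacometric
convention: every suffix of at least three usable points that excludes the
global concentration maximum is fitted, and the window with the highest
adjusted $r^2$ wins, ties (within $10^{-9}$) broken toward the longer
window. When fewer than three points lie strictly after the peak — e.g. a
three-point monotone decline — the window is allowed to start at the peak
itself, since for a bolus the first sample usually *is* the maximum. A
manual window `c(t_start, t_end)` overrides the search. Observations flagged
below the LLOQ, and non-positive concentrations, never enter the regression
or the integration: censored values are excluded, not zeroed, which keeps
the terminal slope unbiased at the cost of slightly underestimating AUC.

### Trapezoid variants

The default is the plain linear rule, $\sum (t_2 - t_1)(C_1 + C_2)/2$. The
`"linear-up/log-down"` option replaces each strictly declining segment by
$(t_2 - t_1)(C_1 - C_2)/\ln(C_1/C_2)$, which is exact when the two points
lie on a common exponential; it falls back to the linear rule on rising or
zero-valued segments. Linear is the default because it is the unqualified
"trapezoidal rule" of standard reports; log-down is preferable for sparse
late sampling and is what the package's own closed-form tests use when
exactness matters.

### C0 back-extrapolation

When a bolus profile starts after $t = 0$ (first sample at 5 min), the
concentration at $t = 0$ is back-extrapolated log-linearly through the first
two usable points (falling back to carrying the first observation back when
they do not decline) and prepended before integration. This is standard NCA
practice for IV bolus data; without it the area of the first interval —
which contains the fastest disposition phase — is silently dropped. Set
`extrapolate_c0 = FALSE` in `run_nca()` to integrate strictly over the
observed range.

### Vss: two conventions

The standard relation is $V_{ss} = Cl \times MRT$. The reference report this
package is patterned on states $V_{ss} = Cl / MRT$ — dimensionally a
clearance per time, yet its printed value is numerically $Cl/MRT$ from its
own table. Both are provided: `vss(cl, mrt, mode = "paper")` (the default,
for reproduction) and `mode = "conventional"`. The discrepancy is surfaced
here rather than silently resolved, and `run_nca()` returns both fields.

### Cohort summaries

`summarize_cohort()` reports the arithmetic mean and sample SD (n − 1
denominator) of each parameter across subjects, averaging per-subject
derived parameters rather than deriving parameters from averaged inputs.
The two orders differ: e.g. a mean half-life of 7.88 h is consistent with a
mean rate constant of 0.09 h⁻¹ only if per-animal ratios are averaged, which
is why the per-subject order is used.

## Validation statistics

* **Accuracy**: relative error, $RE\% = 100\,|nominal - measured|/nominal$.
* **Precision**: relative standard deviation, $RSD\% = 100\,s/\bar{x}$ with
  the sample SD ($n-1$) throughout.
* **Intra-day** tables summarise one day's replicates per level;
  **inter-day** tables pool *all* replicates across days into a single mean
  and SD per level. Pooling (rather than summarising day means) reproduces
  the single-row-per-level layout of conventional inter-day tables and is
  documented as a choice.
* **Acceptance**: a level passes when both RSD% and RE% are ≤ 15, except at
  the LOQ level where the limit is 20 — values are rejected only when
  strictly *above* the limit, per the usual "higher than 15 % not accepted"
  phrasing.
* **Recovery**: 100 × mean(processed responses)/mean(reference responses);
  its SD is that of the individual processed-replicate ratios against the
  reference mean (the propagation rule is rarely stated in reports; this is
  the simplest replicate-level definition).
* **Stability**: percent remaining relative to the initial concentration;
  stable iff the deviation from 100 % is ≤ 5 percentage points.
* **LOD**: lowest tested level with signal-to-noise ≥ 3; **LOQ**: lowest
  tested level with RE% and RSD% strictly below 20. Both are selected among
  the discrete tested levels, never interpolated, matching the level-based
  experimental procedure. (Reports sometimes blur the two — an abstract
  quoting "detection limit 5 ng/mL" alongside an LOD of about 2 ng/mL in the
  body; this package keeps LOD and LOQ distinct.)

## Calibration

`fit_calibration()` regresses the peak-area ratio on nominal concentration
by least squares, unweighted by default — matching a single printed
regression line such as $y = 0.0015x - 0.0087$ — with `1/x` and `1/x²`
weighting available because a 5–1000 ng/mL range spans 200-fold and
variance rarely stays constant across it. A curve with fewer than six
distinct levels is marked not reportable. `back_calculate()` inverts the
line and multiplies by the dilution factor, flagging negative results as
non-physical.

## The synthetic generator

`disposition_params()` defines a sum-of-exponentials bolus curve
$C(t) = \sum_i A_i e^{-\lambda_i t}$. The default
(`default_disposition()`) is tri-exponential with coefficients
(3632, 1909, 350) ng/mL and rates (3, 0.5, 0.0879) h⁻¹ at 5000 µg/kg. These
macro-constants were chosen once, by closed form, so the generator's
analytic summaries equal the reference study's reported parameters: AUC₀₋∞
= ΣAᵢ/λᵢ = 9.01 µg·h/mL, MRT = (ΣAᵢ/λᵢ²)/(ΣAᵢ/λᵢ) = 5.92 h, terminal
t½ = 7.88 h, and C(48 h) = 5.15 ng/mL, i.e. still quantifiable at the last
sample. They are illustrative — no published macro-constants exist for the
original curve — and are labelled as such.

Measurement noise is proportional + additive on the concentration scale,
`C = µ(1 + ε_p) + ε_a` with Gaussian deviates, truncated at zero (physical
non-negativity; truncation is negligible at the CVs used). Between-subject
variability multiplies each subject's *coefficients* by a common mean-one
lognormal factor with the configured CV; rates are shared. Jittering only
the coefficients is the minimal identifiable structure that reproduces
between-animal SDs of the reported kind; jittering rates too would
confound the terminal-slope recovery tests. With all components zero the
simulator output is bit-identical to the model curve.

QC batches use a two-level variance structure, `level × (1 + day effect) ×
(1 + replicate effect)`, day effects shared within a day — the minimal
model under which intra-day RSD converges to the replicate CV and
inter-day RSD exceeds it. Calibration responses apply proportional noise to
the linear response model.

What the generator does **not** emulate: chromatographic peak shapes or
integration (responses enter as area ratios), absorption phases (IV bolus
only), correlated residuals within a profile, heteroscedastic additive
error, or drug degradation over storage. Passing tests therefore show the
*statistical machinery* is correct under the stated error model, not that
any particular real assay meets its acceptance criteria.

## Numerical choices and test scale

* Terminal slopes above −10⁻¹⁰ are declared unestimable (flat phase) rather
  than returned as near-zero rates.
* LOQ/LOD limits use strict inequalities; the 15/20 acceptance rule and the
  ±5 % stability band are inclusive at the boundary.
* Rounding to two decimals happens only at the reporting layer
  (`render_report()`); all computation is full precision.
* Monte-Carlo checks in the test suite use 10⁴ replicate draws (noise CV),
  10³ subjects (between-subject CV), 20 seeds × 6 subjects (half-life
  recovery) and 100 random QC batches (oracle equivalence) — sizes at which
  the standard errors of the checked quantities are several-fold smaller
  than the test tolerances.

## Known limitations

* The automatic terminal window maximises adjusted r² over suffixes only;
  it does not implement exhaustive interior-window searches or curvature
  diagnostics.
* BLQ handling is exclusion-only; no substitution (LLOQ/2) or likelihood
  methods.
* Inter-day precision has no variance-component decomposition (e.g. ANOVA
  intermediate precision); it is the pooled summary described above.
* The simulator's lognormal subject effect applies one factor to all
  coefficients; it cannot generate subjects whose phases vary independently.
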