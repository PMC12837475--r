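---
title: "Measurement uncertainty for QQ immunoassays: model, decisions, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement uncertainty for QQ immunoassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qqum)
```

## The measurement model

A quick-quantitative (QQ) fluorescence immunochromatographic assay reports a
residue concentration X (µg/kg) directly from a strip reader over a 0–300
µg/kg working range. The reliability question near a regulatory limit is not
X itself but its uncertainty. `qqum` implements the GUM treatment of that
question for an additive measurement model with five input sources:
sample weighing, the extraction/pipetting step ("Extractor"), zeroing the
reader against a blank card, the calibration-curve fit, and the test strip
itself ("Lab Card", a composite of strip-to-strip, application and reading
variability).

Each source contributes a standard uncertainty \(u(x_i)\) with sensitivity
coefficient \(c_i\) (all 1 for the additive model). The combined standard
uncertainty follows the law of propagation of uncertainty under
independence,

\[
u_c(y) \;=\; \sqrt{\textstyle\sum_{i=1}^N \big[c_i\,u(x_i)\big]^2},
\]

and the expanded uncertainty is \(U = k\,u_c\) with coverage factor
\(k = 2\) (≈ 95 % for a normal measurand). Results are reported as
"X ± U µg/kg (k = 2)" with the coverage interval \([X-U,\,X+U]\).

### The relative-uncertainty convention

The model is additive with \(c_i = 1\), yet budgets are reported as
percentage shares and the expanded uncertainty as a percentage of X. The
only convention consistent with all of those at once is to store every
component as a **relative** standard uncertainty (a dimensionless fraction
of the measurand), combine the relative values by root sum of squares, and
scale by X only at reporting time: \(u_c = u_{c,\mathrm{rel}} \cdot X\).
This is the convention `qqum` uses throughout; `uncertainty_component()`
documents `u` as a fraction, and `measurement_report()` performs the
scaling.

Percentage shares are squared-contribution ratios,
\(100\,(c_iu_i)^2/u_c^2\); they sum to 100 before display rounding (kept at
full precision internally, shown at 1 decimal). Zero-uncertainty components
are legal and contribute 0 %; an all-zero budget has \(u_c = 0\) and its
shares are undefined (an error, not NaNs).

### Type A and type B evaluation

Type A uncertainties come from replicates: the sample standard deviation
(n − 1 denominator) over the mean. The replicate RSD is used directly as a
component (division by √n for the uncertainty *of the mean* is available
via `of_mean = TRUE` but is not the default, because strip and pipetting
repeatability enter the budget as single-observation dispersions). Type B
uncertainties come from stated bounds with the standard GUM divisors: √3
(rectangular), √6 (triangular), or the source's own coverage factor
(normal). The package deliberately stops there: Welch–Satterthwaite
effective degrees of freedom, Monte-Carlo propagation, and correlated
components are out of scope — k is fixed at 2 and the RSS assumes
independence.

### Reporting and rounding

U is displayed at 3 significant figures and X at the reader's display
resolution of 0.01 µg/kg (2 decimals, configurable). All computations keep
full precision; rounding happens only in `format_measurement()`, print
methods, and explicit `round()` calls at output boundaries. The interval
endpoints are exact `X - U` / `X + U` doubles.

Two defensible defaults exist for the Lab Card component — a measured
multi-batch strip RSD of 4.5 % and the manufacturer's 4 % specification —
and neither is privileged: both are exposed via `lab_card_presets()` and
selected in `run_config()`.

## The assay binding

`measure_sample()` treats the strip readout as already being in
sample-concentration units: the reader's range (0–300 µg/kg) equals the
method's range, and no dilution correction is applied to X — the 1:9
dilution, sample mass and volumes are assumed to be absorbed by the
reader's firmware calibration. They are validated (`validate_inputs()`
collects *all* violations; incubation conditions of 24 ± 2 °C / 10 min warn
rather than abort) and they enter the measurement only through their
uncertainty components. The fluorescence → concentration calibration curve
is intentionally **not** implemented — no functional form is available —
so "Curve Fitting" is an input component, not a computed fit.

Every measurement carries a stepwise calculation record (inputs, each
component's contribution, \(u_{c,\mathrm{rel}}\), scaling, expansion,
interval). `export_record()` writes it as CSV with 17-significant-digit
numbers so `replay_record()` reproduces X and U bit-identically from the
file alone.

## Conformity against the MRL

The decision rule is the interval-against-MRL trichotomy: compliant if the
whole interval is below the limit, non-compliant if wholly above,
inconclusive if the limit falls inside. Two edge decisions were open:

* **Boundary equality** (an endpoint exactly on the MRL) is classified
  inconclusive — the consumer-protective reading of "entire interval
  below/above".
* **Scoring inconclusive results**: accuracy against a binary reference
  (confirmatory LC–MS/MS) has no third category, so an inconclusive
  decision counts as incorrect in `score_accuracy()`. This is the
  conservative choice; it makes accuracy a strict lower bound.

With U = 0 the rule degenerates to the point comparison of X against the
limit. Guard-band optimization and risk-weighted rules are out of scope.

## The paired competency statistics

Before/after operator studies are paired at the operator level, with
differences oriented `pre − post` so that improvements are positive
reductions. `paired_compare()` applies a Shapiro–Wilk gate at
\(\alpha = 0.05\) on the differences: normal → two-tailed paired t with the
t-based 95 % CI and Cohen's \(d_z = \bar d / s_d = t/\sqrt{n}\);
non-normal → exact Wilcoxon signed-rank (exact for n ≤ 25, zero
differences dropped per convention) with the Hodges–Lehmann pseudomedian
as the location surrogate, \(d_z\) still reported from the raw differences
for comparability. Degenerate difference vectors (zero variance) are an
error rather than a meaningless test.

`mean_ci()` reconstructs the t interval from summary statistics alone
(se = mean/t), which lets reported cohort summaries be checked without raw
data. `mcnemar_exact()` uses the exact binomial doubled-tail p on the
discordant counts — at n ≈ 20 the χ² approximation is unreliable — without
the mid-p variant; concordant pairs never change p. The bootstrap for the
change in inter-operator CV resamples operators (paired indices) with
replacement, B = 10 000 by default, percentile 2.5/97.5 interval, and a
mandatory seed; the session RNG state is saved and restored so all
generators are pure functions of their inputs.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` encodes the study conditions of a 20-technician paired
cohort: per-operator pipetting CVs distributed 4.10 ± 0.68 % → 1.79 ±
0.41 % at 100 µL and 2.52 ± 0.49 % → 1.08 ± 0.33 % at 1000 µL, ten
replicates per session. The pre/post dependence across operators is not
derivable from published summaries; it is exposed as the correlation
parameter `rho` (default 0.5, a moderate skill carry-over) and never
asserted. Latent CV pairs are drawn from a correlated bivariate normal
truncated below at 0.1 % (redrawn; avoids degenerate sessions).

One design choice deserves emphasis. The published dispersions (e.g.
± 0.68 %) describe the spread of *observed* per-operator RSDs. An RSD
estimated from 10 replicates carries sampling noise with relative standard
error \(\approx 1/\sqrt{2(n-1)} \approx 24\,\%\); generating replicates
naively and re-estimating RSDs would therefore inflate the between-operator
spread well beyond the published value and break parameter recovery. The
generator instead conditions each session on its summary statistic: the
replicate set is drawn from the normal pipetting law and then affinely
standardized so its sample mean equals the nominal volume and its sample
RSD equals the drawn CV exactly. Consequently the paired cohort metric *is*
the generator truth, `operator_rsd()` on a session reproduces it, and
recovery tests are well-posed. The cost is that replicate-level sampling
noise is not represented in the cohort metric — a deliberate trade
documented here. `simulate_pipetting()` itself remains a plain seeded
normal generator.

`simulate_panel()` produces near-MRL panels: true concentrations uniform on
80–120 µg/kg around the 100 µg/kg limit, measurements
\(X = \mathrm{truth}\cdot(1+\varepsilon)\) with
\(\varepsilon \sim N(0,\,u_{c,\mathrm{rel}})\) at the assay's typical
\(u_{c,\mathrm{rel}} = 0.0625\), and \(U = k\,u_{c,\mathrm{rel}}X\). Truth
labels are the point comparison of the true concentration with the limit.

None of the generators model temperature/humidity effects, strip-batch
drift, operator learning curves within a session, or non-normal pipetting
error; passing tests on synthetic cohorts show that the statistical
machinery recovers known truth under the stated conditions, not that real
cohorts satisfy those conditions. In particular, a published Shapiro–Wilk
statistic (W = 0.959) or an inter-operator CV trajectory (18.7 % → 9.0 %)
cannot be reproduced without the raw cohort, which is not available; these
anchor branch logic and are covered by generator-truth recovery only. (The
published 18.7 → 9.0 trajectory is, incidentally, not implied by the
published cohort means and SDs — another reason it is treated as
non-reproducible.)

## Numerical choices and problem sizes

* RSS combination is checked against an explicit summation-loop oracle at
  1e−12 on random budgets of up to 20 components (1 000 budgets in the
  property suite).
* The conformity property suite draws 10 000 random (X, U, MRL) triples
  for the trichotomy and U-monotonicity checks.
* Cohort-level stochastic checks use 200 seeded cohorts of 20 operators;
  the bootstrap default is B = 10 000, scaled to 500–2 000 inside tests.
  These sizes make the whole suite run in well under a minute while
  keeping Monte-Carlo error far below the asserted margins.
* Reported example quantities (a 188.10 µg/kg sample with
  \(u_c = 11.75\)) are reproduced through the full measurement path, not
  hard-coded.

## Worked example

```{r example}
budget <- assemble_budget(list(
  "Sample Weighing"       = 0.0625 * sqrt(0.112),
  "Extractor"             = 0.0625 * sqrt(0.344),
  "zero-card Calibration" = 0.0625 * sqrt(0.061),
  "Curve Fitting"         = 0.0625 * sqrt(0.006),
  "Lab Card"              = 0.0625 * sqrt(0.477)
))
res <- measure_sample(assay_inputs(strip_reading = 188.10), budget, k = 2)
res$report$text
assess_conformity(res$report$X, res$report$U, mrl = 100)
```

## Known limitations

* k is fixed (no t-based coverage from effective degrees of freedom); for
  very few replicates the 95 % claim of k = 2 is optimistic.
* Components are assumed independent; a shared pipette between "Extractor"
  and "zero-card Calibration" would correlate them and RSS would then
  underestimate \(u_c\).
* The strip calibration function is opaque: any nonlinearity of the
  fluorescence–concentration relation is only representable through the
  "Curve Fitting" component's magnitude.
* Accuracy scoring treats inconclusive as wrong, so reported accuracies
  are conservative near the limit where inconclusive is the *correct*
  metrological behaviour.
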