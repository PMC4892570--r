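---
title: "Modelling HGSOC natural history and ultrasound screening"
author: "hgsocsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HGSOC natural history and ultrasound screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgsocsim)
```

## The model

High-grade serous ovarian cancer (HGSOC) is rarely observed before it is
advanced, so its pre-clinical kinetics must be reconstructed by simulation.
`hgsocsim` models the cell count $N(t)$ of a single untreated primary tumor,
measured from the inception of the first malignant cell ($N_0 = 1$), as
Gompertzian growth

$$\frac{dN}{dt} = N\left(k_{\mathrm{growth}} - k_{\mathrm{decay}} \ln N\right),
\qquad
N(t) = \exp\!\left[\frac{k_{\mathrm{growth}}}{k_{\mathrm{decay}}}
\left(1 - e^{-k_{\mathrm{decay}} t}\right)\right],$$

with carrying capacity $N_\infty = e^{k_{\mathrm{growth}}/k_{\mathrm{decay}}}$,
inflection time $t_i = \ln(k_{\mathrm{growth}}/k_{\mathrm{decay}})/k_{\mathrm{decay}}$
and inflection count $N_i = N_\infty / e$.

A fixed-parameter Gompertz curve saturates once; it cannot express the
stepwise, stop-and-go growth seen in ovarian cancer spheroids and xenografts,
nor the heterogeneity of clinical courses. The model therefore superimposes a
jump process on the saturation rate: at the start of each 28-day period (one
menstrual cycle) a rate-limiting event occurs with probability $\alpha$, and
when it does,

$$k_{\mathrm{decay}} \leftarrow \frac{k_{\mathrm{decay}}}{1 + U},
\qquad U \sim \mathrm{Uniform}(0, 1).$$

Each jump multiplies the capacity exponent by $1+U$, so the tumor, having
plateaued near its current capacity, resumes growth toward a higher one.
Biologically a jump stands for an unspecified (epi)genetic alteration; the
model deliberately does not say which.

Volumes and cell counts are interconvertible at $10^9$ cells/cm³. Two volume
thresholds structure every analysis: a detection volume (baseline 10 cm³,
the excess over normal ovarian volume that makes a transvaginal-ultrasound
finding suspicious; equivalently $10^{10}$ cells or a 2.673 cm spherical
diameter) and a life-threatening volume ($10^3$ cm³, $10^{12}$ cells,
12.407 cm). The *window of opportunity* of a simulated curve is the time
between crossing the two, computed only for curves that cross both; reaching
the life-threatening volume ends a curve's simulation.

## Default study conditions

The default cohort reproduces the conditions of the simulation study the
package implements:

* **1000 curves**, each from one founding cell, simulated in 28-day periods
  until the life-threatening crossing or a 38.5-year horizon. The period
  count is derived from the horizon: $\lceil 38.5 \times 365.25 / 28 \rceil
  = 503$ periods, so crossings are accepted up to $503 \times 28$ days
  ($\approx$ 38.56 years). (The two published anchors — 460 lifetime
  menstrual cycles and 38.5 years — disagree by three years; the horizon
  wins because reported crossing times extend past 35.3 years.)
* **Initial rates.** Each curve's $k_{\mathrm{growth}}$ is drawn uniformly
  from nine clinically derived lower-bound rates (see below);
  $k_{\mathrm{decay},0} = k_{\mathrm{growth}}/2$, so every curve starts with
  capacity $e^2 \approx 7.4$ cells and is undetectable until jumps
  accumulate. Reaching $10^{10}$ cells requires
  $k_{\mathrm{growth}}/k_{\mathrm{decay}} \ge \ln 10^{10} \approx 23$, i.e.
  the product $\prod (1+U_j)$ must exceed 11.5 — typically 5–8 jumps. This
  is why roughly half of all curves stay occult for life: the jump budget of
  a 503-period lifetime at $\alpha \approx 0.015$ is about 7–8 events.
* **Jump probability.** $\alpha$ is lognormal with log-location $\ln 0.01$
  and log-scale $0.5$, rejection-resampled into $[0.0094, 0.150]$, drawn
  once per curve (`redraw = "per_curve"`) and applied every period.

### The $\alpha$ parameterization

The published constraints on $\alpha$ — "mean $10^{-2}$, variance
$25\cdot10^{-2}$, range $0.0094$–$0.150$" — cannot hold simultaneously: a
variance of 0.25 exceeds the maximum possible on that support by two orders
of magnitude, and *any* distribution on $[0.0094, 0.150]$ with mean $0.01$
must put at least 94% of its mass below $0.02$ (Markov's inequality), which
would erase the heterogeneity the right-skewed choice is meant to express.
The package therefore keeps the printed location ($\ln 0.01$), shape
(lognormal, reading $25\cdot10^{-2}$ as the log-space variance, so
$\sigma_L = 0.5$) and range (by rejection), and reports the realized mean of
the clipped distribution — $\approx 0.0151$, exposed as
`alpha_mean_effective` — instead of forcing the nominal one. All four
numbers are configurable.

```{r alpha}
jc <- jump_config()
jc$alpha_mean_effective
```

The per-curve draw (rather than per-period) is the default because the
skewed $\alpha$ is most naturally read as inter-patient heterogeneity, and
because the published spread of detection times (minimum near 4.5 years)
requires some curves with $\alpha \sim 0.1$ accumulating their full jump
requirement within a few years — impossible when every curve averages the
same per-period rate. `redraw = "per_step"` is available for sensitivity
analysis.

### The rate fixture

Only three order statistics of the nine source rates are published: minimum
0.0014, median 0.0133, maximum 0.0448 day⁻¹. `default_rate_fixture()`
reconstructs the other six by geometric interpolation within each half of
the range. It is a synthetic stand-in that reproduces every published
constraint on the rate set, not the original data; any user-supplied rate
file (one rate per line) replaces it. Note a structural consequence: the
slowest fixture rates (0.0014–0.0025 day⁻¹) cannot reach $10^{10}$ cells
within the horizon even at zero saturation, since
$\ln(10^{10})/k_{\mathrm{growth}}$ alone exceeds 25–45 years, so about a
fifth of the cohort is occult by arithmetic rather than by chance.

## Monitoring evaluation

A monitoring protocol places a first visit uniformly in years 0–5 after
inception and repeats every $f$ years (semiannual to quinquennial).
Specificity, compliance and non-contamination are structural: there are no
false positives and no off-schedule visits anywhere in the module. Each
curve is classified exhaustively as

* **occult** — never reaches the protocol's detection volume;
* **succumbed** — crosses detection *and* the life-threatening volume
  strictly before the first visit at or after its detection crossing (both
  crossings fall between consecutive visits, or before the first visit);
* **detected** — otherwise.

Two unstated edge cases are resolved as follows. A visit landing exactly on
the lethal-crossing instant counts as detection (strict inequality; a
measure-zero tie-break fixed for bit-reproducibility). A curve detectable
within the horizon whose catching visit falls beyond the horizon is
*detected* when it never reaches the lethal volume in-simulation (volume is
non-decreasing, so detection at that visit is certain), and *succumbed*
when the lethal crossing precedes every post-detection visit; this keeps
the three-way partition exhaustive.

By default each protocol draws fresh first-visit times per curve
(matching independently simulated protocols). `sensitivity_grid(...,
schedules = "paired")` shares one first-visit draw per curve across all
frequency × threshold cells; with nested frequencies (e.g. 0.5, 1, 2, 4
years) coarser schedules are then visit-subsets of finer ones, making the
monotonicity of missed-cancer percentages exact rather than statistical —
useful for variance-free comparisons and asserted exactly in the tests.

## Numerical choices

* **Closed-form propagation.** Between jumps the trajectory follows the
  exact segment solution
  $\ln N(t) = A + (\ln N_s - A)e^{-k_{\mathrm{decay}}(t - t_s)}$,
  $A = k_{\mathrm{growth}}/k_{\mathrm{decay}}$, in log-cell space (late
  segments have astronomically large capacities that overflow doubles).
  A fourth-order/adaptive numerical integrator (deSolve) serves only as a
  test oracle, at relative tolerance $10^{-6}$ over 1000 randomized
  segments.
* **Continuous-time crossings.** Threshold crossings are inverted
  analytically inside a period rather than rounded to period boundaries
  (published crossing times are not multiples of 28 days). A
  `crossing = "step_end"` switch rounds them up to the period boundary for
  comparison.
* **Sampling.** The clipped lognormal is sampled by inverse CDF on the
  truncated probability interval — exact, and exactly one uniform per draw,
  which keeps per-curve random streams aligned. Draw order per curve is
  fixed (rate index, $\alpha$, period triggers, jump sizes).
* **Reproducibility.** Every curve runs on a substream seeded
  deterministically from the master seed and its curve index, so cohorts
  are reproducible, curves are order-independent, and a single curve can be
  resimulated in isolation. Monitoring first-visit draws use separately
  derived streams.
* **Jump counting.** A crossing is attributed the number of jumps applied
  strictly before its segment ends; a jump scheduled at the exact crossing
  instant (possible only when a crossing coincides with a period boundary)
  does not count, since it did not influence the crossing.

## Worked example

```{r cohort}
cfg <- simulation_config(n_curves = 200, seed = 42)
coh <- simulate_cohort(cfg)
summary(coh)
```

```{r screening}
screening_summary(coh, monitoring_protocol(1, 10))$proportions
head(sensitivity_grid(coh, schedules = "paired"))
```

Rate estimation from bi-dimensional measurements follows the clinical
reduction — weighted radius $r = \sqrt{ab}$ (the published formula's radical
is typographically lost; the geometric mean is the standard
ellipsoid-to-sphere equivalence, and the literal product is selectable via
`convention = "product"`), spherical volume $\tfrac{4\pi}{3}r^3$, and
$k \ge [\ln V_{\mathrm{diag}} - \ln V_{\mathrm{normal}}]/T$ against the
20 cm³ (premenopausal) or 10 cm³ (postmenopausal) normal ovarian volume:

```{r rates}
m <- data.frame(a_cm = c(2, 3), b_cm = c(3, 4),
                status = c("post", "45"), t_days = c(180, 365))
estimate_rates(m)
```

## What the simulation does and does not show

The cohort is *cancer-positive by construction*: every member already
harbors the founding malignant cell at time zero, so occult/succumbed
percentages are conditional on eventual disease, not population screening
yields. The model has no spatial structure, no subclonal rate variation, no
metastasis or stage linkage, no treatment after detection, and a unimodal
ultrasound endpoint only (no CA-125 arm). Within those bounds, passing
tests show that the kinetics, jump mechanics and classification logic are
exact; they cannot validate the clinical realism of the reconstructed
inputs (the nine-rate fixture and the $\alpha$ distribution), which are
only partially published and are the dominant source of uncertainty in any
comparison with the published cohort statistics. Problem sizes throughout
the test suite (cohorts of 100–1000 curves, $10^5$ distributional draws)
were chosen as the smallest that make the statistical assertions sharp at
their stated tolerances.
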