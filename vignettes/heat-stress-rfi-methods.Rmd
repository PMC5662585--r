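---
title: "Methods: heat-stress resilience phenotypes and thermoneutral-anchored RFI"
author: "heatRFI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-stress resilience phenotypes and thermoneutral-anchored RFI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatRFI)
```

# The problem

Finishing pigs exposed to hot episodes eat less, grow slower, and change
body composition. Quantifying *resilience* — how much an individual's
growth and intake drop when heat arrives, and how repeatable that drop is
— requires a design in which the same animal alternates between
thermoneutral (TN) and heat-stress (HS) conditions, and an analysis that
separates period effects, genetic-line effects, diet, room, and the
within-animal covariance across repeated periods.

`heatRFI` implements that analysis end to end for a 52-day episodic
design: a long TN adaptation/baseline period, then three 4-day HS
episodes each followed by 7 TN recovery days (periods TN1, HS1, TN2, HS2,
TN3, HS3, TN4 on days 8–53). Because no animal-level dataset is
distributed with the package, a synthetic cohort generator reproduces the
statistical structure of such an experiment — three genetic lines
(a fast lean commercial cross and two lines divergently selected for
residual feed intake) crossed with two diets and two rooms — so that every
stage of the pipeline is testable and the headline quantities are
recomputable from scratch.

# Period phenotypes

Body weight is weighed one day before each period boundary (days 8, 19,
23, 30, 34, 41, 45, 52, plus day 1). Boundary weights (days 20, 24, 31,
35, 42, 46, 53) are completed by a *sequential forward fill*: in
chronological order, the gain rate of the period ending at boundary `b` is
computed from the already-completed start weight and the measurement one
day before `b`, and the boundary weight adds one day of that rate. Two
properties motivated this interpretation of "add the period's average
gain": (i) it is a self-consistent fixed point — the resulting HS1 gain is
identically the rate over the measured HS interval, `(BW23 − BW20)/3` —
and (ii) it is exact on any piecewise-linear trajectory. The alternative
reading (shifting the day-19 weight with the *following* period's rate)
is not self-consistent; the fill used here is asserted in the tests via
the telescoping identity (period gains times spans sum to `BW53 − BW8`
within machine precision).

Per pig and period we derive: gain `BWG` (kg/d), intake `FI` (mean daily
feed disappearance over the period's days; at most one missing day is
imputed by the period mean), metabolic body weight
`MBW = ((BW_start + BW_end)/2)^0.75`, the assigned ultrasound backfat
(first scan for TN1/HS1, last scan for HS3/TN4, their mean for the middle
periods), and feed conversion efficiency `FCE = BWG/FI`. FCE stays
defined (negative) when a pig loses weight; its inverse FCR does not at
zero gain, which is why FCE is the ratio the package reports. The
resilience phenotypes are the within-pig drops
`LossBWG_c = BWG(HSc) − BWG(TNc)` and `LossFI_c = FI(HSc) − FI(TNc)`
(negative = drop). Gain over the adaptation days (1–8) is exposed by
`adaptation_bwg()` but deliberately enters no model: it is confounded
with arrival stress and diet change.

# Thermoneutral-anchored residual feed intake

The anchor regression pools *all TN pig-periods* (4- and 7-day periods
unweighted, matching the "all individual observations" convention) in an
ordinary least-squares fit

$$FI = b_0 + b_1\,MBW + b_2\,BWG + b_3\,BFT + e.$$

The residual of a TN row is the pig's TN residual feed intake; the TN
coefficients applied to HS rows (`apply_rfi()`) give an HS RFI that
measures intake relative to the *thermoneutral expectation* for the pig's
current size, gain and fatness. Mean TN RFI is exactly zero by OLS; mean
HS RFI is typically negative — heat-stressed pigs eat less than their
depressed gain alone would predict — which is the biologically
interesting sign flip between RFI ("more efficient under HS") and FCE
("less efficient under HS"). The companion `residual_growth()` swaps the
roles of intake and gain. Line- and climate-specific feed requirements
per unit gain are estimated by `fit_feed_requirements()`: a mixed model
for FI over all seven periods with a separate BWG slope per line-climate
cell and a random litter intercept, reference levels HS / low fiber /
highRFI / room 2.

# The REML engine

`hslmm()` fits repeated-measures mixed models by restricted maximum
likelihood. Fixed effects are profiled out by generalized least squares
inside the restricted likelihood; the covariance parameters are searched
by BFGS over smooth unconstrained transforms: log variances, Fisher-z
(tanh) correlations for AR1 and compound symmetry, a logistic-mapped
correlation in (0,1) for the spatial power family, tanh-transformed lags
with positive-definite rejection for Toeplitz, and the log-Cholesky
factor for the unstructured family. The Toeplitz set has no natural
smooth global chart (hyperspherical coordinates parameterize *general*
correlation matrices, not the Toeplitz subset), so rejection inside the
optimizer is the simplest correct treatment; rejected proposals return a
large objective value and the line search backs off. The search runs
from a data-driven start (the empirical covariance of OLS residuals,
shrunk towards its diagonal) plus optional jittered restarts, followed by
a Nelder–Mead polish; all restarts are seeded, so fits are deterministic.

Numerical choices worth knowing:

* **Variance floor.** All block covariances carry a floor of
  $10^{-10}\times$ the response variance, so a variance estimate on the
  boundary (zero litter variance, perfectly fitting noiseless data)
  leaves the restricted likelihood bounded and the fixed-effect
  covariance computable. Variances below $10^{-6}\times$ the response
  variance are reported as 0 with a warning.
* **Blocking.** The marginal covariance is assembled block-wise over the
  connected components induced by the random grouping factors (litters
  link pigs; everything else is subject-diagonal), with precomputed
  index maps, so each likelihood evaluation costs a set of small
  Cholesky factorizations rather than one large one.
* **Tests of fixed effects** are marginal Wald F statistics with residual
  degrees of freedom `n_obs − rank(X)`. Exact parity with
  containment/Satterthwaite approximations of other software is a
  non-goal; direction and significance at realistic effect sizes are the
  contract.
* **Information criteria.** `AIC = −2ℓ_R + 2q` over the `q` covariance
  parameters, AICc with `n − rank(X)` effective observations, and
  Schwarz BIC with the number of subjects. AICc is the primary ranking
  criterion in `select_structure()`; when the two best candidates are
  nested, a REML likelihood-ratio test (χ², df = difference in `q`)
  decides, preferring the simpler structure at p ≥ 0.05. AR1 and
  heterogeneous-AR1 candidates carry an extra random animal intercept,
  matching the convention of combining banded correlation with an animal
  effect; compound symmetry is recognised as nested in AR1-plus-animal
  (they coincide at ρ = 0).
* **Interaction pruning** (`prune_interactions()`) is stepwise: refit,
  drop the single interaction with the largest p ≥ 0.10, repeat; main
  effects are never dropped. Stepwise (rather than simultaneous) removal
  was chosen because it is the reproducible greedy variant; the removal
  trail is part of the report. `alpha = 1` is the documented boundary:
  all interactions are stripped.
* **LS means** average the observed combinations of the other factors
  with equal weight (the nested period-within-climate factor makes the
  full factorial grid partly nonsensical; using observed combinations
  keeps the averaging balanced across the levels being compared),
  covariates at their observed means. Pairwise Wald t tests feed a
  compact letter display built by greedy clique cover.

# The synthetic cohort generator

Each pig carries a latent TN gain `tn_bwg = line mean + litter + animal`
(litter SD 0.05, animal SD 0.10 kg/d by default), a persistent intake
deviation (its true RFI, SD 0.15 kg/d plus a litter component), and a
persistent HS *robustness* effect. True body weight is piecewise linear:
TN periods grow at `tn_bwg`; HS cycle `c` grows at

$$tn\_bwg + L_c + \ell_{line} + s\,(tn\_bwg - \mu_{line}) + u_i +
\varepsilon_{ic},$$

with cycle means $L_c$ = (−0.529, −0.294, −0.245) kg/d (the first episode
hits hardest), line deviations $\ell$ = (−0.418, +0.050, +0.368) for
commercial/lowRFI/highRFI (fast lean pigs drop hardest, so the lines'
TN ranking compresses under HS), trade-off slope $s$, persistent
robustness $u_i$, and transient noise. Intake follows the true
feed-requirement coefficients `rfi_truth` (b0 = 2.42, b1 = −0.01,
b2 = 0.480, b3 = 0.00) plus the pig's RFI deviation, a line-level anchor
that pins the TN intake means (3.22 / 2.63 / 2.77 kg/d), a −0.26 kg/d
high-fiber shift for the commercial line only, and cycle drops
$LossFI_c$ = (−0.662, −0.506, −0.439) kg/d added to the same-cycle TN
expectation. Daily intake multiplies the period mean by mean-one
lognormal noise (CV 0.10); within-day or day-to-day autocorrelation of
intake is not modelled — nothing in the emulated design constrains it.
Weighings add N(0, 0.5 kg) errors, a realistic farm-scale figure.
Scans, loin depth, hot carcass weight (dressing 0.73) and slaughter lean
(the carcass lean equation plus 1 percentage-point noise) complete the
tables. All randomness descends from one master seed through
hashed per-pig and per-litter substreams, so adding pigs never perturbs
existing ones and identical configurations are byte-identical.

## Calibrating the trade-off

Two correlations characterize the resilience structure: pooled TN-period
gain versus the next cycle's gain drop (target −0.70, adjusted for line,
diet, room and cycle) and the first-to-second-cycle repeatability of the
drop (target 0.36). At the *latent* level these targets are jointly
unreachable in this generator: the latent TN gain is constant across
cycles, forcing `corr(Loss1, Loss2) ≥ corr(gain, Loss)²` = 0.49 > 0.36.
What breaks the bound in derived data is weighing error propagating
through the sequential boundary fill: a shared boundary weight enters the
TN gain and the following loss with opposite signs (a mathematical
coupling that makes the pooled correlation more negative), and
neighbouring cycles share boundary estimates (inflating cycle-to-cycle
correlation less than the trade-off). `implied_tradeoff_corr()` therefore
combines the latent covariance with the *exact* linear error-propagation
map, obtained by pushing unit weighing errors through
`estimate_boundary_bw()` itself; `calibrate_tradeoff()` inverts that
closed form for (slope, robustness SD, transient SD), keeping the
transient SD near its incoming value to resolve the leftover degree of
freedom. The closed form is verified against a brute-force simulation of
10^5 pigs in the tests. A zero-target call switches both coupling
mechanisms off exactly rather than solving (with weighing error the
implied pooled correlation at zero slope is slightly negative — the
honest value of the generative model, and a caveat worth remembering when
interpreting trade-off correlations computed from estimated boundary
weights in any dataset of this design).

## What passing tests do and do not show

The generator emulates means, variance components, the episodic design,
and the calibrated correlation structure. It does not emulate
compensatory-growth dynamics beyond the linear period model, intake
autocorrelation, mortality, line-specific intake drops, or
genotype-by-diet interactions beyond the single intake shift. Tests
passing on this cohort demonstrate that the *pipeline* computes the
intended quantities under the modelled structure — not that the modelled
structure captures every feature of real animals.

# Problem sizes and determinism

The test suite and the acceptance checks run cohorts of 8 pigs per
line-diet-room cell (96 pigs, near the emulated study's 97) over 20
seeds for stochastic targets, 10^4–10^5 pigs for law-of-large-numbers
checks of the generator itself, and 120–500 subjects for mixed-model
recovery experiments; these sizes were chosen so Monte-Carlo error is
comfortably inside each assertion's tolerance. Pipeline runs are
reproducible from the archived run configuration and master seed alone;
report tables are byte-identical across reruns (`run.log` carries
wall-clock timings and is the one exception).

# Known limitations

* Degrees of freedom for LS means and Wald tests are residual
  (`n_obs − rank(X)`), anti-conservative relative to Kenward–Roger or
  Satterthwaite for small numbers of subjects.
* The Toeplitz rejection scheme can, in principle, stall the line search
  near the positive-definite boundary; the shrunk diagonal start and
  jittered restarts make this rare in practice.
* The Sawa variant of BIC is version-dependent in its original software
  and is replaced here by Schwarz BIC (labelled as such) in rankings.
* Whether the anchor regression's published explained-variance figures
  are plain or adjusted R² is ambiguous; both are reported in
  `rfi_fit.json`.
* Period intake treats feed disappearance as intake: spillage is not
  modelled.

# A worked example

```{r example, eval = FALSE}
sch <- default_schedule()
cfg <- calibrate_tradeoff(-0.70, 0.36, cohort_config(n_per_cell = 8))
cohort <- generate_cohort(cfg, sch, seed = 1)
der <- derive_phenotypes(cohort, sch)
fit <- rfi_fit(der$phenotypes)
print(fit)
ph <- apply_rfi(fit, der$phenotypes)
tapply(ph$rfi, ph$climate, mean)

report <- run_pipeline(run_config(cohort = cfg), out_dir = "hs_run",
                       seed = 1)
print(report)
```
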