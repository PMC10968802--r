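---
title: "Modelling and forecasting cancer stem cell marker dynamics under 5-FU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and forecasting cancer stem cell marker dynamics under 5-FU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscgp)
```

## The problem

Chemotherapy can enrich a tumour for cancer stem cells (CSCs): if the CSC
subpopulation dies more slowly under a drug such as 5-fluorouracil (5-FU)
than the sensitive bulk, the *fraction* of surviving cells carrying CSC
marker signatures (CD24−CD44+, CD44+, ALDH1+, ABCG2+ combinations) rises
with exposure time. Flow cytometry measures this as a percent-positive time
series per cell line, marker signature and treatment arm. `cscgp` provides
a complete in-silico version of such a study: a mechanistic generator of
marker trajectories, an event-level cytometry simulator with gating, a
genetic-programming (GP) symbolic regressor that fits each trajectory on
early time points and extrapolates it, and the treated-versus-control
statistics.

## The two-compartment selection model

Survivors are split into a resistant compartment (initial fraction $f_0$,
death rate $d_r$ under drug) and a sensitive compartment (rate
$d_s \ge d_r$). The marker-positive fraction among live cells at time $t$
(hours) is

$$f(t) \;=\; \frac{f_0 e^{-d_r t}}{f_0 e^{-d_r t} + (1-f_0)\,e^{-d_s t}},$$

which is non-decreasing whenever $d_s > d_r$ and depends on the rates only
through $d_s - d_r$. Untreated cultures share a single baseline rate
$d_0$ across compartments, so the control fraction stays at $f_0$ and the
control dead fraction is $1 - e^{-d_0 t}$. The treated dead fraction is
$1 - f_0 e^{-d_r t} - (1-f_0) e^{-d_s t}$.

Defaults are calibrated so the model reproduces the headline enrichment of
the study design it emulates: with $f_0 = 0.05$ and
$d_s - d_r = 0.0268\,\mathrm{h}^{-1}$ the treated/control ratio at 52 h is
3.5-fold:

```{r fold}
p <- selection_params()   # f0 = 0.05, d_r = 0.002, d_s = 0.0288, d0 = 0.001
fold_enrichment(p, 52)
```

Remaining defaults: assay times 24/33/43/52 h, three replicates, and
additive Gaussian replicate noise of 1.0 percentage point (clipped to
[0, 100]) — the simplest noise model consistent with reporting means ± SEM
of three independent experiments. Baseline fractions per cell line and
signature are calibration choices, not measured values (the emulated study
reports no absolute baselines); single-marker signatures get larger
baselines (0.05–0.15) than triple-positive ones (0.02–0.05). All defaults
live in one configuration file (`inst/extdata/default_study.yaml`).

Deliberately out of scope: cell-cycle structure, spatial effects,
pharmacokinetics, and plasticity/de-differentiation — the two-compartment
exponential-kill model is the minimal mechanism that produces the observed
enrichment, nothing more.

## Event-level simulation and gating

`simulate_events()` draws per-event forward/side scatter and four
fluorescence channels from log-normal mixtures: live cells form a high-FSC
cluster, dead cells and debris a low-FSC cluster with a wider SSC spread
(apoptotic granularity is modelled as spread, not a separate cluster).
Marker states are assigned per live event from a joint distribution over
the 16 sign combinations; `signature_joint()` rescales an independent
background so a chosen signature has an exact prescribed probability,
giving the gating module a known ground truth. Channel spillover and
compensation are not modelled.

`live_gate()` implements the first-level scatter gate (`fsc >= fsc_min`,
optional `ssc <= ssc_max`); `percent_positive()` computes quadrant
statistics on the live gate only. Positivity is `intensity >= threshold`,
so an event exactly at a threshold counts as positive — stated once here
and tested. Default thresholds sit at the log-scale midpoint between the
simulated negative and positive components; with the default separation
(about 10 SDs for fluorescence, 7 for scatter) gating recovers configured
fractions to within sampling error. Thresholds are configuration, never
constants: real instrument gates are not recoverable from a published
study's text.

## The symbolic regressor

`evolve()` is a from-scratch GP over expression trees with the 14-operator
function set `add, sub, mult, div, sqrt, log, abs, neg, inv, max, min,
sin, cos, tan` and terminals `t` (hours) or an ephemeral constant
(uniform on (−1, 1), or an integer 0–100). Protected semantics guarantee
finite output on finite input: `div(a,b) = 1` when `|b| < 1e-6`;
`log(x) = 0` when `|x| < 1e-6`, else `log|x|`; `sqrt(x) = sqrt(|x|)`;
`inv(x) = 1` when `|x| < 1e-6`; `tan` clamped to ±1e6; every operator
output clamped to ±1e10 with `NaN` mapped to 0.

The loop is conventional: ramped half-and-half initialization (target
depths 2–6, depth cap 8), tournament selection (size 20) on the penalized
fitness `RMSE + 0.001 × node count`, subtree crossover (0.9), subtree /
point / hoist mutation (0.03 / 0.03 / 0.02), the remainder reproduction,
and elitism. Evolution stops at the generation cap or when the best raw
RMSE reaches the stopping threshold (default 1e-3). A single seeded
generator drives every stochastic step in a fixed order, so a seed fully
determines a run; tournament ties break by fewer nodes, then draw order.

Four design choices sit on top of the plain loop; each is standard
symbolic-regression practice and each was adopted because the plain loop
could not reliably re-derive known closed forms from five noise-free
points:

1. **Affine calibration (linear scaling).** Every candidate shape $s(t)$
   is scored after the closed-form least-squares fit of $a + b\,s(t)$;
   the calibrated expression is the model of record, and the reported
   expression string embeds $a$ and $b$, so its plain RMSE equals the raw
   fitness. The search then spends its effort on curve shape rather than
   on scale and offset.
2. **Memetic constant tuning.** Each generation the few best structurally
   distinct candidates get a short derivative-free polish of their
   constants (BFGS for one constant, Nelder–Mead otherwise), once per
   structure. Discovering the right shape with rough constants is then
   sufficient.
3. **Soft restarts.** After eight generations without material (>0.1%)
   improvement, everything but a ten-individual elite is reinitialized,
   giving the run nearly independent epochs of structure search while
   elitism retains the best model.
4. **Admissibility of the returned model.** The model of record must keep
   its predictions inside a wide data-scaled band over the whole
   application horizon (training span through the forecast target). This
   vetoes shapes with a pole or blow-up just outside the training window
   — a real failure mode of protected division: a four-node
   $a + b/(c - t)$ can interpolate three training means perfectly with
   $c$ between the last training point and the validation point. Among
   individuals that reached the stopping threshold, the most parsimonious
   admissible one is returned; otherwise the best admissible penalized
   individual. The screen uses no validation labels — it is a structural
   constraint, knowable at fit time.

Time is fed in raw hours by default; `scale_time = TRUE` enables min–max
scaling (the emulated study does not state a convention, and the affine
calibration makes the choice nearly immaterial).

## Fitting, validation and extrapolation

`fit_series()` averages replicates to one mean per time point, trains the
GP on the 24/33/43 h means only, reports $R^2$ computed over all four
time-point means (training plus the held-out 52 h mean) with the 52 h
absolute error alongside, and extrapolates to 67 h (raw and clipped to
[0, 100], since the quantity is a percentage). One $R^2$ per model over
train-plus-validation means is the only definition consistent with a
single goodness-of-fit score per model when validation is a single time
point, where $R^2$ alone would be undefined. A series whose four means
are identical raises a classed degenerate-$R^2$ error; `run_study()`
isolates such failures per series and carries on, tabulating one row per
(cell line, signature, treatment) with a mean/min/max summary. Per-series
sub-seeds are keyed to the alphabetical rank of the series identity, so
results are invariant to input order.

## Group comparisons

`compare_groups()` reproduces the conventional two-group protocol: both
groups are screened with Shapiro–Wilk at $\alpha = 0.05$; if both pass, a
pooled-variance two-sample t-test, otherwise the Mann–Whitney rank-sum
test; two-sided, significance stars at 0.05/0.01/0.001; fold change is the
ratio of group means. Zero-variance groups, where Shapiro–Wilk is
undefined, route to the rank-sum branch. No multiple-testing correction is
applied by default, matching the emulated protocol. The tests themselves
delegate to `stats::shapiro.test`, `stats::t.test` and
`stats::wilcox.test`; the package's contribution is the dispatch rule and
reporting. Note that with three replicates the exact rank-sum test cannot
reach $p < 0.05$; its minimum two-sided $p$ is 0.1 — a property of the
test, reported as-is.

## What the synthetic study can and cannot show

The default study (2 cell lines × 3 signatures × ±5-FU, master seed 42)
runs in seconds to minutes on one CPU; the full acceptance suite fits 12
series at population 1000 and re-derives three planted formulas in 10
seeds each, sized to stay well inside a half-hour on a single core.

Treated series carry a strong monotone trend (e.g. 5% → 17.5% over
24–52 h for the calibrated triple-positive signature) and the GP recovers
them with $R^2$ typically 0.95–0.999. Control series are a different
matter, and the difference is informative. The model holds the control
fraction constant in time, so a control series is pure replicate noise
around a flat truth (SE of a 3-replicate mean ≈ 0.58 percentage points).
For such a series the four time-point means are independent noise, and
$R^2$ — a ratio of noise terms — has a scale-free distribution with
substantial mass below zero *regardless of the noise level and of the
fitted model*: even an oracle that predicts the true constant exactly has
expected squared validation error at least the noise variance. High $R^2$
on an untreated arm is therefore evidence that the underlying biology
drifts in time (culture age, confluence); a generator that emulates flat
controls cannot, and should not, reproduce it. Passing fits on synthetic
treated series demonstrate trend recovery under realistic noise; they do
not certify extrapolation accuracy on real data, whose fluctuations are
not Gaussian, independent, or flat.

Known limitations, summarised: the mechanistic model is deliberately
minimal (two compartments, constant rates); replicate noise is additive
Gaussian on the percent scale; the cytometry simulator draws independent
log-normal channels (no spillover, doublets, or drift); GP extrapolations
carry no uncertainty bands; and with three training means many shapes are
exactly interpolable, so the parsimony pressure and the admissibility
screen — not the data — decide among them beyond the training window.
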