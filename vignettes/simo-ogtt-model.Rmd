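---
title: "A compartmental glucose-insulin model of the OGTT with incretin effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental glucose-insulin model of the OGTT with incretin effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simogtt)
library(dplyr)
```

## The problem

The oral glucose tolerance test (OGTT) is the routine clinical perturbation
experiment of glucose homeostasis: 75 g of glucose are drunk at time zero and
plasma glucose and insulin are sampled at 0, 30, 60, 90, 120, 150 and 180
minutes. `simogtt` implements a mechanistic interpretation of those fourteen
numbers: a six-compartment ordinary-differential-equation model whose
identified parameters quantify, per subject, insulin sensitivity
(`k_xgi`), pancreatic secretory acceleration (`gamma`), maximal secretion
rate (`k_ig_max`) and the responsiveness of hepatic glucose output
(`lambda_1g`).

Two structural features distinguish the model from bare minimal models and
are essential for fitting oral (rather than intravenous) data:

* an explicit **incretin coupling**: glucose still inside the gut augments
  glucose-stimulated insulin secretion, because gut hormones released on oral
  glucose potentiate the beta cell;
* a **saturating Hill-type secretion law** whose exponent captures how fast
  the pancreas recruits its secretory reserve as glycemia rises.

## Model structure

States: `S` (stomach glucose, mmol), `J` (jejunum), `R` (a transit delay
compartment), `L` (ileum), `G` (plasma glucose, mM), `I` (plasma insulin,
pM). The gut is a linear compartment chain:

$$\dot S = -k_{js} S, \qquad
  \dot J = k_{js} S - (k_{gj} + k_{rj}) J, \qquad
  \dot R = k_{rj} J - k_{lr} R, \qquad
  \dot L = k_{lr} R - k_{gl} L,$$

with absorption to plasma from jejunum (`k_gj`) and ileum (`k_gl`). Plasma
glucose balances disposal, hepatic output and intestinal appearance:

$$\dot G = -k_{xg} G - k_{xgi}\, I\, G + G_{PROD}(G, I)
         + \frac{f\,(k_{gj} J + k_{gl} L)}{V\,BW},$$

$$G_{PROD}(G, I) = T_{1g}\, e^{-\lambda_{1g} G} + T_{2gi}\, e^{-\lambda_{2g} G I},$$

and insulin balances first-order elimination against a Hill-type secretion
driven by the incretin-augmented glycemic signal
$H = G + f_{gj}\,(J + L)$:

$$\dot I = -k_{xi} I + k_{ig}^{max} \frac{H^{\gamma}}{G_*^{\gamma} + H^{\gamma}}.$$

`f_gj` converts gut glucose content (mmol) into a plasma-concentration
equivalent (mM): with the default 0.02 mM/mmol, 50 mmol of glucose in the
bowel (about 9 g) stimulates secretion exactly as a 1 mM rise in glycemia.

### Steady-state closure

Before the dose the system must sit exactly at the observed basal state
(`G_b`, `I_b`) with an empty gut. Four quantities are therefore not free but
determined (`simo_determined()`):

* `T_1g = k_xg G_b exp(lambda_1g G_b)` — the glycemia-only hepatic term
  balances insulin-independent disposal at basal;
* `T_2gi = k_xgi I_b G_b exp(lambda_2g G_b I_b)` — the joint
  glycemia-insulinemia term balances insulin-dependent disposal at basal;
* `lambda_2g = lambda_1g / I_b` — the two suppression exponents coincide at
  basal insulinemia, so a single identified decay rate governs both hepatic
  terms;
* `G_star = G_b (k_ig_max / (k_xi I_b) - 1)^(1/gamma)` — the half-saturation
  glycemia of secretion is pinned by requiring basal secretion to equal
  basal insulin turnover `k_xi I_b`.

This closure was a genuinely open design point: two equilibrium conditions
(the glucose and insulin equations) must determine four quantities. We chose
the term-wise balance for the glucose equation (each hepatic term offsets
its corresponding disposal term) and the `lambda_2g` tie because it is the
only closure we found that (a) zeroes both derivatives exactly for every
admissible parameter combination, (b) leaves exactly the seven reported
parameters free, and (c) keeps all determined quantities non-negative by
construction. A combination where maximal secretion cannot sustain basal
turnover (`k_ig_max <= k_xi I_b`) has no steady state and is rejected with a
typed error; during optimization it is treated as an infinite-loss penalty.

### Fixed parameters

Identifiability from 14 samples forces part of the parameter set to
literature-calibrated constants (`simo_fixed()`):

| symbol | value | unit | rationale |
|---|---|---|---|
| `V` | 0.19 | L/kg | standard glucose distribution space |
| `k_xg` | 0.001 | 1/min | small non-insulin-dependent disposal (red cells, brain handled as constant) |
| `k_gj` | 0.042 | 1/min | leaves 8% of a jejunal bolus after 60 min of absorption-only elimination |
| `f_gj` | 0.02 | mM/mmol | 50 mmol gut glucose acts as +1 mM glycemia |
| `k_rj` | 0.09 | 1/min | with `k_lr`, moves essentially all jejunal glucose to the ileum within 3 h |
| `k_lr` | 0.06 | 1/min | see `k_rj` |

The default estimation set is `{k_js, k_gl, k_xgi, k_xi, k_ig_max, gamma,
lambda_1g}` with the bioavailable fraction `f` held at 1 — seven free
parameters. The partition is configuration-driven (`estimate` argument of
`simo_fit()`), since the seven-parameter count admits other splits; this
default matches the set of parameters for which group-level estimates are
reported in the literature the model derives from.

## Estimation

Single-subject identification is weighted least squares on log-parameters
(`simo_fit()`): positivity for free, multiplicative uncertainty structure,
and a better-conditioned simplex geometry. The error model is proportional,
with channel CVs fixed at 22% (glucose) and 31% (insulin) — in-vivo
variation estimates, deliberately much larger than assay repeatability. The
loss is

$$\sum_{\text{valid } G} \frac{(y - \hat y)^2}{\hat y^2 \,CV_G^2}
 + \sum_{\text{valid } I} \frac{(y - \hat y)^2}{\hat y^2 \,CV_I^2},$$

with the expectations $\hat y$ taken as the *model predictions*, recomputed
at every evaluation (iteratively reweighted). Weighting by predictions
rather than by noisy observations is deliberate: treating noisy data as
truth in the weights is exactly the statistical inconsistency the
model-based approach is meant to avoid. (The alternative literal reading of
"multiplying by squared coefficients of variation" — which would up-weight
the noisier channel — contradicts the stated error model and was rejected.)

The optimizer is Nelder–Mead throughout: five deterministic starts on a
log-space lattice around physiological mid-values (offsets 0, ±0.7, ±0.7
alternating), a cheaper exploratory tolerance for the screen, then repeated
restarts of the winner until a restart improves the loss by less than 1e-6
relative. Ties between starts break toward the lower `k_xgi`. Everything is
seedless and reproducible. Basal values are taken from the t = 0 sample and
treated as known constants, not estimated: they parameterize the
steady-state closure.

Uncertainty: the asymptotic covariance of the log-estimates is
$(J^\top S^{-1} J)^{-1}$ with `J` the central-finite-difference sensitivity
matrix (relative step 1e-4) and `S` the diagonal error covariance
$\hat y^2 CV^2$ at the optimum. An information matrix with condition number
above 1e12 is reported as *not computable* — an outcome, not an error.
Per-parameter CVs are reported in two conventions: `cv_log` (the log-scale
SE, which is also the first-order delta-method CV of the natural-scale
estimate) and `cv_natural` (`sqrt(exp(se^2) - 1)`, exact under
log-normality); the two agree for well-identified parameters.

## Numerical choices

The inner integrator is a compiled adaptive Dormand–Prince 5(4) stepper
(relative tolerance 1e-8, absolute 1e-10) written for this model: a subject
fit evaluates the loss a few thousand times, and the stiff general-purpose
interface would dominate runtime. `deSolve::lsoda` drives the identical
right-hand side as an independent cross-check (`simo_simulate(method =
"lsoda")`); the two routes agree to well within 0.1% and halving tolerances
moves solutions by far less than 0.1%. The system is non-stiff in the
physiological parameter range (rates 0.001–0.15 1/min over 180 min), so an
explicit embedded pair is appropriate. States are clamped at zero against
1e-8-scale round-off undershoot; the Hill term treats a non-positive drive
as zero secretion.

## Synthetic cohorts

No clinical OGTT dataset is distributed, so every downstream stage is
exercised on synthetic cohorts (`generate_cohort()`) with the assumed
population structure: log-parameters multivariate normal per group
(log-normal individual parameters), measurement error additive-normal with
SD equal to prediction × CV (truncated at a small positive floor to keep
observations physical; a log-normal error family is available as an
option). The per-group defaults (`simo_cohort_defaults()`) use the published
group means/SDs for `k_xgi` (NGT 8.62e-5 ± 9.36e-5 down to IGT
2.09e-5 ± 1.95e-5 1/(min pM)), `gamma` (4.42 ± 0.96 to 7.98 ± 5.51),
`k_ig_max` and `lambda_1g`, plus group basal glucose/insulin and body-weight
distributions from the corresponding published group descriptives.
Group values for `k_js`, `k_gl` and `k_xi` are not published anywhere we can
cite; they are physiological placeholders (0.035, 0.025, 0.05 1/min, 30%
CV), chosen once for internal consistency — basal secretion `k_xi * I_b`
must sit well below the published `k_ig_max` magnitudes — and labelled
synthetic. Between-parameter correlations default to zero (diagonal
log-covariance) unless a full matrix is supplied. Basal samples are kept
noise-free because the fitting convention treats them as known.

What passing tests on these cohorts shows — and does not show. The
generator emulates the assumed statistical structure exactly (log-normal
parameters, proportional noise, the standard 7-point grid, the 5-of-7
validity rule), so recovery and calibration results demonstrate internal
consistency of the whole pipeline under its own assumptions. They cannot
demonstrate robustness to model misspecification, non-normal parameter
distributions, correlated assay errors, or irregular sampling, none of
which the generator produces.

## Validation apparatus

* **Visual predictive check** (`simo_vpc()`): per group, 200 replicate
  simulations per subject with parameters drawn from the (two-stage) group
  multivariate normal and noise from the error model; 5th/25th/50th/75th/95th
  percentile curves computed *pooling all replicates in the group* at each
  nominal time (the alternative — per-subject percentiles then aggregation —
  is noted as an open convention; pooling matches group-panel overlays of
  all observations). Band ordering is asserted on every result. On a
  well-specified synthetic cohort the 90% band covers close to 90% of
  held-out observations.
* **Residual diagnostics** (`residual_diagnostics()`): weighted residuals
  `(y - yhat)/(yhat CV)` against time and against prediction, plus
  observed-versus-predicted, per channel.
* **Group statistics** (`group_anova()`, `cv_summary()`,
  `correlation_matrix()`, `trimmed_subset()`): one-way ANOVA, all pairwise
  LSD t-tests on the pooled within-group variance with Hochberg step-up
  adjustment, homogeneous subsets by greedy merging of mean-ordered groups
  (the originating software's exact subset algorithm is unspecified; greedy
  merging is our documented convention), sample CVs with the n-1 SD, and
  Pearson correlation panels with significance tiers. Percentile trimming
  (20th–80th) uses linear interpolation between closest ranks (type 7) and
  attaches its band to the result so re-trimming is idempotent.

## Empirical index panel

`ogtt_indices()` computes the classical surrogate indices: HOMA-IS
(22.5 / (G_b[mM] · I_b[mU/L]), the reciprocal HOMA-IR), HOMA-BCF
(20 · I_b[mU/L] / (G_b − 3.5)), the naive sensitivity index IS_NAIF
(1 / mean glycemia), trapezoid AUCs of glucose and insulin on the observed
grid (no interpolation of missing points), their ratio AUCrig, the
insulinogenic index (I30 − I0)/(G30 − G0), and the 2-hour glucose. Insulin
enters the HOMA formulas in mU/L through a configurable conversion factor
(default 6.945 pmol/L per mU/L); the HOMA/insulinogenic formulas themselves
are the standard literature forms and are documented here because group-level
magnitudes cannot adjudicate individual-level formula variants. OGIS,
ISIcomp, MCRest and similar externally defined indices are deliberately not
implemented — their defining algorithms live in external references — but
plug in through the `extra` argument.

## Problem sizes used in the shipped studies

The packaged simulation studies run at sizes chosen to give stable Monte
Carlo answers on a single workstation core: 50 noise replicates for the
stochastic-recovery study, 20 seeded replicates of a 5 × 15-subject cohort
for the group-separation study (a deliberately scaled-down analogue of the
published 78-subject comparison), and 200 VPC replicates per subject — the
same replicate count used for the published check.

## Known limitations

* The stomach-emptying law is linear; nonlinear gastric emptying is out of
  scope.
* Basal values are treated as error-free constants; their measurement error
  propagates unmodelled into the steady-state closure.
* The asymptotic covariance is only as good as the asymptotic regime: with
  7 parameters and 14 samples some fits sit near the identifiability
  boundary, where the marginal SEs of weakly identified parameters
  (typically `lambda_1g`, `k_gl`) become very large or the information
  matrix is flagged not-computable.
* GLP-1/GIP concentrations are not modelled as observables; the incretin
  signal is a pure function of gut glucose content.
* Two-stage population summaries (sample mean/covariance of per-subject
  estimates) are used throughout; full nonlinear mixed-effects estimation is
  a non-goal.

## A worked example

```{r example, eval = FALSE}
# one synthetic NGT-like subject, fitted and summarized
cohort <- generate_cohort(simo_cohort_defaults(n = c(NGT = 1)), seed = 1)
fit <- simo_fit(cohort)
tidy(fit)
glance(fit)
autoplot(fit)

# empirical indices and group statistics on a five-group cohort
cohort5 <- generate_cohort(simo_cohort_defaults(), seed = 2)
panel <- ogtt_indices(cohort5)
group_anova(panel, "IS_NAIF")
```
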