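# simogtt

Mechanistic modelling of the oral glucose tolerance test (OGTT) for people
who need per-subject insulin sensitivity and secretion indices from routine
clinical data: diabetologists, physiologists and modellers working with
7-point glucose/insulin curves.

A standard OGTT yields just fourteen numbers per subject — glucose and
insulin at 0, 30, 60, 90, 120, 150 and 180 min after a 75 g oral glucose
load. `simogtt` interprets them with a six-compartment ODE model in which
the glucose bolus transits stomach → jejunum → (delay) → ileum, is absorbed
into plasma, and gut glucose content additionally potentiates insulin
secretion (the incretin effect). Plasma glucose balances insulin-independent
disposal (`k_xg G`), insulin-dependent disposal (`k_xgi I G`), net hepatic
glucose output suppressed exponentially by glycemia and insulinemia, and
intestinal appearance; insulin balances first-order elimination against a
saturating Hill-type secretion with exponent `gamma` driven by
`G + f_gj (J + L)`:

    dG/dt = -k_xg G - k_xgi I G + T_1g e^(-lambda_1g G) + T_2gi e^(-lambda_2g G I)
            + f (k_gj J + k_gl L) / (V BW)
    dI/dt = -k_xi I + k_ig_max H^gamma / (G*^gamma + H^gamma),   H = G + f_gj (J + L)

Seven parameters are estimated per subject by weighted least squares on
log-parameters (proportional error, CV 22% glucose / 31% insulin,
multi-start Nelder–Mead); `T_1g`, `T_2gi`, `lambda_2g` and the secretion
half-saturation `G*` follow from the basal steady state. The headline
output is `k_xgi`, a per-subject insulin sensitivity index with the same
dimensions as the minimal-model S_I, plus asymptotic standard errors.

The package also provides:

* empirical index panel: HOMA-IS, HOMA-BCF, IS_NAIF, AUCs, insulinogenic
  index, 2-h glucose (`ogtt_indices()`);
* synthetic OGTT cohorts with log-normal individual parameters and
  proportional measurement error for five glucose-tolerance groups
  (`generate_cohort()`, `simo_cohort_defaults()`);
* validation tooling: visual predictive checks with percentile bands
  (`simo_vpc()`), weighted-residual diagnostics
  (`residual_diagnostics()`);
* group statistics: one-way ANOVA with LSD post-hoc tests under Hochberg
  correction and homogeneous subsets, 20th–80th percentile trimming,
  CV summaries, correlation panels (`group_anova()` and friends);
* CSV/YAML I/O with explicit unit declaration (mg/dl ↔ mM, mU/L ↔ pM) and a
  small CLI (`inst/cli/simo.R`).

## Worked example

```r
library(simogtt)

# simulate one NGT-like subject and identify it back
free  <- simo_free(k_js = 0.03, k_gl = 0.02, k_xgi = 8.62e-5, k_xi = 0.06,
                   k_ig_max = 46, gamma = 4.42, lambda_1g = 0.58)
basal <- simo_basal(4.748, 50.6)                    # mM, pM
dose  <- dose_to_mmol(75, "g")                      # 416.3 mmol
traj  <- simo_simulate(free, simo_fixed(), basal, dose, body_weight = 75,
                       times = seq(0, 180, 30))
traj[, c("time", "G", "I")]
#>    time     G     I
#> 1     0  4.75  50.6
#> 2    30  8.78 392.
#> 3    60  8.58 657.
#> 4    90  7.07 592.
#> 5   120  6.16 401.
#> 6   150  5.68 245.
#> 7   180  5.33 153.

obs <- tibble::tibble(subject = "s1", time = traj$time, glucose = traj$G,
                      insulin = traj$I, dose = dose, weight = 75)
fit <- simo_fit(obs)
tidy(fit)[, c("parameter", "estimate")]
#>   parameter  estimate
#> 1      k_js  3.00e-02
#> 2      k_gl  2.00e-02
#> 3     k_xgi  8.62e-05
#> 4      k_xi  6.00e-02
#> 5  k_ig_max  4.60e+01
#> 6     gamma  4.42e+00
#> 7 lambda_1g  5.80e-01
```

The simulated curve peaks at 8.8 mM glucose / 657 pM insulin around 30–60
min and relaxes toward basal — a typical normal-tolerance response — and the
noise-free fit recovers every generating parameter to well under 1%
relative. On noisy data (`generate_cohort()`) the estimates scatter around
the truth with the insulin sensitivity `k_xgi` as the most precisely
recovered parameter.

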