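---
title: "Methods: virtual-population validation of ML concentration prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-population validation of ML concentration prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model

`pkmlval` validates regression learners that predict a drug's plasma
concentration at an arbitrary time from seven observable quantities:
target time, infusion rate, age, lean body mass (LBM), infusion duration
(`TINFCAT`), and two anchor concentrations measured in the same patient
(Cp at the end of infusion and at four times the infusion duration). The
ground truth comes from a population-pharmacokinetic (PPK) simulator.

Each virtual subject is a draw from a three-compartment covariate model.
A structural parameter `P` (central volume `V1`, peripheral volumes
`V2`, `V3`, elimination clearance `CL1`, inter-compartmental clearances
`CL2`, `CL3`) has typical value linear in centred covariates and a
log-normal individual deviation:

```
P_i = (theta0 + theta_age (age_i - 40) + theta_lbm (lbm_i - 55)) * exp(eta_i),
eta_i ~ N(0, omega^2),   age ~ U(20, 85) yr,   lbm ~ U(36, 76) kg
```

The built-in remifentanil parameterisation (`remifentanil_ppk_model()`)
uses litres and litres/minute; concentrations are reported in ug/L and
times in minutes. The six `eta` terms are sampled **independently**: the
covariate model specifies only marginal variances, and no joint
(covariance) information is available, so independence is the minimal
assumption. This choice matters for interpretation (see *Limitations*).
No residual (intra-individual) error is added to virtual profiles; the
virtual arm isolates inter-individual variability, while the clinical
synthesizer adds measurement noise explicitly.

Covariates outside the stated uniform ranges can drive typical values
(especially `CL3`) non-positive; `typical_params()` signals this rather
than clamping, because the covariate equations are only claimed to be
valid over the sampled ranges.

## Kinetics

Amounts in the mammillary three-compartment system under a zero-order
infusion satisfy `dA/dt = K A + b(t)` with the usual micro rate
constants (`k10 = CL1/V1`, `k12 = CL2/V1`, `k21 = CL2/V2`,
`k13 = CL3/V1`, `k31 = CL3/V3`) and `b = (rate, 0, 0)` while `t <=
TINFCAT`. `simulate_profile()` evaluates the analytic solution through
an eigendecomposition of `K`, with the `phi(l, t) = (e^{lt} - 1)/l` term
taken in its `l -> 0` limit so degenerate cases (e.g. `CL2 = CL3 = 0`,
the one-compartment limit) remain exact. If the eigenbasis is
numerically ill-conditioned the solver falls back to a matrix
exponential on the input-augmented system, which requires no inversion
of `K`. Because the solution is analytic, requested times are evaluated
exactly — there is no interpolation error at feature time points, and no
cached grid is needed. The test suite pins the solver to a stiff ODE
oracle (`deSolve::lsoda`, relative tolerance 1e-6 over 50 random
parameter sets), to the one-compartment closed form at 1e-9, and to mass
balance.

## Cohort design

Clustering uses four per-subject features: age, LBM, Cp at 10 min and Cp
at 40 min — the two PPK covariates plus summaries of the end-of-infusion
and elimination phases under the reference regimen (227 ug/min for 10
min). `cluster_population()` runs Ward-linkage agglomerative clustering
(`hclust`, `ward.D2`) on Euclidean distances, `k = 10` by default.

**Raw versus standardised features.** The features are incommensurate
(years, kg, ug/L), so z-scoring would be the conventional statistical
choice, and it is available via `scale = TRUE`. The default, however, is
raw units, for two reasons: common agglomerative-clustering
implementations do not standardise by default, and the centroid
distances this produces (near clusters around 20 raw units, far clusters
of 50-130) are on the scale practitioners of this design report, whereas
standardised distances live on an entirely different scale (order 1-5).
Raw clustering lets the high-variance features (age, Cp10) dominate
cluster shape; that is a property of the design being emulated, not an
accident.

The test cluster is chosen uniformly at random (seeded); the *near* and
*far* training clusters minimise/maximise centroid distance to it, ties
broken toward the lowest label. 100 test subjects are sampled uniformly
from the test cluster and nested training subsets (default 10, 50, 100,
500, 1000 subjects; each a prefix of the next) are drawn without
replacement from each training cluster. Ward clusters of 10,000 subjects
vary in size (roughly 200-2300 across seeds), so a requested subset can
exceed its source cluster; the subset is then capped at the cluster size
and the actual count is recorded in the results (`size_actual`). This
keeps every (cluster, size) cell defined on every seed at the cost of
occasionally shrinking the largest cells.

## Feature extraction

For virtual subjects all values are read exactly off the simulated
profile. For clinical records, whose sampling times are irregular, two
schemes mirror how sampling schedules are planned: fixed clock times (5,
15, 30, 50, 100 min) and multiples of the infusion duration (0.5, 1.5,
3, 5, 10 x `TINFCAT`). Each grid time takes the nearest observed sample;
the matching window defaults to half the gap to the adjacent grid time,
ties go to the earlier sample, and unmatched grid times are dropped
rather than imputed (mirroring how subjects with unusable schedules are
excluded rather than filled in). Anchor concentrations are likewise
nearest samples, with a window of half the distance between the two
anchor times; an unresolvable anchor is an error because every row of
that subject would be invalid. A multiple of 1 would copy the
`cp_tinf` anchor into the objective and is flagged with a leakage
warning.

Cross-validation folds (`kfold_split()`, default k = 5) are drawn at the
*subject* level: rows of one subject share covariates and anchors, so
row-level folds would leak test information into training.

## Learners and tuning

All methods are fit on `log10(y)`: concentrations span several decades,
the evaluation metric is log-scale, and back-transforming `10^pred`
guarantees positive output. The naive `average` baseline is the
arithmetic mean concentration of the training rows at each time group —
the classical naive-average-data predictor — with unseen times mapped to
the nearest trained time (earlier on ties).

Tunable methods use compact, literature-standard grids
(`default_grid()`): six decades of log-spaced `lambda` for lasso/ridge,
`k in {3,5,7,11}` for kNN, a 3x3 log grid in cost/gamma for the RBF SVM,
`mtry in {2,4,7}` (300 trees) for the random forest, depth/rounds grids
for the two boosters, and width/decay for the neural network. Grids are
data-frame valued and overridable per experiment
(`experiment_config(grids = ...)`). Tuning holds out 20% of training
*subjects* (seeded), scores each grid point by validation log10-MSE,
takes the first minimum (deterministic tie-break in grid order) and
refits on all training rows. Gradient boosting and extreme gradient
boosting are both backed by the `xgboost` library with distinct grids
(shallow-tree, low-learning-rate settings for `gb`, the conventional
deeper/faster grid for `xgb`); the method labels are preserved in all
outputs. Constant feature columns (rate and infusion duration in the
fixed-regimen virtual arm) receive unit scale in the shared feature
scaler so distance-based methods remain well-defined.

## Metrics

`mse_log()` and `r2_log()` compute `1/n Σ (log10 ŷ − log10 y)²` and
`1 − SSres/SStot` on log10 values. Whether such metrics are meant in
base 10 or base e is a recurring ambiguity in this literature; base 10
is the default here because it matches log-axis plotting conventions,
and every result table carries natural-log companions (`mse_ln`,
`r2_ln`, a factor `ln(10)² ≈ 5.30` apart) so results remain comparable
under either reading. Both metrics are invariant to a change of
concentration units. Pooled ("overall") MSE is the mean over rows — the
count-weighted mean of per-group MSEs — while *size-averaged* summaries
are unweighted means of the five per-size overall values. `R²` is `NA`
(flagged, not fabricated) for groups with fewer than two distinct
observations. Cross-validated cells are reported as mean ± SD across
folds.

## The synthetic clinical cohort

`synthesize_cohort()` stands in for a real infusion dataset so the
clinical arm runs without any download. It emulates the published
marginal statistics of a 64-subject remifentanil cohort: infusion rate
from a truncated log-normal moment-matched to mean 227 ug/min and SD 101
(clipped to 63-750) and duration matched to mean 10 min, SD 4 (clipped
to 4-20) — log-normals because the reported dosing statistics are
right-skewed (median below mean); covariates from the same uniforms as
the virtual arm; sampling schedules covering both extraction grids with
3% proportional jitter; and multiplicative log-normal residual error
with a 15% CV, a typical bioanalytical magnitude. Rate and duration are
drawn independently — no joint information is available to calibrate a
correlation.

What the generator does *not* emulate: real sampling schedules (often
sparser and clustered early), assay quantification limits, covariate
distributions of a real clinic (true age distributions are not uniform),
correlated random effects, and model misspecification (the synthetic
"patients" obey the same compartment model the simulator uses). A
passing clinical-arm test therefore demonstrates that the pipeline is
correct and that the learners extract the available signal — not that
the same accuracy would be achieved on real patients.

## Reproducibility

Every stochastic stage owns a seed derived from the master seed by a
documented string hash (`derive_seed(master, stage, ...)`), so whole
experiments are byte-reproducible from `experiment_config()` alone and
any single (method, cluster, size, fold) cell can be re-run in
isolation. Learner backends are pinned to single-threaded, seeded
execution. The acceptance script replays the full virtual experiment
(10,000 subjects) in about a minute on one CPU; the test suite uses the
same scale for the end-to-end checks and smaller cohorts (tens to
hundreds of subjects) for unit-level properties, which keeps the whole
suite in the minutes range without weakening the full-scale checks.

## Limitations

The anchors constrain only two directions of the six-dimensional
random-effect space. With independent `eta`, the concentration at
intermediate times (between the anchors) and late times (beyond the
second anchor) is therefore *not* a deterministic function of the seven
explanatory variables: an irreducible conditional spread remains, is
smallest during the infusion, and grows into the elimination phase. Two
practical consequences show up in the full-scale experiments. First,
every learner plateaus well above zero log-scale error at 15-100 min no
matter how large the training set. Second, for a *far* training cluster
the error is dominated by extrapolation bias rather than estimation
variance, so increasing the training size need not reduce it
monotonically. Under correlated (effectively low-rank) inter-individual
variability the same two anchors would pin essentially the whole
random-effect vector and the profile with it, leaving learners far less
residual error; results from this design are thus highly sensitive to
the assumed random-effect structure, which is exactly why the generator
states its independence assumption explicitly.

Other limitations: single continuous infusions only (no absorption, lag,
nonlinear elimination or repeated dosing); no NLME estimation (the
simulator is generative only); hierarchical clustering is quadratic in
subjects, so populations much beyond ~20,000 would need a different
designer.
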