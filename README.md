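# pkmlval

Validation tooling for machine-learning prediction of drug plasma
concentration–time profiles, with remifentanil as the built-in worked
system.

## The problem

Population pharmacokinetics (PPK) describes how a drug's
concentration–time course varies across patients: typical trends are
covariate equations (here in age and lean body mass, LBM), and
inter-individual variability (IIV) enters as log-normal random effects.
An increasingly popular alternative to nonlinear mixed-effects modelling
is to train regression learners that map a handful of observable
quantities — the prediction target time, the infusion regimen, the
covariates, and one or two *anchor* concentrations already measured in
that patient — directly to the concentration at the target time. Before
trusting such a model in the clinic one wants to know how its accuracy
depends on (a) how *similar* the training patients are to the test
patients and (b) how *many* training patients are available.

`pkmlval` rebuilds that validation study end to end:

1. **Virtual population.** Subjects are drawn from a three-compartment
   covariate model. For parameter `P` with intercept `θ0`, age slope
   `θa` and LBM slope `θl`:

   `P_i = (θ0 + θa (age_i − 40) + θl (lbm_i − 55)) · exp(η_i)`,
   `η_i ~ N(0, ω²)`, `age ~ U(20, 85)`, `lbm ~ U(36, 76)`.

   The built-in remifentanil model has volumes `V1, V2, V3` (L),
   clearances `CL1, CL2, CL3` (L/min) and IIV variances
   `ω² = (0.26, 0.29, 0.66, 0.14, 0.36, 0.41)`.
2. **Kinetics.** Plasma concentration under a constant-rate infusion is
   solved analytically (eigendecomposition of the mammillary
   micro-rate-constant matrix), exact at every requested time, and
   verified in the tests against a stiff ODE integrator to 1e-6.
3. **Cohort design.** Subjects are clustered (Ward agglomerative
   clustering on age, LBM, Cp at 10 min and Cp at 40 min); one cluster is
   the test set and the nearest/farthest clusters (centroid distance)
   supply nested training subsets of 10–1000 subjects.
4. **Learners.** Lasso, ridge, kNN, SVM, random forest, gradient
   boosting, extreme gradient boosting and a neural network, each tuned
   by grid search on a subject-level 20% validation split, all fit on
   `log10` concentration — plus the classical naïve-average baseline
   (per-time-point mean of the training concentrations).
5. **Metrics.** `MSE = 1/n Σ (log10 ŷ − log10 y)²` and
   `R² = 1 − SSres/SStot` on the log scale, pooled and per time point
   (natural-log companions are reported for diagnosis).
6. **Synthetic clinical arm.** A generator emulates a real-world cohort
   (64 subjects; dose rate and infusion duration from truncated
   log-normals matched to mean 227 µg/min, SD 101, range 63–750 and mean
   10 min, SD 4, range 4–20; irregular sampling; 15% multiplicative
   residual error), evaluated by subject-level 5-fold cross-validation.

## Worked example

```r
library(pkmlval)

model    <- remifentanil_ppk_model()
pop      <- sample_population(model, 2000, seed = 42)
regimen  <- dosing_regimen(rate = 227, tinfcat = 10)
profiles <- simulate_cohort(pop, regimen, times = c(5, 10, 15, 30, 40, 50, 100))

feats      <- build_cluster_features(pop, profiles)
assignment <- cluster_population(feats, k = 10)
split      <- select_splits(assignment, test_size = 50, sizes = c(200, 50), seed = 1)
split
#> Split: test cluster 9 (n=50), near 4 (d=22.92), far 10 (d=128.71)
#>   near subsets: 172, 50
#>   far subsets: 34, 34

rows  <- virtual_feature_table(pop, profiles, regimen)
train <- rows[rows$subject_id %in% as.integer(split$train$near[["200"]]), ]
test  <- rows[rows$subject_id %in% as.integer(split$test_ids), ]

fit <- fit_cp_model(ml_spec("rf", seed = 1), train)
evaluate_cell(predict(fit, test), test, method = "rf", cluster = "near", size = 200L)
#>   time_group     mse    r2   n
#> 1        100 0.66191 0.331  50
#> 2         15 0.03260 0.369  50
#> 3         30 0.02377 0.873  50
#> 4          5 0.00421 0.682  50
#> 5         50 0.03300 0.902  50
#> 6    overall 0.15110 0.895 250
```

Reading the output: an overall log10-scale MSE of 0.151 means a typical
prediction misses the observed concentration by a factor of
`10^sqrt(0.151) ≈ 2.4`; accuracy is excellent during and shortly after
the infusion (MSE 0.004 at 5 min, i.e. ±16%) and deteriorates into the
elimination phase (0.66 at 100 min), where the profile depends on
slow-compartment kinetics that the anchor concentrations pin down only
loosely. The near training subsets here come from the cluster whose
centroid is 22.9 raw-feature units from the test cluster; the far
cluster is 128.7 units away and yields visibly worse cells.

The full experiment (both arms, all methods, full study-scale sizes) is
one call each:

```r
exp_v <- run_virtual(experiment_config(seed = 1))
exp_c <- run_clinical(experiment_config(methods = c("rf", "average"), seed = 1))
```

A thin command-line wrapper with subcommands `simulate-population`,
`synthesize-cohort`, `run-virtual` and `run-clinical` is installed at
`inst/cli/pkmlval`.

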