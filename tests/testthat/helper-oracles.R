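# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the ODE oracle integrates the compartment
# system numerically with deSolve, and the metric oracles are plain loops.

# Numeric integration of the mammillary 3-compartment infusion model; returns
# Cp at `times` plus the amounts and cumulative elimination for mass-balance
# checks.
ode_oracle <- function(params, rate, tinf, times) {
  V1 <- params[["V1"]]; V2 <- params[["V2"]]; V3 <- params[["V3"]]
  CL1 <- params[["CL1"]]; CL2 <- params[["CL2"]]; CL3 <- params[["CL3"]]
  k10 <- CL1 / V1; k12 <- CL2 / V1; k21 <- CL2 / V2
  k13 <- CL3 / V1; k31 <- CL3 / V3
  rhs <- function(t, A, parms) {
    r <- if (t <= tinf) rate else 0
    list(c(r - (k10 + k12 + k13) * A[1] + k21 * A[2] + k31 * A[3],
           k12 * A[1] - k21 * A[2],
           k13 * A[1] - k31 * A[3],
           k10 * A[1]))                      # cumulative elimination
  }
  grid <- sort(unique(c(0, tinf, times)))
  out <- deSolve::lsoda(c(0, 0, 0, 0), grid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  i <- match(times, out[, 1])
  list(cp = out[i, 2] / V1, amounts = out[i, 2:4, drop = FALSE],
       eliminated = out[i, 5])
}

# Brute-force log-scale metrics (explicit loops, base 10)
mse_log_oracle <- function(pred, obs) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (log10(pred[i]) - log10(obs[i]))^2
  s / length(pred)
}

r2_log_oracle <- function(pred, obs) {
  lo <- log10(obs)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(obs)) {
    ss_res <- ss_res + (log10(pred[i]) - lo[i])^2
    ss_tot <- ss_tot + (lo[i] - mean(lo))^2
  }
  1 - ss_res / ss_tot
}

# A small simulated cohort reused by feature/learner tests
tiny_cohort <- function(n = 30, seed = 7, rate = 227, tinf = 10,
                        times = c(5, 10, 15, 30, 40, 50, 100)) {
  model <- remifentanil_ppk_model()
  pop <- sample_population(model, n, seed = seed)
  regimen <- dosing_regimen(rate, tinf)
  profiles <- simulate_cohort(pop, regimen, times)
  list(model = model, pop = pop, regimen = regimen, profiles = profiles)
}

# A synthetic clinical record with exactly placed samples
exact_record <- function(id = 1, age = 40, lbm = 55, rate = 227, tinf = 10,
                         times = c(5, 10, 15, 30, 40, 50, 100),
                         params = typical_params(remifentanil_ppk_model(),
                                                 age, lbm)) {
  prof <- simulate_profile(params, dosing_regimen(rate, tinf), times)
  clinical_record(id, age, lbm, rate, tinf, times, prof$cp)
}
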