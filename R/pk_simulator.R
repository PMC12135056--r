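#' Constant-rate infusion dosing regimen
#'
#' @param rate infusion rate in ug/min (>= 0; a zero rate is the degenerate
#'   no-input regimen).
#' @param tinfcat infusion duration in min (> 0). The name follows the
#'   clinical dataset convention for the termination time of infusion.
#' @return an object of class `dosing_regimen` with fields `rate`, `tinfcat`
#'   and `dose = rate * tinfcat` (ug).
#' @export
dosing_regimen <- function(rate, tinfcat) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate < 0) {
    stop_pkmlval("rate must be a single finite non-negative number (ug/min)")
  }
  assert_positive_finite(tinfcat, "tinfcat")
  structure(list(rate = rate, tinfcat = tinfcat, dose = rate * tinfcat),
            class = "dosing_regimen")
}

# Micro rate-constant matrix of the mammillary 3-compartment model, in the
# standard clearance/volume parameterisation: elimination k10 = CL1/V1,
# distribution k12 = CL2/V1, k21 = CL2/V2, k13 = CL3/V1, k31 = CL3/V3.
rate_matrix <- function(params) {
  V1 <- params[["V1"]]; V2 <- params[["V2"]]; V3 <- params[["V3"]]
  CL1 <- params[["CL1"]]; CL2 <- params[["CL2"]]; CL3 <- params[["CL3"]]
  k10 <- CL1 / V1; k12 <- CL2 / V1; k21 <- CL2 / V2
  k13 <- CL3 / V1; k31 <- CL3 / V3
  matrix(c(-(k10 + k12 + k13), k21,  k31,
           k12,               -k21,  0,
           k13,                0,   -k31),
         nrow = 3, byrow = TRUE)
}

# Analytic amounts for zero-order input b = (rate, 0, 0) over [0, tinf]:
#   A(t)        = P diag(phi(l, t)) P^-1 b                 (t <= tinf)
#   A(t)        = P diag(exp(l (t - tinf))) P^-1 A(tinf)   (t  > tinf)
# with phi(l, t) = (exp(l t) - 1)/l (limit t as l -> 0) and K = P diag(l)
# P^-1. Mammillary rate matrices are diagonalizable with real non-positive
# eigenvalues for essentially all parameter sets; if the eigenbasis is
# numerically degenerate we fall back to a matrix-exponential evaluation on
# the augmented (input-extended) system, which needs no inversion of K.
solve_amounts <- function(K, rate, tinf, times) {
  e <- eigen(K)
  scale <- max(abs(Re(e$values)), 1e-12)
  if (max(abs(Im(e$values))) > 1e-9 * scale || rcond(Re(e$vectors)) < 1e-10) {
    return(solve_amounts_expm(K, rate, tinf, times))
  }
  lam <- Re(e$values); P <- Re(e$vectors)
  phi <- function(t) ifelse(lam == 0, t, expm1(lam * t) / lam)
  cb <- solve(P, c(rate, 0, 0))
  amounts_inf <- function(t) drop(P %*% (cb * phi(t)))
  ca <- solve(P, amounts_inf(tinf))
  t(vapply(times, function(t) {
    if (t <= tinf) amounts_inf(t) else drop(P %*% (ca * exp(lam * (t - tinf))))
  }, numeric(3)))
}

solve_amounts_expm <- function(K, rate, tinf, times) {
  # augmented system: d/dt (A, u) = [[K, b], [0, 0]] (A, u), u(0) = 1, so
  # A(t) = expm(M t)[1:3, 4] during the infusion even when K is singular
  M <- rbind(cbind(K, c(rate, 0, 0)), 0)
  a_inf <- function(t) as.matrix(Matrix::expm(M * t))[1:3, 4]
  a_tinf <- a_inf(tinf)
  t(vapply(times, function(t) {
    if (t <= tinf) a_inf(t)
    else drop(as.matrix(Matrix::expm(K * (t - tinf))) %*% a_tinf)
  }, numeric(3)))
}

#' Simulate a plasma concentration-time profile
#'
#' Solves the mammillary three-compartment model under a constant-rate
#' intravenous infusion and returns the central-compartment concentration
#' `Cp = A1/V1` at exactly the requested times (the solution is analytic, so
#' no interpolation is involved at any time point).
#'
#' @param params named numeric 6-vector (or 1-row slice of a population)
#'   with `V1, V2, V3` (L) and `CL1, CL2, CL3` (L/min), all > 0.
#' @param regimen a [dosing_regimen()].
#' @param times sorted, non-negative times in min.
#' @param subject_id optional identifier carried into the result.
#' @return an object of class `conc_profile`: list with `subject_id`,
#'   `times` (min) and `cp` (ug/L).
#' @export
simulate_profile <- function(params, regimen, times, subject_id = NA_integer_) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  params <- unlist(params)[PK_PARAMS]
  if (any(is.na(params))) {
    stop_pkmlval("params must contain V1, V2, V3, CL1, CL2, CL3")
  }
  # volumes and the elimination clearance must be strictly positive; the
  # inter-compartmental clearances may be zero (degenerate 1-compartment case)
  assert_positive_finite(params[c("V1", "V2", "V3", "CL1")],
                         "volumes and elimination clearance")
  if (any(!is.finite(params[c("CL2", "CL3")])) ||
      any(params[c("CL2", "CL3")] < 0)) {
    stop_pkmlval("inter-compartmental clearances must be finite and >= 0")
  }
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0)) {
    stop_pkmlval("times must be finite and non-negative")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_pkmlval("times must be strictly increasing")
  }
  if (regimen$rate == 0) {
    cp <- numeric(length(times))
  } else {
    A <- solve_amounts(rate_matrix(params), regimen$rate, regimen$tinfcat, times)
    cp <- pmax(A[, 1], 0) / params[["V1"]]
  }
  structure(list(subject_id = subject_id, times = as.numeric(times), cp = cp),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile, subject %s (%d time points)\n",
              x$subject_id, length(x$times)))
  print(data.frame(time_min = x$times, cp = x$cp), row.names = FALSE)
  invisible(x)
}

#' Simulate profiles for a whole cohort
#'
#' Element-wise application of [simulate_profile()]; order is preserved and
#' per-subject failures are re-signalled with the subject id attached.
#'
#' @param population a `pk_population` data frame (or any data frame with an
#'   `id` column and `V1..CL3` columns).
#' @param regimen a single [dosing_regimen()] or a list with one per subject.
#' @param times a single time grid or a list with one grid per subject.
#' @return a named list of `conc_profile` objects, names = subject ids.
#' @export
simulate_cohort <- function(population, regimen, times) {
  n <- nrow(population)
  if (n == 0) return(list())
  regimens <- if (inherits(regimen, "dosing_regimen")) {
    rep(list(regimen), n)
  } else regimen
  grids <- if (is.list(times)) times else rep(list(times), n)
  if (length(regimens) != n || length(grids) != n) {
    stop_pkmlval("need one regimen and one time grid per subject")
  }
  params <- population_params(population)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- tryCatch(
      simulate_profile(params[i, ], regimens[[i]], grids[[i]],
                       subject_id = population$id[i]),
      error = function(e) {
        stop_pkmlval("subject ", population$id[i], ": ", conditionMessage(e))
      })
  }
  names(out) <- as.character(population$id)
  out
}

#' Read/write profiles as long-format CSV
#'
#' Columns `subject_id`, `time_min`, `cp`.
#'
#' @param profiles a list of `conc_profile` objects.
#' @param path file path.
#' @return `read_profiles` returns a named list of `conc_profile` objects.
#' @export
write_profiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, time_min = p$times, cp = p$cp)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tab <- read.csv(path)
  need <- c("subject_id", "time_min", "cp")
  if (!all(need %in% names(tab))) {
    stop_pkmlval("profile file needs columns ", paste(need, collapse = ", "))
  }
  lapply(split(tab, factor(tab$subject_id, levels = unique(tab$subject_id))),
         function(d) {
           structure(list(subject_id = d$subject_id[1], times = d$time_min,
                          cp = d$cp), class = "conc_profile")
         })
}

# Fetch Cp at an exact grid time from a profile; used by the feature builder
# and the cluster designer, which require exact (not interpolated) values.
profile_cp_at <- function(profile, time, tol = 1e-8) {
  i <- which(abs(profile$times - time) <= tol)
  if (length(i) != 1) {
    stop_pkmlval("profile for subject ", profile$subject_id,
                 " has no sample at exactly t = ", time, " min")
  }
  profile$cp[i]
}
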