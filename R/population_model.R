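#' Population pharmacokinetic covariate model
#'
#' A `pop_model` holds the fixed-effect (typical value) covariate equations
#' and the inter-individual variability (IIV) variances of a mammillary
#' three-compartment infusion model. Each of the six structural parameters
#' (central volume `V1`, peripheral volumes `V2`, `V3`, elimination clearance
#' `CL1`, inter-compartmental clearances `CL2`, `CL3`) has a typical value
#' that is linear in centred age and lean body mass (LBM),
#' `TV = intercept + b_age * (age - age_ref) + b_lbm * (lbm - lbm_ref)`,
#' and an individual value `TV * exp(eta)` with `eta ~ N(0, omega2)`.
#'
#' @param theta 6 x 3 numeric matrix of fixed effects; rows `V1, V2, V3,
#'   CL1, CL2, CL3`, columns `intercept`, `age`, `lbm`. Volumes in L,
#'   clearances in L/min, slopes per year and per kg.
#' @param omega2 named numeric vector of six IIV variances (log scale).
#' @param age_range,lbm_range sampling ranges (uniform) for the covariates,
#'   in years and kg.
#' @param age_ref,lbm_ref covariate centring constants.
#' @return an object of class `pop_model`.
#' @seealso [remifentanil_ppk_model()] for the built-in remifentanil model.
#' @export
pop_model <- function(theta, omega2,
                      age_range = c(20, 85), lbm_range = c(36, 76),
                      age_ref = 40, lbm_ref = 55) {
  theta <- as.matrix(theta)
  if (!all(dim(theta) == c(6, 3))) {
    stop_pkmlval("theta must be a 6 x 3 matrix (parameters x intercept/age/lbm)")
  }
  dimnames(theta) <- list(PK_PARAMS, c("intercept", "age", "lbm"))
  omega2 <- setNames(as.numeric(omega2), PK_PARAMS)
  if (any(!is.finite(omega2)) || any(omega2 <= 0)) {
    stop_pkmlval("all omega2 entries must be finite and > 0")
  }
  if (any(theta[, "intercept"] <= 0)) {
    stop_pkmlval("all typical-value intercepts must be > 0")
  }
  if (length(age_range) != 2 || diff(age_range) <= 0 ||
      length(lbm_range) != 2 || diff(lbm_range) <= 0) {
    stop_pkmlval("age_range and lbm_range must be proper intervals (lo < hi)")
  }
  structure(list(theta = theta, omega2 = omega2,
                 age_range = as.numeric(age_range),
                 lbm_range = as.numeric(lbm_range),
                 age_ref = age_ref, lbm_ref = lbm_ref),
            class = "pop_model")
}

PK_PARAMS <- c("V1", "V2", "V3", "CL1", "CL2", "CL3")

#' Built-in remifentanil population model
#'
#' The published age/LBM covariate model for remifentanil: typical values
#' linear in `(age - 40)` and `(lbm - 55)` with log-normal IIV, covariates
#' sampled uniformly on 20-85 years and 36-76 kg.
#'
#' @return a [pop_model()] object.
#' @export
remifentanil_ppk_model <- function() {
  theta <- rbind(
    V1  = c(5.1,   -0.0201,  0.072),
    V2  = c(9.82,  -0.0811,  0.108),
    V3  = c(5.42,   0,       0),
    CL1 = c(2.6,   -0.0162,  0.0191),
    CL2 = c(2.05,  -0.0301,  0),
    CL3 = c(0.076, -0.00113, 0)
  )
  omega2 <- c(V1 = 0.26, V2 = 0.29, V3 = 0.66,
              CL1 = 0.14, CL2 = 0.36, CL3 = 0.41)
  pop_model(theta, omega2)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK covariate model (3-compartment, infusion)\n")
  cat(sprintf("  age ~ U(%g, %g) yr (ref %g), lbm ~ U(%g, %g) kg (ref %g)\n",
              x$age_range[1], x$age_range[2], x$age_ref,
              x$lbm_range[1], x$lbm_range[2], x$lbm_ref))
  print(cbind(x$theta, omega2 = x$omega2))
  invisible(x)
}

#' Typical (fixed-effect) PK parameters at given covariates
#'
#' Evaluates the covariate equations at `eta = 0`. Vectorised over `age` and
#' `lbm` (recycled to common length).
#'
#' @param model a [pop_model()].
#' @param age age in years, finite and positive.
#' @param lbm lean body mass in kg, finite and positive.
#' @return for scalar input a named numeric vector `V1..CL3`; otherwise a
#'   matrix with one row per subject.
#' @export
typical_params <- function(model, age, lbm) {
  stopifnot(inherits(model, "pop_model"))
  assert_positive_finite(age, "age")
  assert_positive_finite(lbm, "lbm")
  n <- max(length(age), length(lbm))
  age <- rep_len(age, n); lbm <- rep_len(lbm, n)
  tv <- cbind(1, age - model$age_ref, lbm - model$lbm_ref) %*% t(model$theta)
  colnames(tv) <- PK_PARAMS
  if (any(tv <= 0)) {
    stop_pkmlval("typical value non-positive at the supplied covariates; ",
                 "the covariate model is only valid over its stated ranges")
  }
  if (n == 1) tv[1, ] else tv
}

#' Sample one virtual subject
#'
#' Draws covariates uniformly over the model ranges and the six IIV terms
#' independently from zero-mean normals with the model variances, using the
#' current RNG stream. Individual parameters are `typical * exp(eta)`.
#'
#' @param model a [pop_model()].
#' @param id integer subject identifier.
#' @return a one-row data frame with columns `id`, `age`, `lbm`,
#'   `eta_V1..eta_CL3`, `V1..CL3`.
#' @export
sample_subject <- function(model, id = 1L) {
  sample_population_rows(model, ids = as.integer(id))
}

#' Sample a virtual population
#'
#' @param model a [pop_model()].
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed; for a fixed seed the population is
#'   reproduced exactly. `NULL` uses the current RNG stream.
#' @return a `pk_population` data frame with `n` rows, ids `1..n`.
#' @export
sample_population <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "pop_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_pkmlval("n must be a single integer >= 1")
  }
  with_seed_or_not(seed, sample_population_rows(model, ids = seq_len(n)))
}

sample_population_rows <- function(model, ids) {
  n <- length(ids)
  age <- runif(n, model$age_range[1], model$age_range[2])
  lbm <- runif(n, model$lbm_range[1], model$lbm_range[2])
  eta <- vapply(PK_PARAMS,
                function(p) rnorm(n, 0, sqrt(model$omega2[[p]])),
                numeric(n))
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, PK_PARAMS))
  tv <- typical_params(model, age, lbm)
  if (n == 1) tv <- matrix(tv, nrow = 1, dimnames = list(NULL, PK_PARAMS))
  params <- tv * exp(eta)
  out <- data.frame(id = ids, age = age, lbm = lbm)
  colnames(eta) <- paste0("eta_", PK_PARAMS)
  out <- cbind(out, eta, params)
  class(out) <- c("pk_population", "data.frame")
  out
}

#' Extract the PK parameter matrix from a population
#'
#' @param population a `pk_population` data frame.
#' @return numeric matrix (subjects x 6) of individual parameters.
#' @export
population_params <- function(population) {
  as.matrix(population[, PK_PARAMS, drop = FALSE])
}

#' Read/write a virtual population as CSV
#'
#' Columns: `id`, `age`, `lbm`, `eta_V1..eta_CL3`, `V1..CL3`.
#'
#' @param population a `pk_population`.
#' @param path file path.
#' @return `read_population` returns a `pk_population`.
#' @export
write_population <- function(population, path) {
  write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- read.csv(path)
  need <- c("id", "age", "lbm", paste0("eta_", PK_PARAMS), PK_PARAMS)
  missing <- setdiff(need, names(pop))
  if (length(missing)) {
    stop_pkmlval("population file lacks columns: ", paste(missing, collapse = ", "))
  }
  class(pop) <- c("pk_population", "data.frame")
  pop
}

#' Read/write a population model as a YAML config
#'
#' Allows other drugs' covariate models to be swapped in from a structured
#' text file with fields `theta` (named rows of intercept/age/lbm), `omega2`,
#' `age_range`, `lbm_range`, `age_ref`, `lbm_ref`.
#'
#' @param model a [pop_model()].
#' @param path file path.
#' @return `read_pop_model` returns a [pop_model()].
#' @export
write_pop_model <- function(model, path) {
  obj <- list(
    theta = lapply(seq_len(6), function(i) as.list(setNames(
      model$theta[i, ], c("intercept", "age", "lbm")))),
    omega2 = as.list(model$omega2),
    age_range = model$age_range, lbm_range = model$lbm_range,
    age_ref = model$age_ref, lbm_ref = model$lbm_ref
  )
  names(obj$theta) <- PK_PARAMS
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pop_model
#' @export
read_pop_model <- function(path) {
  obj <- yaml::read_yaml(path)
  theta <- t(vapply(PK_PARAMS, function(p) {
    unlist(obj$theta[[p]])[c("intercept", "age", "lbm")]
  }, numeric(3)))
  pop_model(theta, unlist(obj$omega2)[PK_PARAMS],
            age_range = unlist(obj$age_range),
            lbm_range = unlist(obj$lbm_range),
            age_ref = obj$age_ref %||% 40, lbm_ref = obj$lbm_ref %||% 55)
}
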