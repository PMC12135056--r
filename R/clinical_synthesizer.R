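#' Specification of a synthetic clinical cohort
#'
#' Describes a real-world-like infusion cohort: per-subject dosing rate and
#' infusion duration drawn from truncated log-normal distributions
#' moment-matched to the target mean/SD (the printed cohort statistics of the
#' reference remifentanil dataset are the defaults), covariates drawn
#' uniformly as in the virtual population, irregular sampling schedules, and
#' multiplicative log-normal residual error on the observed concentrations.
#'
#' @param n number of subjects (>= 5).
#' @param rate_mean,rate_sd,rate_range target mean, SD and truncation bounds
#'   of the infusion rate (ug/min).
#' @param tinf_mean,tinf_sd,tinf_range same for the infusion duration (min).
#' @param residual_cv coefficient of variation of the multiplicative residual
#'   error (0 disables noise).
#' @param jitter_cv proportional jitter of the nominal sampling times (0
#'   disables jitter).
#' @param fixed_grid,tinf_multiples nominal sampling anchors: fixed clock
#'   times, and multiples of the infusion duration (1 and 4 are always
#'   included so the anchor concentrations are resolvable).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 64,
                        rate_mean = 227, rate_sd = 101,
                        rate_range = c(63, 750),
                        tinf_mean = 10, tinf_sd = 4, tinf_range = c(4, 20),
                        residual_cv = 0.15, jitter_cv = 0.03,
                        fixed_grid = c(5, 15, 30, 50, 100),
                        tinf_multiples = c(0.5, 1.5, 3, 5, 10)) {
  if (n < 5) stop_pkmlval("n must be >= 5")
  for (rng in list(rate_range, tinf_range)) {
    if (length(rng) != 2 || diff(rng) <= 0) {
      stop_pkmlval("truncation bounds must be proper intervals")
    }
  }
  if (rate_mean <= rate_range[1] || rate_mean >= rate_range[2] ||
      tinf_mean <= tinf_range[1] || tinf_mean >= tinf_range[2]) {
    stop_pkmlval("target means must lie inside the truncation bounds")
  }
  structure(list(n = n, rate_mean = rate_mean, rate_sd = rate_sd,
                 rate_range = rate_range, tinf_mean = tinf_mean,
                 tinf_sd = tinf_sd, tinf_range = tinf_range,
                 residual_cv = residual_cv, jitter_cv = jitter_cv,
                 fixed_grid = fixed_grid, tinf_multiples = tinf_multiples),
            class = "cohort_spec")
}

# Log-normal moment matching: meanlog/sdlog reproducing the target arithmetic
# mean and SD, then rejection-sampled into the truncation bounds (the
# clinical dosing statistics are right-skewed: median < mean).
rlnorm_truncated <- function(n, mean, sd, range) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  out <- numeric(0)
  for (tries in 1:1000) {
    draw <- stats::rlnorm(2 * n, meanlog, sqrt(sdlog2))
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop_pkmlval("truncation bounds reject nearly all draws; spec unsatisfiable")
}

#' Synthesize a clinical cohort
#'
#' Per subject: covariates and regimen are drawn from the cohort-spec
#' distributions,
#' the true profile is simulated from the population model, sampling times
#' are placed near both extraction grids (fixed clock times and multiples of
#' the infusion duration) with proportional jitter, and observed
#' concentrations are the true values times `exp(eps)`,
#' `eps ~ N(0, log(1 + cv^2))`.
#'
#' @param spec a [cohort_spec()].
#' @param model the generating [pop_model()].
#' @param seed integer seed.
#' @return a list of [clinical_record()] objects. The generating population
#'   and regimens are attached as attributes `population` and `regimens` so
#'   simulator consistency is verifiable.
#' @export
synthesize_cohort <- function(spec, model = remifentanil_ppk_model(),
                              seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_or_not(seed, {
    pop <- sample_population_rows(model, ids = seq_len(spec$n))
    rate <- rlnorm_truncated(spec$n, spec$rate_mean, spec$rate_sd,
                             spec$rate_range)
    tinf <- rlnorm_truncated(spec$n, spec$tinf_mean, spec$tinf_sd,
                             spec$tinf_range)
    sigma <- sqrt(log(1 + spec$residual_cv^2))
    params <- population_params(pop)
    records <- vector("list", spec$n)
    regimens <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      regimen <- dosing_regimen(rate[i], tinf[i])
      nominal <- sort(unique(c(spec$fixed_grid,
                               tinf[i] * unique(c(1, 4, spec$tinf_multiples)))))
      jit <- if (spec$jitter_cv > 0) {
        pmax(pmin(rnorm(length(nominal), 0, spec$jitter_cv), 2 * spec$jitter_cv),
             -2 * spec$jitter_cv)
      } else rep(0, length(nominal))
      times <- sort(nominal * (1 + jit))
      times <- times[times > 0]
      times <- times[c(TRUE, diff(times) > 1e-6)]
      prof <- simulate_profile(params[i, ], regimen, times,
                               subject_id = pop$id[i])
      eps <- if (spec$residual_cv > 0) rnorm(length(times), 0, sigma) else 0
      records[[i]] <- clinical_record(
        subject_id = pop$id[i], age = pop$age[i], lbm = pop$lbm[i],
        rate = rate[i], tinfcat = tinf[i],
        times = times, cp = prof$cp * exp(eps))
      regimens[[i]] <- regimen
    }
    attr(records, "population") <- pop
    attr(records, "regimens") <- regimens
    records
  })
}

#' Read/write a clinical cohort as a NONMEM-style CSV
#'
#' One row per sample with columns `ID, TIME, DV, AGE, LBM, AMT, RATE,
#' TINFCAT` (`DV` = observed concentration, `AMT` = total dose).
#'
#' @param records a list of [clinical_record()] objects.
#' @param path file path.
#' @return `read_cohort` returns a list of [clinical_record()] objects.
#' @export
write_cohort <- function(records, path) {
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(ID = r$subject_id, TIME = r$samples$time, DV = r$samples$cp,
               AGE = r$age, LBM = r$lbm, AMT = r$dose, RATE = r$rate,
               TINFCAT = r$tinfcat)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

NONMEM_COLS <- c("ID", "TIME", "DV", "AGE", "LBM", "AMT", "RATE", "TINFCAT")

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path)
  records_from_table(tab)
}

records_from_table <- function(tab) {
  missing <- setdiff(NONMEM_COLS, names(tab))
  if (length(missing)) {
    stop_pkmlval("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(tab[NONMEM_COLS]))
  if (length(bad)) {
    stop_pkmlval("malformed cohort row(s) at line(s): ",
                 paste(head(bad + 1, 5), collapse = ", "))
  }
  lapply(split(tab, factor(tab$ID, levels = unique(tab$ID))), function(d) {
    d <- d[order(d$TIME), ]
    clinical_record(subject_id = d$ID[1], age = d$AGE[1], lbm = d$LBM[1],
                    rate = d$RATE[1], tinfcat = d$TINFCAT[1],
                    times = d$TIME, cp = d$DV, dose = d$AMT[1])
  })
}

#' Load a cohort from a spreadsheet with the NONMEM-style layout
#'
#' Reads an `.xlsx` sheet whose header matches the CSV layout of
#' [write_cohort()]. Requires the `readxl` package.
#'
#' @param path path to the workbook.
#' @param sheet sheet name or index.
#' @return a list of [clinical_record()] objects.
#' @export
read_cohort_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop_pkmlval("read_cohort_xlsx requires the readxl package")
  }
  records_from_table(as.data.frame(readxl::read_excel(path, sheet = sheet)))
}
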