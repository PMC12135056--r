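#' Feature rows from a simulated profile
#'
#' Builds the supervised-learning rows for one virtual subject: one row per
#' target time, carrying the seven explanatory variables (target time,
#' infusion rate, age, LBM, infusion duration, and the two anchor
#' concentrations Cp at the end of infusion and at four times the infusion
#' duration) plus the objective `y` = Cp at the target time. All values are
#' read exactly from the simulated grid; a missing required time is an error.
#'
#' @param profile a `conc_profile` containing `tinfcat`, `4 * tinfcat` and
#'   every target time exactly.
#' @param age,lbm subject covariates.
#' @param regimen the subject's [dosing_regimen()].
#' @param target_times prediction target times in min.
#' @return a data frame of feature rows with columns `subject_id`,
#'   `time_group`, [FEATURE_COLS] and `y`.
#' @export
rows_from_profile <- function(profile, age, lbm, regimen,
                              target_times = c(5, 15, 30, 50, 100)) {
  if (length(target_times) == 0) return(empty_feature_rows())
  tinf <- regimen$tinfcat
  cp_tinf <- profile_cp_at(profile, tinf)
  cp_4tinf <- profile_cp_at(profile, 4 * tinf)
  y <- vapply(target_times, function(tt) profile_cp_at(profile, tt), numeric(1))
  feature_rows(subject_id = profile$subject_id,
               time_group = as.character(target_times),
               target_time = target_times, rate = regimen$rate,
               age = age, lbm = lbm, tinfcat = tinf,
               cp_tinf = cp_tinf, cp_4tinf = cp_4tinf, y = y)
}

feature_rows <- function(subject_id, time_group, target_time, rate, age, lbm,
                         tinfcat, cp_tinf, cp_4tinf, y) {
  data.frame(subject_id = subject_id, time_group = time_group,
             target_time = target_time, rate = rate, age = age, lbm = lbm,
             tinfcat = tinfcat, cp_tinf = cp_tinf, cp_4tinf = cp_4tinf, y = y,
             stringsAsFactors = FALSE)
}

empty_feature_rows <- function() {
  feature_rows(subject_id = integer(), time_group = character(),
               target_time = numeric(), rate = numeric(), age = numeric(),
               lbm = numeric(), tinfcat = numeric(), cp_tinf = numeric(),
               cp_4tinf = numeric(), y = numeric())
}

#' Feature table for a whole virtual cohort
#'
#' @param population a `pk_population`.
#' @param profiles list of `conc_profile` objects (as from
#'   [simulate_cohort()]).
#' @param regimen the shared [dosing_regimen()].
#' @param target_times prediction target times in min.
#' @return row-bound output of [rows_from_profile()] for every subject.
#' @export
virtual_feature_table <- function(population, profiles, regimen,
                                  target_times = c(5, 15, 30, 50, 100)) {
  if (nrow(population) == 0 || length(target_times) == 0) {
    return(empty_feature_rows())
  }
  prof_for <- profile_lookup(profiles, population$id)
  need <- c(target_times, regimen$tinfcat, 4 * regimen$tinfcat)
  # column-wise assembly: one exact profile lookup per (subject, time)
  cp <- t(vapply(population$id, function(sid) {
    p <- prof_for(sid)
    vapply(need, function(tt) profile_cp_at(p, tt), numeric(1))
  }, numeric(length(need))))
  nt <- length(target_times)
  idx <- rep(seq_len(nrow(population)), each = nt)
  feature_rows(subject_id = population$id[idx],
               time_group = rep(as.character(target_times), nrow(population)),
               target_time = rep(target_times, nrow(population)),
               rate = regimen$rate, age = population$age[idx],
               lbm = population$lbm[idx], tinfcat = regimen$tinfcat,
               cp_tinf = cp[idx, nt + 1], cp_4tinf = cp[idx, nt + 2],
               y = as.vector(t(cp[, seq_len(nt)])))
}

#' A clinical record: one subject's dosing and sampled concentrations
#'
#' @param subject_id identifier.
#' @param age,lbm covariates (years, kg).
#' @param rate infusion rate (ug/min).
#' @param tinfcat infusion duration (min).
#' @param times,cp sampled times (min, sorted) and concentrations (ug/L);
#'   at least two samples are required so the anchors can be resolved.
#' @param dose total dose (ug); defaults to `rate * tinfcat`.
#' @return an object of class `clinical_record`.
#' @export
clinical_record <- function(subject_id, age, lbm, rate, tinfcat, times, cp,
                            dose = rate * tinfcat) {
  if (length(times) != length(cp) || length(times) < 2) {
    stop_pkmlval("need at least two samples with matching times and cp")
  }
  if (is.unsorted(times)) stop_pkmlval("samples must be time-sorted")
  structure(list(subject_id = subject_id, age = age, lbm = lbm, dose = dose,
                 rate = rate, tinfcat = tinfcat,
                 samples = data.frame(time = as.numeric(times),
                                      cp = as.numeric(cp))),
            class = "clinical_record")
}

# Nearest-sample resolution: the sample closest to `target` wins, ties broken
# toward the earlier time; NA when nothing falls inside the window.
nearest_sample <- function(samples, target, window) {
  gap <- abs(samples$time - target)
  i <- which(gap == min(gap))[1]          # order is time-sorted: first = earlier
  if (gap[i] > window) return(NULL)
  samples[i, ]
}

# Per-grid-point matching window: half the gap to the adjacent grid time
# (edge points use their single adjacent gap).
half_gap_windows <- function(grid) {
  if (length(grid) == 1) return(grid / 2)
  gaps <- diff(grid)
  vapply(seq_along(grid), function(j) {
    adj <- c(if (j > 1) gaps[j - 1], if (j < length(grid)) gaps[j])
    min(adj) / 2
  }, numeric(1))
}

extract_rows <- function(record, grid, labels, window = NULL) {
  stopifnot(inherits(record, "clinical_record"))
  o <- order(grid)
  grid <- grid[o]; labels <- labels[o]
  windows <- if (is.null(window)) half_gap_windows(grid) else rep_len(window, length(grid))
  anchors <- c(record$tinfcat, 4 * record$tinfcat)
  anchor_window <- diff(anchors) / 2
  cp_tinf <- nearest_sample(record$samples, anchors[1], anchor_window)
  cp_4tinf <- nearest_sample(record$samples, anchors[2], anchor_window)
  if (is.null(cp_tinf) || is.null(cp_4tinf)) {
    stop_pkmlval("subject ", record$subject_id, ": anchor concentrations at ",
                 "TINFCAT and 4 x TINFCAT cannot be resolved within ",
                 signif(anchor_window, 3), " min")
  }
  rows <- lapply(seq_along(grid), function(j) {
    s <- nearest_sample(record$samples, grid[j], windows[j])
    if (is.null(s)) return(NULL)    # unmatched grid times are dropped, not imputed
    feature_rows(subject_id = record$subject_id, time_group = labels[j],
                 target_time = s$time, rate = record$rate, age = record$age,
                 lbm = record$lbm, tinfcat = record$tinfcat,
                 cp_tinf = cp_tinf$cp, cp_4tinf = cp_4tinf$cp, y = s$cp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_feature_rows() else out
}

#' Extract feature rows at fixed clock times
#'
#' For each grid time the observed sample nearest to it becomes the objective
#' (`target_time` records the observed time actually used); the anchors are
#' likewise the nearest samples to `TINFCAT` and `4 x TINFCAT`. Grid times
#' with no sample inside the matching window are dropped.
#'
#' @param record a [clinical_record()].
#' @param grid fixed extraction times in min.
#' @param window optional fixed matching window (min); default is half the
#'   gap to the adjacent grid time.
#' @return a data frame of feature rows (possibly fewer than `length(grid)`).
#' @export
extract_fixed_times <- function(record, grid = c(5, 15, 30, 50, 100),
                                window = NULL) {
  extract_rows(record, grid, labels = as.character(grid), window = window)
}

#' Extract feature rows at multiples of the infusion duration
#'
#' As [extract_fixed_times()] with grid `multiples * TINFCAT`; rows are
#' labelled `"0.5x"`, `"1.5x"`, ... A multiple of 1 makes the objective
#' coincide with the `cp_tinf` anchor and is flagged with a warning.
#'
#' @param record a [clinical_record()].
#' @param multiples multiples of the infusion duration.
#' @param window optional fixed matching window (min).
#' @return a data frame of feature rows.
#' @export
extract_tinf_multiples <- function(record, multiples = c(0.5, 1.5, 3, 5, 10),
                                   window = NULL) {
  if (any(multiples == 1)) {
    warning("multiple 1 duplicates the cp_tinf anchor as the objective ",
            "(information leakage)", call. = FALSE)
  }
  extract_rows(record, multiples * record$tinfcat,
               labels = paste0(multiples, "x"), window = window)
}

#' Subject-level k-fold cross-validation split
#'
#' Folds are drawn at the subject level (all rows of one subject share a
#' fold) with near-equal sizes, deterministically for a fixed seed.
#'
#' @param ids vector of subject ids (one entry per subject).
#' @param k number of folds (<= number of subjects).
#' @param seed integer seed.
#' @return a list of `k` elements, each `list(train = ids, test = ids)`.
#' @export
kfold_split <- function(ids, k = 5, seed = NULL) {
  ids <- unique(ids)
  n <- length(ids)
  if (k < 2 || k > n) stop_pkmlval("k must be between 2 and the number of subjects")
  with_seed_or_not(seed, {
    shuffled <- sample(ids)
    fold <- rep(seq_len(k), length.out = n)   # sizes differ by at most one
    lapply(seq_len(k), function(f) {
      list(train = shuffled[fold != f], test = shuffled[fold == f])
    })
  })
}

#' Write a feature table to CSV
#'
#' @param rows a feature-row data frame.
#' @param path file path.
#' @export
write_feature_table <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
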