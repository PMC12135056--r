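#' Configuration of a validation experiment
#'
#' Bundles every tunable of the two experiment arms. The defaults reproduce
#' the reference study conditions: 10,000 virtual subjects, a fixed
#' 227 ug/min x 10 min infusion, 10 clusters, a 100-subject test set,
#' training subsets of 1000/500/100/50/10 subjects, target times
#' 5/15/30/50/100 min, and 5-fold subject-level cross-validation for the
#' clinical arm.
#'
#' @param n_population virtual population size.
#' @param rate,tinfcat the shared virtual-arm infusion regimen (ug/min, min).
#' @param k_clusters number of clusters.
#' @param test_size number of test subjects drawn from the test cluster.
#' @param train_sizes requested training-subset sizes (capped at the selected
#'   cluster's size when it is smaller).
#' @param methods learner methods to run (see [ml_spec()]).
#' @param target_times prediction target times (min).
#' @param cluster_anchor_times times (min) of the two concentration features
#'   used for clustering.
#' @param scale_features z-score clustering features? (see
#'   [cluster_population()]).
#' @param test_label fixed test cluster label, or `NULL` for a seeded random
#'   choice.
#' @param extraction clinical-arm extraction scheme, `"fixed_times"` or
#'   `"tinf_multiples"`.
#' @param k_folds folds for the clinical arm.
#' @param seed master seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param model generating [pop_model()].
#' @param cohort a [cohort_spec()] for the synthetic clinical arm.
#' @param grids optional named list of hyperparameter grids overriding
#'   [default_grid()] per method.
#' @param validation_fraction hold-out fraction for tuning.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_population = 10000, rate = 227, tinfcat = 10,
                              k_clusters = 10, test_size = 100,
                              train_sizes = c(1000, 500, 100, 50, 10),
                              methods = c("rf", "gb", "xgb", "average"),
                              target_times = c(5, 15, 30, 50, 100),
                              cluster_anchor_times = c(10, 40),
                              scale_features = FALSE, test_label = NULL,
                              extraction = c("fixed_times", "tinf_multiples"),
                              k_folds = 5, seed = 1,
                              model = remifentanil_ppk_model(),
                              cohort = cohort_spec(), grids = NULL,
                              validation_fraction = 0.2) {
  extraction <- match.arg(extraction)
  methods <- vapply(methods, match.arg, "", choices = ML_METHODS)
  structure(list(n_population = n_population, rate = rate, tinfcat = tinfcat,
                 k_clusters = k_clusters, test_size = test_size,
                 train_sizes = train_sizes, methods = unname(methods),
                 target_times = target_times,
                 cluster_anchor_times = cluster_anchor_times,
                 scale_features = scale_features, test_label = test_label,
                 extraction = extraction, k_folds = k_folds,
                 seed = as.integer(seed), model = model, cohort = cohort,
                 grids = grids, validation_fraction = validation_fraction),
            class = "experiment_config")
}

spec_for <- function(config, method, ...) {
  ml_spec(method, grid = config$grids[[method]] %||% default_grid(method),
          validation_fraction = config$validation_fraction,
          seed = derive_seed(config$seed, "fit", method, ...))
}

log_stage <- function(...) {
  if (isTRUE(getOption("pkmlval.verbose", FALSE))) {
    message(sprintf("[pkmlval] %s", paste0(...)))
  }
}

#' Run the virtual-population experiment arm
#'
#' Executes the full virtual pipeline: sample the population, simulate
#' profiles, cluster, pick test/near/far clusters, build feature rows, and
#' for every (method, cluster, size) cell tune and fit the learner on the
#' training subset and evaluate it on the test subjects.
#'
#' @param config an [experiment_config()].
#' @return a list of class `virtual_experiment` with `results` (row-bound
#'   [evaluate_cell()] tables, one block per cell, plus the per-cell actual
#'   training-subject count `size_actual`), `split` (the [select_splits()]
#'   object), `assignment` (the clustering) and `config`.
#' @export
run_virtual <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  regimen <- dosing_regimen(config$rate, config$tinfcat)
  times <- sort(unique(c(config$target_times, regimen$tinfcat,
                         4 * regimen$tinfcat, config$cluster_anchor_times)))
  log_stage("sampling population n=", config$n_population)
  pop <- sample_population(config$model, config$n_population,
                           seed = derive_seed(config$seed, "population"))
  log_stage("simulating profiles at ", length(times), " time points")
  profiles <- simulate_cohort(pop, regimen, times)
  feats <- build_cluster_features(pop, profiles, config$cluster_anchor_times)
  log_stage("clustering into k=", config$k_clusters)
  assignment <- cluster_population(feats, k = config$k_clusters,
                                   scale = config$scale_features)
  split <- select_splits(assignment, test_label = config$test_label,
                         test_size = config$test_size,
                         sizes = config$train_sizes,
                         seed = derive_seed(config$seed, "split"))
  all_rows <- virtual_feature_table(pop, profiles, regimen,
                                    config$target_times)
  test_rows <- all_rows[all_rows$subject_id %in% as.integer(split$test_ids), ]
  results <- list()
  for (cl in c("near", "far")) {
    for (s in names(split$train[[cl]])) {
      ids <- as.integer(split$train[[cl]][[s]])
      train_rows <- all_rows[all_rows$subject_id %in% ids, ]
      for (method in config$methods) {
        log_stage("fit ", method, " cluster=", cl, " size=", s,
                  " rows=", nrow(train_rows))
        model <- fit_cp_model(spec_for(config, method, cl, s), train_rows)
        cell <- evaluate_cell(predict(model, test_rows), test_rows,
                              method = method, cluster = cl,
                              size = as.integer(s))
        cell$size_actual <- length(ids)
        results[[length(results) + 1]] <- cell
      }
    }
  }
  structure(list(results = do.call(rbind, results), split = split,
                 assignment = assignment, config = config),
            class = "virtual_experiment")
}

#' Run the clinical (real-world-like) experiment arm
#'
#' Extracts feature rows from each clinical record under the configured
#' scheme, splits subjects into k folds, and per (fold, method) fits on the
#' training folds and evaluates on the held-out fold. Fold results are
#' aggregated as mean and SD.
#'
#' @param config an [experiment_config()].
#' @param cohort a list of [clinical_record()] objects, a path to a
#'   NONMEM-style CSV, or `NULL` to synthesize a cohort from
#'   `config$cohort`.
#' @return a list of class `clinical_experiment` with `results` (per-fold
#'   cells), `summary` ([summarize_folds()] output), `folds` and `config`.
#' @export
run_clinical <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    cohort <- synthesize_cohort(config$cohort, model = config$model,
                                seed = derive_seed(config$seed, "cohort"))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  extract <- switch(config$extraction,
                    fixed_times = extract_fixed_times,
                    tinf_multiples = extract_tinf_multiples)
  rows <- do.call(rbind, lapply(cohort, extract))
  ids <- unique(rows$subject_id)
  folds <- kfold_split(ids, k = config$k_folds,
                       seed = derive_seed(config$seed, "folds"))
  results <- list()
  for (f in seq_along(folds)) {
    train_rows <- rows[rows$subject_id %in% folds[[f]]$train, ]
    test_rows <- rows[rows$subject_id %in% folds[[f]]$test, ]
    for (method in config$methods) {
      log_stage("fold ", f, " fit ", method, " rows=", nrow(train_rows))
      model <- fit_cp_model(spec_for(config, method, "cv", f), train_rows)
      results[[length(results) + 1]] <-
        evaluate_cell(predict(model, test_rows), test_rows, method = method,
                      cluster = "cv", fold = f)
    }
  }
  results <- do.call(rbind, results)
  structure(list(results = results, summary = summarize_folds(results),
                 folds = folds, config = config),
            class = "clinical_experiment")
}

#' Pull one overall metric out of a virtual experiment
#'
#' Convenience accessor used by reports: the `"overall"` row of a given
#' (method, cluster, size) cell.
#'
#' @param exp a `virtual_experiment`.
#' @param method,cluster method name and `"near"`/`"far"`.
#' @param size requested training size (`NULL` for all sizes).
#' @param metric column to return (default `"mse"`).
#' @return named numeric vector, one entry per size.
#' @export
overall_metric <- function(exp, method, cluster, size = NULL,
                           metric = "mse") {
  r <- exp$results
  r <- r[r$method == method & r$cluster == cluster &
           r$time_group == "overall", ]
  if (!is.null(size)) r <- r[r$size %in% size, ]
  setNames(r[[metric]], r$size)
}
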