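#' Specification of a concentration-profile learner
#'
#' The panel comprises eight regression methods - lasso, ridge, k-nearest
#' neighbours, support vector machine (RBF), random forest, gradient
#' boosting, extreme gradient boosting and a single-hidden-layer neural
#' network - plus the naive per-time-point `average` baseline. Tunable
#' methods are tuned by grid search on a subject-level 20% validation split
#' scored by log10-scale MSE, then refit on the full training rows with the
#' selected hyperparameters.
#'
#' All learners are fit on `log10(y)` and predictions are back-transformed,
#' which matches the log-scale evaluation metric and guarantees positive
#' predicted concentrations.
#'
#' @param method one of `"lasso"`, `"ridge"`, `"knn"`, `"svm"`, `"rf"`,
#'   `"gb"`, `"xgb"`, `"nn"`, `"average"`.
#' @param grid data frame of candidate hyperparameter combinations (one row
#'   per grid point); `NULL` uses [default_grid()]. Ties in validation score
#'   are broken toward the earlier grid row.
#' @param validation_fraction fraction of training subjects held out for
#'   tuning (strictly between 0 and 1).
#' @param seed integer seed controlling the validation split and any
#'   fit-time randomness.
#' @return an object of class `ml_spec`.
#' @export
ml_spec <- function(method, grid = NULL, validation_fraction = 0.2, seed = 1L) {
  method <- match.arg(method, ML_METHODS)
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_pkmlval("validation_fraction must be strictly between 0 and 1")
  }
  if (is.null(grid)) grid <- default_grid(method)
  if (method != "average" && (is.null(grid) || nrow(grid) == 0)) {
    stop_pkmlval("tunable method '", method, "' needs a non-empty grid")
  }
  structure(list(method = method, grid = grid,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "ml_spec")
}

ML_METHODS <- c("lasso", "ridge", "knn", "svm", "rf", "gb", "xgb", "nn",
                "average")

#' Default hyperparameter grids
#'
#' Compact, literature-standard grids per method: log-spaced regularisation
#' over six decades for the penalised linear models, `k` in 3-11 for kNN, a
#' 3 x 3 log grid in cost/gamma for the RBF SVM, feature-subsampling and node
#' size for the forest, depth/rounds/learning rate for the boosters, and
#' hidden-layer width with weight decay for the network.
#'
#' @param method a method name (see [ml_spec()]).
#' @return a data frame with one row per grid point (`NULL` for `average`).
#' @export
default_grid <- function(method) {
  switch(method,
    lasso = ,
    ridge = data.frame(lambda = 10^seq(-6, 0, length.out = 7)),
    knn = data.frame(k = c(3, 5, 7, 11)),
    svm = expand.grid(cost = c(1, 10, 100), gamma = c(0.01, 0.1, 1)),
    rf = expand.grid(num.trees = 300, mtry = c(2, 4, 7), min.node.size = 1),
    gb = expand.grid(max_depth = c(2, 3), nrounds = c(100, 300), eta = 0.1),
    xgb = expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.3), nrounds = 150),
    nn = expand.grid(size = c(5, 10), decay = c(1e-3, 1e-1)),
    average = NULL)
}

#' Fit a learner on a table of feature rows
#'
#' @param spec an [ml_spec()].
#' @param rows feature rows (as built by [virtual_feature_table()],
#'   [extract_fixed_times()] or [extract_tinf_multiples()]): the columns in
#'   `FEATURE_COLS` plus `subject_id`, `time_group` and the objective `y`.
#' @return an object of class `cp_model` with the chosen hyperparameters, the
#'   tuning score table and an opaque predictor handle.
#' @export
fit_cp_model <- function(spec, rows) {
  stopifnot(inherits(spec, "ml_spec"))
  check_feature_rows(rows, need_y = TRUE)
  if (nrow(rows) < 5) stop_pkmlval("need at least 5 training rows")
  if (any(rows$y <= 0)) stop_pkmlval("objective concentrations must be > 0")
  if (length(unique(rows$y)) == 1) {
    stop_pkmlval("degenerate training set: constant objective")
  }
  ly <- log10(rows$y)
  X <- rows[, FEATURE_COLS, drop = FALSE]

  if (spec$method == "average") {
    fit <- fit_average(rows)
    return(new_cp_model(spec, hyper = NULL, fit = fit, scores = NULL,
                        n = nrow(rows)))
  }

  engine <- learner_engine(spec$method)
  grid <- spec$grid
  scores <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    split <- validation_split(rows$subject_id, spec$validation_fraction,
                              spec$seed)
    if (length(split$val) == 0 || length(split$train) == 0) {
      stop_pkmlval("training set too small for a ", spec$validation_fraction,
                   " validation split")
    }
    tr <- rows$subject_id %in% split$train
    for (g in seq_len(nrow(grid))) {
      m <- engine$fit(X[tr, , drop = FALSE], ly[tr], grid[g, , drop = FALSE],
                      seed = spec$seed)
      pred <- engine$predict(m, X[!tr, , drop = FALSE])
      scores[g] <- mean((pred - ly[!tr])^2)
    }
    best <- which.min(scores)     # first minimum: ties go to earlier grid rows
  } else {
    best <- 1L
  }
  hyper <- grid[best, , drop = FALSE]
  fit <- engine$fit(X, ly, hyper, seed = spec$seed)
  new_cp_model(spec, hyper = hyper, fit = fit,
               scores = cbind(grid, val_mse = scores), n = nrow(rows))
}

new_cp_model <- function(spec, hyper, fit, scores, n) {
  structure(list(method = spec$method, hyper = hyper, fit = fit,
                 tuning = scores, n = n, seed = spec$seed),
            class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("cp_model: %s (fit on %d rows, seed %d)\n", x$method, x$n, x$seed))
  if (!is.null(x$hyper)) {
    cat("  chosen:", paste(names(x$hyper), unlist(x$hyper), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict concentrations for new feature rows
#'
#' @param object a fitted `cp_model`.
#' @param newdata feature rows carrying the seven explanatory variables (and,
#'   for the average baseline, `time_group` when available).
#' @param ... unused.
#' @return numeric vector of positive predicted concentrations (ug/L), one
#'   per row.
#' @export
predict.cp_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(numeric(0))
  if (object$method == "average") {
    return(unname(predict_average(object$fit, newdata)))
  }
  check_feature_rows(newdata, need_y = FALSE)
  engine <- learner_engine(object$method)
  unname(10^engine$predict(object$fit, newdata[, FEATURE_COLS, drop = FALSE]))
}

check_feature_rows <- function(rows, need_y) {
  need <- c(FEATURE_COLS, if (need_y) "y")
  missing <- setdiff(need, names(rows))
  if (length(missing)) {
    stop_pkmlval("feature rows lack columns: ", paste(missing, collapse = ", "))
  }
  bad <- !vapply(rows[need], function(col) all(is.finite(col)), logical(1))
  if (any(bad)) {
    stop_pkmlval("non-finite values in feature columns: ",
                 paste(need[bad], collapse = ", "))
  }
  invisible(rows)
}

# Subject-level validation split: tuning must not see rows of the subjects it
# scores, since rows from one subject share covariates and anchors.
validation_split <- function(subject_ids, fraction, seed) {
  subjects <- unique(subject_ids)
  n_val <- max(1L, round(length(subjects) * fraction))
  if (n_val >= length(subjects)) {
    stop_pkmlval("too few subjects (", length(subjects),
                 ") for a ", fraction, " validation split")
  }
  val <- with_seed_or_not(seed, sample(as.character(subjects), n_val))
  list(train = setdiff(as.character(subjects), val), val = val)
}

## ---- naive average baseline -------------------------------------------

# Arithmetic mean concentration per time group; prediction at an unseen time
# maps to the trained group with the nearest reference time (earlier wins on
# ties).
fit_average <- function(rows) {
  groups <- split(rows, rows$time_group)
  tab <- do.call(rbind, lapply(groups, function(g) {
    data.frame(time_group = g$time_group[1], mean_cp = mean(g$y),
               ref_time = mean(g$target_time))
  }))
  tab[order(tab$ref_time), ]
}

predict_average <- function(tab, newdata) {
  pred <- rep(NA_real_, nrow(newdata))
  if ("time_group" %in% names(newdata)) {
    hit <- match(newdata$time_group, tab$time_group)
    pred <- tab$mean_cp[hit]
  }
  miss <- is.na(pred)
  if (any(miss)) {
    if (!"target_time" %in% names(newdata)) {
      stop_pkmlval("average baseline needs time_group or target_time")
    }
    nearest <- vapply(newdata$target_time[miss], function(tt) {
      gap <- abs(tab$ref_time - tt)
      which(gap == min(gap))[1]            # table is time-ordered: earlier wins
    }, integer(1))
    pred[miss] <- tab$mean_cp[nearest]
  }
  pred
}

#' Persist a fitted model with a sidecar metadata file
#'
#' Saves the predictor to `path` (RDS) and writes `<path>.json` recording the
#' method, chosen hyperparameters, training size and seed, so archived models
#' are identifiable without loading them.
#'
#' @param model a fitted `cp_model`.
#' @param path file path for the model object.
#' @return `load_cp_model` returns the `cp_model`.
#' @export
save_cp_model <- function(model, path) {
  stopifnot(inherits(model, "cp_model"))
  saveRDS(model, path)
  meta <- list(method = model$method,
               hyperparameters = as.list(model$hyper),
               n_training_rows = model$n, seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_cp_model
#' @export
load_cp_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cp_model")) stop_pkmlval("not a saved cp_model: ", path)
  model
}

## ---- method engines ----------------------------------------------------

learner_engine <- function(method) {
  switch(method,
    lasso = glmnet_engine(alpha = 1),
    ridge = glmnet_engine(alpha = 0),
    knn = knn_engine(),
    svm = svm_engine(),
    rf = rf_engine(),
    gb = xgboost_engine(),
    xgb = xgboost_engine(),
    nn = nn_engine(),
    stop_pkmlval("unknown method: ", method))
}

glmnet_engine <- function(alpha) {
  list(
    fit = function(X, ly, hyper, seed) {
      fit <- glmnet::glmnet(as.matrix(X), ly, alpha = alpha,
                            lambda = hyper$lambda)
      list(fit = fit, lambda = hyper$lambda)
    },
    predict = function(m, X) {
      drop(predict(m$fit, as.matrix(X), s = m$lambda))
    })
}

# Shared feature scaler for the distance/gradient-based methods; constant
# columns (rate and infusion duration in the fixed-regimen virtual arm) get
# unit scale so they stay inert instead of producing NaN.
make_scaler <- function(X) {
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, sd, numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  as.data.frame(Map(function(col, c, s) (col - c) / s, X,
                    scaler$center[names(X)], scaler$scale[names(X)]))
}

knn_engine <- function() {
  list(
    fit = function(X, ly, hyper, seed) {
      scaler <- make_scaler(X)
      k <- min(hyper$k, nrow(X) - 1)
      list(fit = caret::knnreg(apply_scaler(scaler, X), ly, k = k),
           scaler = scaler)
    },
    predict = function(m, X) {
      as.numeric(predict(m$fit, apply_scaler(m$scaler, X)))
    })
}

svm_engine <- function() {
  list(
    fit = function(X, ly, hyper, seed) {
      scaler <- make_scaler(X)
      list(fit = e1071::svm(as.matrix(apply_scaler(scaler, X)), ly,
                            type = "eps-regression", kernel = "radial",
                            cost = hyper$cost, gamma = hyper$gamma,
                            scale = FALSE),
           scaler = scaler)
    },
    predict = function(m, X) {
      as.numeric(predict(m$fit, as.matrix(apply_scaler(m$scaler, X))))
    })
}

rf_engine <- function() {
  list(
    fit = function(X, ly, hyper, seed) {
      ranger::ranger(x = X, y = ly, num.trees = hyper$num.trees,
                     mtry = min(hyper$mtry, ncol(X)),
                     min.node.size = hyper$min.node.size,
                     seed = seed, num.threads = 1)
    },
    predict = function(m, X) {
      predict(m, data = X, num.threads = 1)$predictions
    })
}

xgboost_engine <- function() {
  list(
    fit = function(X, ly, hyper, seed) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = ly)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = hyper$max_depth, eta = hyper$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hyper$nrounds, verbose = 0)
    },
    predict = function(m, X) {
      as.numeric(predict(m, xgboost::xgb.DMatrix(as.matrix(X))))
    })
}

nn_engine <- function() {
  list(
    fit = function(X, ly, hyper, seed) {
      scaler <- make_scaler(X)
      y_center <- mean(ly); y_scale <- sd(ly)
      fit <- with_seed_or_not(seed, nnet::nnet(
        as.matrix(apply_scaler(scaler, X)), (ly - y_center) / y_scale,
        size = hyper$size, decay = hyper$decay, linout = TRUE,
        maxit = 500, trace = FALSE))
      list(fit = fit, scaler = scaler, y_center = y_center, y_scale = y_scale)
    },
    predict = function(m, X) {
      raw <- as.numeric(predict(m$fit, as.matrix(apply_scaler(m$scaler, X))))
      raw * m$y_scale + m$y_center
    })
}
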