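# rows with a known smooth relationship used across learner tests
make_rows <- function(n_subj = 40, seed = 3) {
  cohort <- tiny_cohort(n = n_subj, seed = seed)
  virtual_feature_table(cohort$pop, cohort$profiles, cohort$regimen)
}

test_that("average baseline predicts per-time-point training means", {
  rows <- make_rows(10)
  two <- rows[rows$target_time %in% c(5, 15), ]
  fit <- fit_cp_model(ml_spec("average"), two)
  pred <- predict(fit, two)
  means <- tapply(two$y, two$target_time, mean)
  expect_equal(pred[two$target_time == 5], rep(unname(means["5"]), 10))
  expect_equal(pred[two$target_time == 15], rep(unname(means["15"]), 10))
  # an unseen target time maps to the nearest trained time (10 -> 5, 11 -> 15)
  probe <- two[1:2, ]
  probe$time_group <- c("u1", "u2"); probe$target_time <- c(10, 11)
  expect_equal(predict(fit, probe),
               unname(c(means["5"], means["15"])))
  # equidistant probe breaks the tie toward the earlier trained time
  probe$target_time <- c(10, 10)
  expect_equal(predict(fit, probe), rep(unname(means["5"]), 2))
})

test_that("grid search selects the validation-optimal point", {
  rows <- make_rows(30)
  spec <- ml_spec("knn", seed = 5)
  fit <- fit_cp_model(spec, rows)
  expect_equal(which.min(fit$tuning$val_mse),
               which(fit$tuning$k == fit$hyper$k))
  # independent re-scoring: rebuild the same subject-level split and score
  # each k with a directly fitted knn regression
  split <- pkmlval:::validation_split(rows$subject_id, 0.2, 5)
  tr <- rows$subject_id %in% split$train
  scaler <- pkmlval:::make_scaler(rows[tr, pkmlval:::FEATURE_COLS])
  xs_tr <- pkmlval:::apply_scaler(scaler, rows[tr, pkmlval:::FEATURE_COLS])
  xs_va <- pkmlval:::apply_scaler(scaler, rows[!tr, pkmlval:::FEATURE_COLS])
  manual <- vapply(spec$grid$k, function(k) {
    m <- caret::knnreg(xs_tr, log10(rows$y[tr]), k = k)
    mean((predict(m, xs_va) - log10(rows$y[!tr]))^2)
  }, numeric(1))
  expect_equal(fit$tuning$val_mse, manual, tolerance = 1e-10)
})

test_that("a single-point grid makes tuning a no-op", {
  rows <- make_rows(12)
  grid <- data.frame(num.trees = 100, mtry = 4, min.node.size = 1)
  fit <- fit_cp_model(ml_spec("rf", grid = grid, seed = 2), rows)
  expect_equal(fit$hyper, grid, ignore_attr = TRUE)
})

test_that("random forest beats the mean predictor on a learnable signal", {
  set.seed(10)
  n <- 200
  rows <- data.frame(subject_id = rep(1:40, each = 5),
                     time_group = rep(as.character(c(5, 15, 30, 50, 100)), 40),
                     target_time = rep(c(5, 15, 30, 50, 100), 40),
                     rate = 227, age = runif(n, 20, 85),
                     lbm = runif(n, 36, 76), tinfcat = 10,
                     cp_tinf = runif(n, 10, 100), cp_4tinf = runif(n, 1, 10))
  rows$y <- rows$cp_tinf * 2            # exact linear function of one feature
  train <- rows[rows$subject_id <= 30, ]
  test <- rows[rows$subject_id > 30, ]
  fit <- fit_cp_model(ml_spec("rf", seed = 4), train)
  rf_mse <- mse_log(predict(fit, test), test$y)
  mean_mse <- mse_log(rep(mean(train$y), nrow(test)), test$y)
  expect_lt(rf_mse, mean_mse)
})

test_that("every learner yields positive, deterministic predictions", {
  rows <- make_rows(25, seed = 9)
  test <- make_rows(8, seed = 11)
  for (method in c("lasso", "ridge", "knn", "svm", "rf", "gb", "xgb", "nn",
                   "average")) {
    f1 <- fit_cp_model(ml_spec(method, seed = 7), rows)
    f2 <- fit_cp_model(ml_spec(method, seed = 7), rows)
    p1 <- predict(f1, test)
    p2 <- predict(f2, test)
    expect_length(p1, nrow(test))
    expect_true(all(p1 > 0), info = method)
    expect_equal(p1, p2, info = method)
    # identical rows get identical predictions
    rep_rows <- test[c(1, 1), ]
    pr <- predict(f1, rep_rows)
    expect_equal(pr[1], pr[2], info = method)
    # empty input gives an empty prediction vector
    expect_length(predict(f1, test[0, ]), 0)
  }
})

test_that("fitted models round-trip through disk with sidecar metadata", {
  rows <- make_rows(12)
  fit <- fit_cp_model(ml_spec("rf", grid = data.frame(
    num.trees = 100, mtry = 4, min.node.size = 1), seed = 3), rows)
  f <- withr::local_tempfile(fileext = ".rds")
  save_cp_model(fit, f)
  back <- load_cp_model(f)
  expect_equal(predict(back, rows), predict(fit, rows))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$method, "rf")
  expect_equal(meta$hyperparameters$mtry, 4)
  expect_equal(meta$seed, 3)
})

test_that("degenerate training sets are rejected", {
  rows <- make_rows(10)
  expect_error(fit_cp_model(ml_spec("rf"), rows[1:3, ]), "at least 5")
  const <- rows[1:10, ]; const$y <- 2
  expect_error(fit_cp_model(ml_spec("rf"), const), "constant")
  one_subj <- rows[rows$subject_id == 1, ]
  expect_error(fit_cp_model(ml_spec("knn", seed = 1), one_subj), "too few")
  expect_error(predict(fit_cp_model(ml_spec("rf", seed = 1), rows),
                       rows[, c("age", "lbm")]), "lack columns")
  expect_error(ml_spec("rf", validation_fraction = 1), "strictly between")
  expect_error(ml_spec("nope"), "arg")
})
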