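#' Log-scale mean squared error
#'
#' Mean of squared differences of log-transformed concentrations,
#' `MSE = 1/n * sum (log10(pred_i) - log10(obs_i))^2`. The metric is
#' invariant to a common multiplicative rescaling of both vectors (a change
#' of concentration units).
#'
#' @param pred,obs positive concentration vectors of equal length.
#' @param base logarithm base; 10 by default, use `exp(1)` for natural-log
#'   diagnostics.
#' @return a non-negative scalar.
#' @export
mse_log <- function(pred, obs, base = 10) {
  check_metric_inputs(pred, obs)
  mean((log(pred, base) - log(obs, base))^2)
}

#' Log-scale coefficient of determination
#'
#' `R^2 = 1 - SSres/SStot` on log-transformed values, with `SStot` about the
#' mean of `log(obs)`.
#'
#' @inheritParams mse_log
#' @return a scalar `<= 1`.
#' @export
r2_log <- function(pred, obs, base = 10) {
  check_metric_inputs(pred, obs)
  lo <- log(obs, base)
  ss_tot <- sum((lo - mean(lo))^2)
  if (ss_tot == 0) stop_pkmlval("R2 undefined: observations all equal on log scale")
  1 - sum((log(pred, base) - lo)^2) / ss_tot
}

check_metric_inputs <- function(pred, obs) {
  if (length(pred) != length(obs)) stop_pkmlval("pred and obs lengths differ")
  if (length(pred) == 0) stop_pkmlval("empty prediction vector")
  if (any(!is.finite(pred)) || any(!is.finite(obs)) ||
      any(pred <= 0) || any(obs <= 0)) {
    stop_pkmlval("all concentrations must be finite and > 0")
  }
  invisible(NULL)
}

#' Evaluate one (method, split, size) cell
#'
#' Computes the log10-scale MSE and R2 overall (pooled over all rows) and per
#' time group, with natural-log companions for diagnosis. The pooled overall
#' MSE is the mean of squared log residuals over all rows - the count-weighted
#' (not unweighted) mean of the per-group MSEs.
#'
#' @param pred positive predicted concentrations, aligned to `rows`.
#' @param rows the evaluated feature rows (uses `y` and `time_group`).
#' @param method,cluster,size,fold optional cell identity columns copied into
#'   the result.
#' @return a data frame with one row per time group plus an `"overall"` row:
#'   columns `method`, `cluster`, `size`, `fold`, `time_group`, `mse`, `r2`,
#'   `mse_ln`, `r2_ln`, `n`. `r2` is `NA` for groups where it is undefined
#'   (fewer than two distinct observations).
#' @export
evaluate_cell <- function(pred, rows, method = NA_character_,
                          cluster = NA_character_, size = NA_integer_,
                          fold = NA_integer_) {
  if (nrow(rows) == 0) stop_pkmlval("no rows to evaluate")
  if (length(pred) != nrow(rows)) stop_pkmlval("pred length must match rows")
  groups <- c(split(seq_len(nrow(rows)), rows$time_group),
              list(overall = seq_len(nrow(rows))))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    r2 <- tryCatch(r2_log(pred[i], rows$y[i]), error = function(e) NA_real_)
    r2_ln <- tryCatch(r2_log(pred[i], rows$y[i], base = exp(1)),
                      error = function(e) NA_real_)
    data.frame(method = method, cluster = cluster, size = size, fold = fold,
               time_group = g, mse = mse_log(pred[i], rows$y[i]), r2 = r2,
               mse_ln = mse_log(pred[i], rows$y[i], base = exp(1)),
               r2_ln = r2_ln, n = length(i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate cross-validation cells as mean and SD across folds
#'
#' @param results row-bound [evaluate_cell()] output with a `fold` column.
#' @return a data frame keyed by (`method`, `time_group`) with
#'   `mse_mean`, `mse_sd`, `r2_mean`, `r2_sd`, `n_folds` and the pooled row
#'   count `n`.
#' @export
summarize_folds <- function(results) {
  key <- interaction(results$method, results$time_group, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(method = d$method[1], time_group = d$time_group[1],
               mse_mean = mean(d$mse), mse_sd = sd(d$mse),
               r2_mean = mean(d$r2), r2_sd = sd(d$r2),
               n_folds = nrow(d), n = sum(d$n), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write an evaluation results table to CSV
#'
#' @param results a results data frame.
#' @param path file path.
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
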