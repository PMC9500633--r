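#' Coefficient of determination and root mean square error
#'
#' R2 here is the coefficient of determination 1 - SSE/SST (which can be
#' negative for a model worse than predicting the mean), not a squared
#' Pearson correlation.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return List with `r2` and `rmse`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("undefined R-squared: var(y) is zero", call. = FALSE)
  sse <- sum((y - yhat)^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / length(y)))
}

#' Leave-one-out cross-validated Q2
#'
#' Refits the model on every leave-one-out training subset with the
#' hyperparameters held fixed, predicts the held-out sample, and reports
#' Q2 = 1 - PRESS/SST.
#'
#' @param X Design matrix (typically the training partition).
#' @param y Response vector.
#' @param backend Backend name, see [fit_backend()].
#' @param hyperparameters Named list (`n_estimators`, `random_state` or
#'   `n_components`) fixed across the refits.
#' @return Q2_LOO (scalar).
#' @export
q2_loo <- function(X, y, backend, hyperparameters = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out requires n >= 3", call. = FALSE)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(
      do.call(fit_backend,
              c(list(X = X[-i, , drop = FALSE], y = y[-i],
                     backend = backend), hyperparameters)),
      error = function(e) {
        stop("leave-one-out refit failed at sample ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
    pred[i] <- predict(m, X[i, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Y-randomization (response scrambling) robustness check
#'
#' Permutes the responses, re-runs the full fitting procedure — grid search
#' included — on the scrambled data, and records the test-set R2 and the
#' training-set Q2_LOO of the selected model. A model that owes its
#' performance to real structure collapses under scrambling. With
#' `n_iter = 1` the single permutation's values are reported; otherwise the
#' mean across iterations.
#'
#' @param split A `split_dataset` (partition kept fixed; responses are
#'   permuted jointly across train and test positions).
#' @param backend Backend name; for `"pls"` the component count is
#'   re-selected per permutation, for ensembles the grid search is re-run.
#' @param estimator_range,seed_range,objective Grid-search settings, as used
#'   for the unscrambled model (ensemble backends).
#' @param n_iter Number of permutations (>= 1).
#' @param seed Seed for the permutations.
#' @return List with `r2_yrand`, `q2_yrand` (means across iterations), the
#'   per-iteration vectors `r2_iter`, `q2_iter`, and `n_iter`.
#' @export
y_randomization <- function(split, backend = "random_forest",
                            estimator_range = 1:20, seed_range = 1:5,
                            objective = "test_r2",
                            n_iter = 50L, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  y_all <- c(split$y_train, split$y_test)
  if (stats::var(y_all) == 0) {
    stop("undefined metrics: constant response cannot be scrambled",
         call. = FALSE)
  }
  n_tr <- length(split$y_train)
  r2s <- q2s <- numeric(n_iter)
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max, n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(perm_seeds[it])
    yp <- sample(y_all)
    sp <- split
    sp$y_train <- yp[seq_len(n_tr)]
    sp$y_test <- yp[-seq_len(n_tr)]
    model <- if (backend == "pls") {
      fit_pls(sp)$model
    } else {
      grid_search_fit(sp, backend = backend,
                      estimator_range = estimator_range,
                      seed_range = seed_range, objective = objective)$model
    }
    r2s[it] <- regression_metrics(sp$y_test, predict(model, sp$X_test))$r2
    q2s[it] <- q2_loo(sp$X_train, sp$y_train, backend,
                      model$hyperparameters)
  }
  list(r2_yrand = mean(r2s), q2_yrand = mean(q2s),
       r2_iter = r2s, q2_iter = q2s, n_iter = as.integer(n_iter))
}

#' External predictivity coefficients and concordance correlation
#'
#' The three external Q2 variants differ in reference mean and normalization:
#' \deqn{Q^2_{F1} = 1 - \sum_{test}(y-\hat y)^2 / \sum_{test}(y-\bar y_{train})^2}
#' \deqn{Q^2_{F2} = 1 - \sum_{test}(y-\hat y)^2 / \sum_{test}(y-\bar y_{test})^2}
#' \deqn{Q^2_{F3} = 1 - [\sum_{test}(y-\hat y)^2/n_{test}] / [\sum_{train}(y-\bar y_{train})^2/n_{train}]}
#' Lin's concordance correlation coefficient measures agreement of the test
#' predictions with the observations around the identity line:
#' \deqn{CCC = 2\sum(y-\bar y)(\hat y-\bar{\hat y}) / [\sum(y-\bar y)^2 + \sum(\hat y-\bar{\hat y})^2 + n(\bar y-\bar{\hat y})^2]}
#' Q2_F2 is identically the coefficient of determination on the test
#' partition.
#'
#' @param y_train Training responses (reference mean/variance).
#' @param y_test Test responses.
#' @param yhat_test Test predictions.
#' @return List with `qf1`, `qf2`, `qf3`, `ccc`.
#' @export
external_metrics <- function(y_train, y_test, yhat_test) {
  if (length(y_test) < 2L || length(y_train) < 2L) {
    stop("need at least 2 train and 2 test samples", call. = FALSE)
  }
  if (length(y_test) != length(yhat_test)) {
    stop("y_test and yhat_test must have equal length", call. = FALSE)
  }
  sse <- sum((y_test - yhat_test)^2)
  ss_f1 <- sum((y_test - mean(y_train))^2)
  ss_f2 <- sum((y_test - mean(y_test))^2)
  ss_tr <- sum((y_train - mean(y_train))^2)
  if (ss_f1 == 0) stop("undefined metric QF1: zero denominator", call. = FALSE)
  if (ss_f2 == 0) stop("undefined metric QF2: zero denominator", call. = FALSE)
  if (ss_tr == 0) stop("undefined metric QF3: zero denominator", call. = FALSE)
  n_te <- length(y_test)
  dy <- y_test - mean(y_test)
  dp <- yhat_test - mean(yhat_test)
  ccc_den <- sum(dy^2) + sum(dp^2) + n_te * (mean(y_test) - mean(yhat_test))^2
  if (ccc_den == 0) stop("undefined metric CCC: zero denominator", call. = FALSE)
  list(qf1 = 1 - sse / ss_f1,
       qf2 = 1 - sse / ss_f2,
       qf3 = 1 - (sse / n_te) / (ss_tr / length(y_train)),
       ccc = 2 * sum(dy * dp) / ccc_den)
}

#' Acceptance thresholds for a QSAR model
#'
#' The conventional criteria: Q2_LOO > 0.5; R2_yrand < 0.5; Q2_yrand < 0.5;
#' RMSE(test) < 0.2; R2(test) > 0.6; Q2_F1 > 0.5; Q2_F2 > 0.5; Q2_F3 > 0.5;
#' CCC > 0.85. All inequalities are strict.
#'
#' @param report A populated `validation_report` (or any list carrying the
#'   named metrics).
#' @return Named logical vector, one element per criterion plus `overall`
#'   (the conjunction).
#' @export
evaluate_criteria <- function(report) {
  need <- c("q2_loo", "r2_yrand", "q2_yrand", "rmse_test", "r2_test",
            "qf1", "qf2", "qf3", "ccc")
  have <- need %in% names(report) &
    !vapply(report[need], function(v) is.null(v) || is.na(v), TRUE)
  if (!all(have)) {
    stop("incomplete report: missing metric(s) ",
         paste(need[!have], collapse = ", "), call. = FALSE)
  }
  out <- c(q2_loo   = report$q2_loo   > 0.5,
           r2_yrand = report$r2_yrand < 0.5,
           q2_yrand = report$q2_yrand < 0.5,
           rmse     = report$rmse_test < 0.2,
           r2       = report$r2_test  > 0.6,
           qf1      = report$qf1 > 0.5,
           qf2      = report$qf2 > 0.5,
           qf3      = report$qf3 > 0.5,
           ccc      = report$ccc > 0.85)
  c(out, overall = all(out))
}

#' Full internal and external validation battery for a fitted model
#'
#' Computes train/test R2 and RMSE, leave-one-out Q2 on the training
#' partition (hyperparameters fixed at the selected values), optional
#' Y-randomization, the external predictivity coefficients and the
#' concordance correlation coefficient on the test partition, and the
#' criterion verdicts.
#'
#' @param model A fitted `qsar_model`.
#' @param split The `split_dataset` it was fit on (columns may be a superset
#'   of the model's features).
#' @param yrand Settings for [y_randomization()] as a named list
#'   (`n_iter`, `seed`, `estimator_range`, `seed_range`), or NULL to skip
#'   (Y-randomization metrics are then NA and its criteria NA).
#' @return Object of class `validation_report` with all metrics,
#'   `criteria_pass`, and bookkeeping fields (`backend`, `hyperparameters`,
#'   `features`, `n_train`, `n_test`, `yrand_n_iter`).
#' @export
validate_model <- function(model, split, yrand = NULL) {
  Xtr <- split$X_train[, model$features, drop = FALSE]
  Xte <- split$X_test[, model$features, drop = FALSE]
  pr_tr <- predict(model, Xtr)
  pr_te <- predict(model, Xte)
  m_tr <- regression_metrics(split$y_train, pr_tr)
  m_te <- regression_metrics(split$y_test, pr_te)
  q2 <- q2_loo(Xtr, split$y_train, model$backend, model$hyperparameters)
  ext <- external_metrics(split$y_train, split$y_test, pr_te)
  yr <- list(r2_yrand = NA_real_, q2_yrand = NA_real_, n_iter = 0L)
  if (!is.null(yrand)) {
    sub <- split
    sub$X_train <- Xtr; sub$X_test <- Xte; sub$columns <- model$features
    yr <- do.call(y_randomization,
                  c(list(split = sub, backend = model$backend), yrand))
  }
  report <- structure(
    list(backend = model$backend,
         hyperparameters = model$hyperparameters,
         features = model$features,
         n_train = length(split$y_train), n_test = length(split$y_test),
         r2_train = m_tr$r2, rmse_train = m_tr$rmse,
         r2_test = m_te$r2, rmse_test = m_te$rmse,
         q2_loo = q2,
         r2_yrand = yr$r2_yrand, q2_yrand = yr$q2_yrand,
         yrand_n_iter = yr$n_iter,
         qf1 = ext$qf1, qf2 = ext$qf2, qf3 = ext$qf3, ccc = ext$ccc,
         predicted_test = pr_te, predicted_train = pr_tr),
    class = "validation_report")
  report$criteria_pass <- if (is.null(yrand)) NULL else
    evaluate_criteria(report)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (", x$backend, "; ",
      x$n_train, " train / ", x$n_test, " test)\n", sep = "")
  f <- function(v) formatC(v, digits = 2, format = "f")
  cat("  R2(train) ", f(x$r2_train), "  R2(test) ", f(x$r2_test),
      "  RMSE(train) ", f(x$rmse_train), "  RMSE(test) ", f(x$rmse_test),
      "\n  Q2_LOO ", f(x$q2_loo),
      "  R2_yrand ", f(x$r2_yrand), "  Q2_yrand ", f(x$q2_yrand),
      "\n  QF1 ", f(x$qf1), "  QF2 ", f(x$qf2), "  QF3 ", f(x$qf3),
      "  CCC ", f(x$ccc), "\n", sep = "")
  if (!is.null(x$criteria_pass)) {
    cat("  criteria passed: ",
        sum(x$criteria_pass[names(x$criteria_pass) != "overall"]), "/9",
        if (x$criteria_pass[["overall"]]) " (all)" else "", "\n", sep = "")
  }
  invisible(x)
}
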