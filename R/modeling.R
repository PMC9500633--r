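#' Random train/test split at a fixed ratio
#'
#' Uniform random sampling without replacement; with the default 3:1 ratio
#' the test set holds `round(n/4)` samples, so 72 samples split 54/18 and 36
#' samples split 27/9.
#'
#' @param X Design matrix with named columns.
#' @param y Response vector.
#' @param ratio Train:test ratio (default 3, i.e. 3:1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return Object of class `split_dataset`: `X_train`, `y_train`, `X_test`,
#'   `y_test`, `columns`, `idx_train`, `idx_test`, `seed`, `ratio`.
#' @export
split_train_test <- function(X, y, ratio = 3, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("too few samples: need n >= 4 to split", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  n_test <- round(n / (ratio + 1))
  set.seed(as.integer(seed))
  idx_test <- sort(sample.int(n, n_test))
  idx_train <- setdiff(seq_len(n), idx_test)
  structure(list(X_train = X[idx_train, , drop = FALSE],
                 y_train = y[idx_train],
                 X_test = X[idx_test, , drop = FALSE],
                 y_test = y[idx_test],
                 columns = colnames(X),
                 idx_train = idx_train, idx_test = idx_test,
                 seed = as.integer(seed), ratio = ratio),
            class = "split_dataset")
}

#' Two-axis grid search over ensemble size and random state
#'
#' Exhaustively evaluates every (n_estimators, random_state) cell, scoring
#' each fitted model by the selected objective, and refits the best cell.
#' The default objective is the coefficient of determination on the held-out
#' test partition — the selection rule the headline workflow uses, which
#' leaks the test set into model selection; `objective = "cv"` instead scores
#' by k-fold cross-validation inside the training set and touches the test
#' set only after selection. Ties are broken toward the smallest
#' `n_estimators`, then the smallest `random_state`.
#'
#' @param split A `split_dataset`.
#' @param backend `"random_forest"` or `"adaboost"`.
#' @param estimator_range Integer vector of candidate tree counts.
#' @param seed_range Integer vector of candidate random states.
#' @param objective `"test_r2"` (default) or `"cv"` (honest inner
#'   cross-validation).
#' @param cv_folds Folds for `objective = "cv"`.
#' @param cv_seed Seed for the fold assignment.
#' @return List with `model` (the refit best `qsar_model`) and `grid`
#'   (class `grid_search_result`: `best_n_estimators`, `best_random_state`,
#'   `best_objective`, `objective`, `trace` data frame of every cell).
#' @export
grid_search_fit <- function(split, backend = c("random_forest", "adaboost"),
                            estimator_range = 1:100, seed_range = 1:100,
                            objective = c("test_r2", "cv"),
                            cv_folds = 5L, cv_seed = 1L) {
  backend <- match.arg(backend)
  objective <- match.arg(objective)
  if (!length(estimator_range) || !length(seed_range)) {
    stop("estimator_range and seed_range must be non-empty", call. = FALSE)
  }
  if (stats::var(split$y_train) == 0 ||
      (objective == "test_r2" && stats::var(split$y_test) == 0)) {
    stop("undefined R-squared: response has zero variance", call. = FALSE)
  }
  if (objective == "cv") {
    set.seed(as.integer(cv_seed))
    folds <- sample(rep_len(seq_len(cv_folds), length(split$y_train)))
  }
  score_cell <- function(ne, rs) {
    if (objective == "test_r2") {
      m <- fit_backend(split$X_train, split$y_train, backend,
                       n_estimators = ne, random_state = rs)
      regression_metrics(split$y_test, predict(m, split$X_test))$r2
    } else {
      pred <- numeric(length(split$y_train))
      for (f in seq_len(cv_folds)) {
        hold <- folds == f
        m <- fit_backend(split$X_train[!hold, , drop = FALSE],
                         split$y_train[!hold], backend,
                         n_estimators = ne, random_state = rs)
        pred[hold] <- predict(m, split$X_train[hold, , drop = FALSE])
      }
      regression_metrics(split$y_train, pred)$r2
    }
  }
  cells <- expand.grid(random_state = seed_range,
                       n_estimators = estimator_range)
  # ordered so the first maximum is the tie-break winner:
  # smallest n_estimators, then smallest random_state
  cells <- cells[order(cells$n_estimators, cells$random_state), ]
  obj <- mapply(score_cell, cells$n_estimators, cells$random_state)
  best <- which.max(obj)
  trace <- data.frame(n_estimators = cells$n_estimators,
                      random_state = cells$random_state,
                      objective = obj)
  model <- fit_backend(split$X_train, split$y_train, backend,
                       n_estimators = cells$n_estimators[best],
                       random_state = cells$random_state[best])
  grid <- structure(list(best_n_estimators = cells$n_estimators[best],
                         best_random_state = cells$random_state[best],
                         best_objective = obj[best],
                         objective = objective,
                         trace = trace),
                    class = "grid_search_result")
  list(model = model, grid = grid)
}

#' Importance-threshold descriptor selection with refit
#'
#' Keeps the descriptors whose normalized importance weight is strictly
#' greater than `threshold` (default 0.1) and re-runs the hyperparameter grid
#' search on the reduced design. If no descriptor passes, the single most
#' important one is kept and a warning is issued.
#'
#' @param model A fitted ensemble `qsar_model` with importance weights.
#' @param split The `split_dataset` the model was fit on.
#' @param threshold Importance cutoff in (0, 1); strict greater-than. A
#'   threshold of 0 keeps every descriptor with positive importance.
#' @param estimator_range,seed_range,objective,cv_folds,cv_seed Passed to
#'   [grid_search_fit()] for the refit.
#' @return List with `model` (refit on the retained columns), `grid`, and
#'   `retained` (character vector of kept descriptor names).
#' @export
select_features <- function(model, split, threshold = 0.1,
                            estimator_range = 1:100, seed_range = 1:100,
                            objective = c("test_r2", "cv"),
                            cv_folds = 5L, cv_seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(model$importance)) {
    stop("model has no importance weights (PLS models are not selected this way)",
         call. = FALSE)
  }
  keep <- names(model$importance)[model$importance > threshold]
  if (!length(keep)) {
    keep <- names(which.max(model$importance))
    warning("no descriptor importance exceeded the threshold; ",
            "retaining the single most important descriptor: ", keep,
            call. = FALSE)
  }
  sub <- split
  sub$X_train <- split$X_train[, keep, drop = FALSE]
  sub$X_test <- split$X_test[, keep, drop = FALSE]
  sub$columns <- keep
  res <- grid_search_fit(sub, backend = model$backend,
                         estimator_range = estimator_range,
                         seed_range = seed_range, objective = objective,
                         cv_folds = cv_folds, cv_seed = cv_seed)
  list(model = res$model, grid = res$grid, retained = keep, split = sub)
}

#' Fit a PLS regression model, selecting components by leave-one-out Q2
#'
#' When `n_components` is not supplied, every candidate component count up to
#' `min(p, n_train - 2)` is scored by leave-one-out cross-validated Q2 on the
#' training partition and the maximizer is kept (smallest count on ties).
#'
#' @param split A `split_dataset`.
#' @param n_components Fixed component count, or NULL to select by LOO Q2.
#' @return List with `model` (a `qsar_model`), `n_components`, and
#'   `q2_by_ncomp` (named vector, NULL when `n_components` was fixed).
#' @export
fit_pls <- function(split, n_components = NULL) {
  p <- ncol(split$X_train)
  n <- nrow(split$X_train)
  q2 <- NULL
  if (is.null(n_components) && p == 1L) {
    n_components <- 1L
  } else if (is.null(n_components)) {
    ncomp_max <- max(1L, min(p, n - 2L, design_rank(split$X_train)))
    press <- rep(0, ncomp_max)
    for (i in seq_len(n)) {
      f <- mixOmics::pls(split$X_train[-i, , drop = FALSE],
                         split$y_train[-i], ncomp = ncomp_max,
                         mode = "regression")
      pr <- predict(f, split$X_train[i, , drop = FALSE])$predict[1L, 1L, ]
      press <- press + (split$y_train[i] - pr)^2
    }
    tss <- sum((split$y_train - mean(split$y_train))^2)
    q2 <- 1 - press / tss
    names(q2) <- paste0("ncomp", seq_len(ncomp_max))
    n_components <- which.max(q2)
  }
  model <- fit_backend(split$X_train, split$y_train, backend = "pls",
                       n_components = n_components)
  list(model = model, n_components = as.integer(n_components),
       q2_by_ncomp = q2)
}

#' Cross-category prediction
#'
#' Applies a model trained on one category's training set to another
#' category's test set and reports the external performance. When the model's
#' own test partition is supplied this reduces to ordinary evaluation.
#'
#' @param model A fitted `qsar_model`.
#' @param X_test,y_test Test design and responses (any category).
#' @param y_train Training responses of the model (reference mean and
#'   variance for the external predictivity coefficients).
#' @return List: `predicted`, `r2`, `rmse`, and `external`
#'   (`qf1`, `qf2`, `qf3`, `ccc`).
#' @export
cross_cluster_predict <- function(model, X_test, y_test, y_train) {
  X_test <- as.matrix(X_test)
  miss <- setdiff(model$features, colnames(X_test))
  if (length(miss)) {
    stop("test design lacks model feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  yhat <- predict(model, X_test)
  m <- regression_metrics(y_test, yhat)
  ext <- external_metrics(y_train, y_test, yhat)
  list(predicted = yhat, r2 = m$r2, rmse = m$rmse, external = ext)
}

#' Drop near-duplicate descriptors before modeling
#'
#' Among every pair of descriptors with absolute Pearson correlation above
#' `threshold`, keeps the one more strongly correlated (in absolute value)
#' with the response — collinear descriptors typically reflect the same
#' structural factor, and only one is carried into the model.
#'
#' @param X Design matrix with named columns.
#' @param y Response vector.
#' @param threshold Absolute-correlation cutoff (default 0.95).
#' @return Character vector of retained column names.
#' @export
prefilter_correlated <- function(X, y, threshold = 0.95) {
  X <- as.matrix(X)
  keep <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  usable <- sds > 0
  r_y <- rep(0, ncol(X))
  r_y[usable] <- abs(stats::cor(X[, usable, drop = FALSE], y))
  names(r_y) <- colnames(X)
  drop <- character(0)
  cols <- colnames(X)[usable]
  if (length(cols) > 1) {
    cmat <- abs(stats::cor(X[, cols, drop = FALSE]))
    for (i in seq_along(cols)[-length(cols)]) {
      for (j in (i + 1):length(cols)) {
        a <- cols[i]; b <- cols[j]
        if (a %in% drop || b %in% drop) next
        if (cmat[a, b] > threshold) {
          drop <- c(drop, if (r_y[a] >= r_y[b]) b else a)
        }
      }
    }
  }
  setdiff(keep, drop)
}
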