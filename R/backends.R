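#' @importFrom stats predict
NULL

backend_names <- function() c("pls", "random_forest", "adaboost")

# numerical rank of the column-centered design (PLS components cannot exceed it)
design_rank <- function(X) {
  qr(base::scale(as.matrix(X), center = TRUE, scale = FALSE))$rank
}

#' Fit a single QSAR regression backend at fixed hyperparameters
#'
#' Common constructor behind grid search, descriptor selection, LOO
#' cross-validation and Y-randomization. Backends:
#' \describe{
#'   \item{random_forest}{[randomForest::randomForest()] with `n_estimators`
#'     trees; `random_state` seeds the bootstrap draws. Importance is
#'     node-impurity (residual-sum-of-squares) decrease, normalized to sum 1.}
#'   \item{adaboost}{AdaBoost.R2 with squared loss on depth-3 regression-tree
#'     base learners (see [adaboost_r2()]); `random_state` seeds the weighted
#'     resampling. Importance is the estimator-weight-averaged tree
#'     importance, normalized to sum 1.}
#'   \item{pls}{Partial least squares regression ([mixOmics::pls()], scores
#'     on standardized columns) with `n_components` latent components.}
#' }
#'
#' @param X Numeric design matrix with named columns.
#' @param y Response vector.
#' @param backend One of `"pls"`, `"random_forest"`, `"adaboost"`.
#' @param n_estimators Ensemble size (tree count), ensemble backends.
#' @param random_state Integer seed for the backend's internal randomness.
#' @param n_components Latent components, PLS only; defaults to
#'   `min(ncol(X), nrow(X) - 2)`.
#' @return Object of class `qsar_model`: `backend`, `hyperparameters`,
#'   `features` (column names used), `importance` (named, sums to 1 for
#'   ensemble backends, NULL for PLS), `fit`.
#' @export
fit_backend <- function(X, y, backend = backend_names(),
                        n_estimators = 10L, random_state = 1L,
                        n_components = NULL) {
  backend <- match.arg(backend)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  fit <- importance <- NULL
  hyper <- list()
  if (backend == "random_forest") {
    set.seed(as.integer(random_state))
    fit <- randomForest::randomForest(x = X, y = y,
                                      ntree = as.integer(n_estimators))
    imp <- fit$importance[, "IncNodePurity"]
    importance <- if (sum(imp) > 0) imp / sum(imp) else
      stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X))
    hyper <- list(n_estimators = as.integer(n_estimators),
                  random_state = as.integer(random_state))
  } else if (backend == "adaboost") {
    fit <- adaboost_r2(X, y, n_estimators = as.integer(n_estimators),
                       random_state = as.integer(random_state))
    importance <- fit$importance
    hyper <- list(n_estimators = as.integer(n_estimators),
                  random_state = as.integer(random_state))
  } else {
    if (is.null(n_components)) n_components <- min(ncol(X), nrow(X) - 2L)
    rk <- design_rank(X)
    if (n_components > rk) {
      warning("rank-deficient design: reducing PLS components from ",
              n_components, " to ", rk, call. = FALSE)
      n_components <- rk
    }
    n_components <- max(1L, min(as.integer(n_components), ncol(X)))
    if (ncol(X) == 1L) {
      # the one-component PLS solution on a single descriptor coincides with
      # simple least squares; compute it directly
      cf <- stats::coef(stats::lsfit(X[, 1L], y))
      fit <- structure(list(coef = cf), class = "pls_univariate")
    } else {
      fit <- mixOmics::pls(X, y, ncomp = n_components, mode = "regression")
    }
    hyper <- list(n_components = n_components)
  }
  structure(list(backend = backend, hyperparameters = hyper,
                 features = colnames(X), importance = importance,
                 fit = fit),
            class = "qsar_model")
}

#' Predict viability for new samples
#'
#' @param object A `qsar_model`.
#' @param newdata Matrix or data frame containing at least the model's
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- newdata[, object$features, drop = FALSE]
  switch(object$backend,
    random_forest = unname(predict(object$fit, X)),
    adaboost = predict_adaboost_r2(object$fit, X),
    pls = {
      if (inherits(object$fit, "pls_univariate")) {
        unname(object$fit$coef[1L] + object$fit$coef[2L] * X[, 1L])
      } else {
        p <- predict(object$fit, X)$predict
        unname(p[, 1L, object$hyperparameters$n_components])
      }
    })
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("QSAR regression model (", x$backend, ")\n", sep = "")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  hp <- vapply(x$hyperparameters, function(v) format(v), "")
  cat("  hyperparameters:",
      paste(names(hp), hp, sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$importance)) {
    cat("  importance:",
        paste(names(x$importance), round(x$importance, 3),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' AdaBoost.R2 regression with squared loss
#'
#' Boosting for regression by iterative reweighting: each round draws a
#' bootstrap sample of the training set with probabilities given by the
#' current weights, fits a depth-3 regression tree, maps its absolute errors
#' through the squared loss normalized by the largest error, and updates the
#' weights so poorly predicted samples gain influence. Rounds with average
#' loss >= 0.5 terminate the ensemble; a perfect round gets full confidence
#' and also terminates. Prediction is the estimator-weighted median of the
#' per-tree predictions.
#'
#' @param X Design matrix with named columns.
#' @param y Response vector.
#' @param n_estimators Maximum boosting rounds.
#' @param random_state Seed for the weighted resampling.
#' @param maxdepth Base-learner tree depth (default 3).
#' @return Object of class `adaboost_r2`: `trees`, `estimator_weights`,
#'   `importance` (named, sums to 1), `features`.
#' @export
adaboost_r2 <- function(X, y, n_estimators = 50L, random_state = 1L,
                        maxdepth = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  df <- data.frame(y = y, X, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, xval = 0,
                               minsplit = 5L, minbucket = 2L)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  set.seed(as.integer(random_state))
  for (t in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tree <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                         control = ctrl)
    pred <- predict(tree, df)
    err <- abs(y - pred)
    emax <- max(err)
    if (emax == 0) {                       # perfect round: keep, full weight
      trees[[t]] <- tree
      betas[t] <- 1e-10
      break
    }
    loss <- (err / emax)^2                 # squared loss
    ebar <- sum(w * loss)
    if (ebar >= 0.5) {                     # weak learner no better than chance
      if (t == 1L) { trees[[t]] <- tree; betas[t] <- 0.5 }
      break
    }
    beta <- ebar / (1 - ebar)
    trees[[t]] <- tree
    betas[t] <- beta
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  ew <- log(1 / betas)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  for (t in seq_along(trees)) {
    vi <- trees[[t]]$variable.importance
    if (!is.null(vi) && sum(vi) > 0) {
      imp[names(vi)] <- imp[names(vi)] + ew[t] * vi / sum(vi)
    }
  }
  importance <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X))
  structure(list(trees = trees, estimator_weights = ew,
                 importance = importance, features = colnames(X)),
            class = "adaboost_r2")
}

#' Weighted-median prediction for an AdaBoost.R2 ensemble
#' @keywords internal
predict_adaboost_r2 <- function(object, X) {
  X <- as.data.frame(as.matrix(X)[, object$features, drop = FALSE])
  preds <- vapply(object$trees, function(tr) predict(tr, X),
                  numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X))
  ew <- object$estimator_weights
  apply(preds, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(ew[o])
    p[o][which(cw >= 0.5 * sum(ew))[1L]]
  })
}
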