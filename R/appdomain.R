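#' Leverage of query samples with respect to a training design
#'
#' Hat-matrix leverage h_i = x_i (X'X)^-1 x_i' of each query row against the
#' training design, computed on the model's retained descriptor columns
#' exactly as printed — no intercept column and no centering (a centered
#' variant is available via `center = TRUE`, since conventions vary). When
#' X'X is singular the Moore-Penrose pseudo-inverse is used with a warning.
#'
#' @param X_train Training design matrix (named columns).
#' @param X_query Matrix of query rows with the same columns (defaults to the
#'   training design itself).
#' @param center Subtract the training column means from both matrices first.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(X_train, X_query = X_train, center = FALSE) {
  X_train <- as.matrix(X_train)
  X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train) ||
      (!is.null(colnames(X_train)) && !is.null(colnames(X_query)) &&
       !identical(colnames(X_train), colnames(X_query)))) {
    stop("X_query columns must match X_train columns", call. = FALSE)
  }
  if (center) {
    mu <- colMeans(X_train)
    X_train <- sweep(X_train, 2, mu)
    X_query <- sweep(X_query, 2, mu)
  }
  xtx <- crossprod(X_train)
  inv <- tryCatch(solve(xtx), error = function(e) {
    warning("X'X is singular; using the Moore-Penrose pseudo-inverse",
            call. = FALSE)
    MASS::ginv(xtx)
  })
  rowSums((X_query %*% inv) * X_query)
}

#' Critical leverage h* = 3(p + 1)/n
#'
#' @param p Number of (retained) descriptors.
#' @param n Number of training samples.
#' @return The critical leverage value.
#' @examples
#' critical_leverage(4, 54)  # 0.2778
#' critical_leverage(5, 27)  # 0.6667
#' @export
critical_leverage <- function(p, n) {
  if (p < 1 || n < 1) stop("p and n must be >= 1", call. = FALSE)
  3 * (p + 1) / n
}

#' Standardized prediction residuals
#'
#' Residuals divided by a common scale, by convention the training-set RMSE
#' of the fitted model.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @param scale Positive scale (training RMSE).
#' @return Numeric vector (y - yhat)/scale.
#' @export
standardized_residuals <- function(y, yhat, scale) {
  if (length(y) != length(yhat)) {
    stop("y and yhat must have equal length", call. = FALSE)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate fit: residual scale must be > 0", call. = FALSE)
  }
  (y - yhat) / scale
}

#' Williams-plot applicability-domain report
#'
#' Per-sample leverage (against the training X'X on the model's retained
#' descriptors) and standardized residual for both partitions, the critical
#' leverage h* = 3(p + 1)/n_train, and the +/-`residual_limit` residual band.
#' A sample is in the applicability domain iff its leverage does not exceed
#' h* and its standardized residual lies within the band.
#'
#' @param model A fitted `qsar_model`.
#' @param split The `split_dataset` it was fit on.
#' @param residual_limit Standardized-residual critical value (default 2.5).
#' @param center Passed to [leverages()].
#' @return Object of class `ad_report`: `samples` (data frame: `partition`,
#'   `leverage`, `std_residual`, `in_domain`), `h_star`, `residual_limit`,
#'   `p`, `n_train`, `residual_scale`, and `n_outside` (per partition).
#' @export
williams_report <- function(model, split, residual_limit = 2.5,
                            center = FALSE) {
  Xtr <- split$X_train[, model$features, drop = FALSE]
  Xte <- split$X_test[, model$features, drop = FALSE]
  pr_tr <- predict(model, Xtr)
  pr_te <- predict(model, Xte)
  s <- regression_metrics(split$y_train, pr_tr)$rmse
  h <- c(leverages(Xtr, Xtr, center = center),
         leverages(Xtr, Xte, center = center))
  z <- standardized_residuals(c(split$y_train, split$y_test),
                              c(pr_tr, pr_te), s)
  part <- rep(c("train", "test"), c(nrow(Xtr), nrow(Xte)))
  p <- length(model$features)
  h_star <- critical_leverage(p, nrow(Xtr))
  in_dom <- h <= h_star & abs(z) <= residual_limit
  samples <- data.frame(partition = part, leverage = h, std_residual = z,
                        in_domain = in_dom, stringsAsFactors = FALSE)
  structure(list(samples = samples, h_star = h_star,
                 residual_limit = residual_limit,
                 p = p, n_train = nrow(Xtr), residual_scale = s,
                 n_outside = c(train = sum(!in_dom[part == "train"]),
                               test = sum(!in_dom[part == "test"]))),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat("Applicability domain (Williams) report\n")
  cat("  p = ", x$p, ", n_train = ", x$n_train,
      ", h* = ", formatC(x$h_star, digits = 4, format = "f"),
      ", residual limit = ±", x$residual_limit, "\n", sep = "")
  cat("  outside domain: train ", x$n_outside[["train"]],
      ", test ", x$n_outside[["test"]], "\n", sep = "")
  invisible(x)
}
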