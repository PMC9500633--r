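test_that("3:1 random split gives the expected partition sizes", {
  X <- matrix(rnorm(72 * 8), 72, 8, dimnames = list(NULL, descriptor_names()))
  y <- rnorm(72)
  sp <- split_train_test(X, y, seed = 1)
  expect_equal(length(sp$y_train), 54L)
  expect_equal(length(sp$y_test), 18L)
  sp36 <- split_train_test(X[1:36, ], y[1:36], seed = 1)
  expect_equal(length(sp36$y_train), 27L)
  expect_equal(length(sp36$y_test), 9L)
  # disjoint, exhaustive, reproducible
  expect_length(intersect(sp$idx_train, sp$idx_test), 0)
  expect_equal(sort(c(sp$idx_train, sp$idx_test)), 1:72)
  sp2 <- split_train_test(X, y, seed = 1)
  expect_identical(sp$idx_test, sp2$idx_test)
  sp3 <- split_train_test(X, y, seed = 2)
  expect_false(identical(sp$idx_test, sp3$idx_test))
  expect_error(split_train_test(X[1:3, ], y[1:3]), "too few")
})

test_that("grid search matches a brute-force loop over all cells", {
  sp <- linear_split(n = 24, noise = 0.5)
  est <- c(2, 5, 9); rs <- c(1, 3)
  res <- grid_search_fit(sp, "random_forest", est, rs)
  # independent brute force over the same grid
  best <- -Inf; best_cell <- NULL
  for (ne in est) for (r in rs) {
    m <- fit_backend(sp$X_train, sp$y_train, "random_forest",
                     n_estimators = ne, random_state = r)
    r2 <- regression_metrics(sp$y_test, predict(m, sp$X_test))$r2
    if (r2 > best) { best <- r2; best_cell <- c(ne, r) }
  }
  expect_equal(res$grid$best_objective, best, tolerance = 1e-12)
  expect_equal(c(res$grid$best_n_estimators, res$grid$best_random_state),
               best_cell)
  expect_equal(nrow(res$grid$trace), length(est) * length(rs))
  # 1x1 grid is that cell
  one <- grid_search_fit(sp, "random_forest", 5, 3)
  expect_equal(one$grid$best_n_estimators, 5)
  expect_equal(one$grid$best_random_state, 3)
  # deterministic
  res2 <- grid_search_fit(sp, "random_forest", est, rs)
  expect_identical(res$grid$trace, res2$grid$trace)
})

test_that("ensemble importance weights are normalized and drive selection", {
  sp <- linear_split(n = 30, p = 5, noise = 0.1, beta = c(5, 3, 1, 0, 0))
  for (b in c("random_forest", "adaboost")) {
    m <- fit_backend(sp$X_train, sp$y_train, b, n_estimators = 20,
                     random_state = 1)
    expect_equal(sum(m$importance), 1, tolerance = 1e-9)
    expect_true(all(m$importance >= 0))
  }
  m <- fit_backend(sp$X_train, sp$y_train, "random_forest",
                   n_estimators = 30, random_state = 1)
  # threshold 0 keeps everything with positive importance
  sel0 <- select_features(m, sp, threshold = 0,
                          estimator_range = 1:5, seed_range = 1)
  expect_setequal(sel0$retained,
                  names(m$importance)[m$importance > 0])
  # a crafted importance profile: 4 weights above 0.1 are retained
  m2 <- m
  m2$importance <- c(d1 = 0.49, d2 = 0.25, d3 = 0.14, d4 = 0.11, d5 = 0.01)
  names(m2$importance) <- colnames(sp$X_train)
  sel <- select_features(m2, sp, threshold = 0.1,
                         estimator_range = 1:5, seed_range = 1)
  expect_equal(length(sel$retained), 4L)
  expect_identical(sel$model$features, sel$retained)
  # fallback: nothing passes -> single best descriptor, with a warning
  m3 <- m
  m3$importance[] <- 1 / 5
  expect_warning(
    sel1 <- select_features(m3, sp, threshold = 0.5,
                            estimator_range = 1:5, seed_range = 1),
    "single most important")
  expect_equal(length(sel1$retained), 1L)
})

test_that("PLS recovers an exact linear signal and reduces to least squares", {
  sp <- linear_split(n = 24, p = 3, noise = 0)
  fit <- fit_pls(sp)
  v <- regression_metrics(sp$y_test, predict(fit$model, sp$X_test))
  expect_equal(v$r2, 1, tolerance = 1e-9)
  # one component on one column = simple least squares
  sp1 <- linear_split(n = 20, p = 1, noise = 0.3)
  fit1 <- fit_pls(sp1, n_components = 1)
  ols <- lm(y ~ x, data.frame(y = sp1$y_train, x = sp1$X_train[, 1]))
  pred_ols <- predict(ols, data.frame(x = sp1$X_test[, 1]))
  expect_equal(predict(fit1$model, sp1$X_test), unname(pred_ols),
               tolerance = 1e-9)
  # permuted responses break the association
  set.seed(99)
  spp <- sp
  spp$y_train <- sample(sp$y_train)
  fitp <- fit_pls(spp, n_components = 3)
  expect_lt(regression_metrics(sp$y_test, predict(fitp$model, sp$X_test))$r2,
            0.3)
})

test_that("rank-deficient designs reduce the PLS component count with a warning", {
  sp <- linear_split(n = 20, p = 3, noise = 0.1)
  # append an exact linear combination of the first two columns
  add <- function(X) cbind(X, d4 = X[, 1] + X[, 2])
  sp$X_train <- add(sp$X_train); sp$X_test <- add(sp$X_test)
  expect_warning(f <- fit_backend(sp$X_train, sp$y_train, "pls",
                                  n_components = 4),
                 "rank-deficient")
  expect_equal(f$hyperparameters$n_components, 3L)
})

test_that("cross-category prediction reduces to ordinary evaluation on its own test set", {
  sp <- linear_split(n = 24, noise = 0.2)
  m <- fit_backend(sp$X_train, sp$y_train, "random_forest",
                   n_estimators = 20, random_state = 1)
  cp <- cross_cluster_predict(m, sp$X_test, sp$y_test, sp$y_train)
  direct <- regression_metrics(sp$y_test, predict(m, sp$X_test))
  expect_equal(cp$r2, direct$r2)
  expect_equal(cp$rmse, direct$rmse)
  expect_equal(cp$external$qf2, direct$r2, tolerance = 1e-12)
  bad <- sp$X_test; colnames(bad) <- paste0("z", 1:3)
  expect_error(cross_cluster_predict(m, bad, sp$y_test, sp$y_train),
               "lacks model feature")
})

test_that("AdaBoost.R2 fits, predicts by weighted median, and terminates on perfect fits", {
  sp <- linear_split(n = 60, noise = 0.2)
  m <- fit_backend(sp$X_train, sp$y_train, "adaboost",
                   n_estimators = 30, random_state = 2)
  pr <- predict(m, sp$X_test)
  expect_true(all(is.finite(pr)))
  expect_gt(regression_metrics(sp$y_test, pr)$r2, 0.4)
  # deterministic given random_state
  m2 <- fit_backend(sp$X_train, sp$y_train, "adaboost",
                    n_estimators = 30, random_state = 2)
  expect_equal(pr, predict(m2, sp$X_test))
  # constant response: first tree is perfect, ensemble stops early
  mc <- adaboost_r2(sp$X_train, rep(1, nrow(sp$X_train)), n_estimators = 10)
  expect_equal(length(mc$trees), 1L)
})

test_that("correlated-descriptor prefilter keeps the better-correlated twin", {
  set.seed(13)
  n <- 40
  x1 <- rnorm(n)
  X <- cbind(a = x1, b = x1 + rnorm(n, 0, 0.01), c = rnorm(n))
  y <- 2 * x1 + rnorm(n, 0, 0.1)
  kept <- prefilter_correlated(X, y, threshold = 0.95)
  expect_true("c" %in% kept)
  expect_equal(length(kept), 2L)
  expect_true(abs(cor(X[, kept[1]], y)) >= abs(cor(X[, setdiff(c("a", "b"), kept)], y)))
})
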