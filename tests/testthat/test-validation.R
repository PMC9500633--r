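test_that("coefficient of determination and RMSE match hand arithmetic", {
  y <- c(0, 1, 2); yhat <- c(0, 0, 2)
  m <- regression_metrics(y, yhat)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  expect_equal(regression_metrics(y, y), list(r2 = 1, rmse = 0))
  expect_equal(regression_metrics(y, rep(mean(y), 3))$r2, 0)
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "zero")
  expect_error(regression_metrics(1, 1), "length")
})

test_that("leave-one-out Q2 matches the closed-form hat-matrix shortcut for least squares", {
  # linear signal, PLS with full components = ordinary least squares
  set.seed(3)
  n <- 12
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "d1"))
  y <- 2 + 3 * X[, 1] + rnorm(n, 0, 0.4)
  q2 <- q2_loo(X, y, "pls", list(n_components = 1))
  # oracle: PRESS from the hat matrix of the intercept+slope fit
  H <- {
    Xi <- cbind(1, X)
    Xi %*% solve(crossprod(Xi)) %*% t(Xi)
  }
  e <- y - H %*% y
  press <- sum((e / (1 - diag(H)))^2)
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-9)

  # exact linear response gives Q2 = 1
  sp <- linear_split(n = 15, p = 2, noise = 0)
  expect_equal(q2_loo(sp$X_train, sp$y_train, "pls",
                      list(n_components = 2)), 1, tolerance = 1e-9)
})

test_that("leave-one-out Q2 is non-positive in expectation for pure noise", {
  set.seed(17)
  q2s <- replicate(5, {
    X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("d", 1:3)))
    q2_loo(X, rnorm(10), "pls", list(n_components = 2))
  })
  expect_lt(mean(q2s), 0)
})

test_that("external predictivity coefficients match hand-computed toy values", {
  # perfect predictions
  ext <- external_metrics(c(0, 1, 2), c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(unlist(ext), c(qf1 = 1, qf2 = 1, qf3 = 1, ccc = 1))
  # hand arithmetic: SSE = 0.5, test SS = 0.5, train mean = test mean = 0.5
  ext2 <- external_metrics(c(0, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(ext2$qf2, 0, tolerance = 1e-12)
  expect_equal(ext2$qf1, 0, tolerance = 1e-12)   # identical reference means
  expect_equal(ext2$qf3, 0, tolerance = 1e-12)
  expect_equal(ext2$ccc, 0, tolerance = 1e-12)   # constant predictions
  # another hand case: y_tr = (0,2), y_te = (1,3), yhat = (1,2)
  # SSE = 1; QF1: sum (y_te - 1)^2 = 4 -> 0.75; QF2: sum (y_te - 2)^2 = 2 -> 0.5
  # QF3: (1/2) / (2/2) = 0.5 -> 0.5
  ext3 <- external_metrics(c(0, 2), c(1, 3), c(1, 2))
  expect_equal(ext3$qf1, 0.75, tolerance = 1e-12)
  expect_equal(ext3$qf2, 0.5, tolerance = 1e-12)
  expect_equal(ext3$qf3, 0.5, tolerance = 1e-12)
  # CCC by its formula: dy = (-1,1), dp = (-0.5,0.5), means 2 and 1.5
  expect_equal(ext3$ccc, 2 * 1 / (2 + 0.5 + 2 * 0.25), tolerance = 1e-12)
  expect_error(external_metrics(c(1, 1), c(0, 1), c(0, 1)), "QF3")
  expect_error(external_metrics(c(0, 1), c(1, 1), c(0, 1)), "QF2")
})

test_that("QF2 is identically the test-partition R2 and QF1 >= QF2 always", {
  set.seed(23)
  for (i in 1:100) {
    n_tr <- sample(5:30, 1); n_te <- sample(3:15, 1)
    y_tr <- rnorm(n_tr); y_te <- rnorm(n_te); yh <- rnorm(n_te)
    ext <- external_metrics(y_tr, y_te, yh)
    expect_equal(ext$qf2, regression_metrics(y_te, yh)$r2, tolerance = 1e-12)
    expect_gte(ext$qf1, ext$qf2 - 1e-12)
  }
})

test_that("CCC never exceeds the absolute Pearson correlation", {
  set.seed(29)
  for (i in 1:30) {
    y <- rnorm(10); yh <- rnorm(10, y, 0.5)
    ccc <- external_metrics(rnorm(5), y, yh)$ccc
    expect_lte(abs(ccc), abs(cor(y, yh)) + 1e-12)
  }
})

test_that("metrics are invariant to a common permutation of the samples", {
  set.seed(37)
  y_tr <- rnorm(10); y_te <- rnorm(8); yh <- rnorm(8)
  o <- sample(8)
  expect_equal(external_metrics(y_tr, y_te, yh),
               external_metrics(y_tr, y_te[o], yh[o]))
  expect_equal(regression_metrics(y_te, yh),
               regression_metrics(y_te[o], yh[o]))
})

test_that("Y-randomization is reproducible and rejects a constant response", {
  sp <- linear_split(n = 16, p = 2, noise = 0.3)
  a <- y_randomization(sp, "pls", n_iter = 1, seed = 5)
  b <- y_randomization(sp, "pls", n_iter = 1, seed = 5)
  expect_identical(a, b)
  spc <- sp; spc$y_train[] <- 1; spc$y_test[] <- 1
  expect_error(y_randomization(spc, "pls", n_iter = 1), "constant")
})

test_that("criterion verdicts apply the thresholds with strict inequalities", {
  good <- list(q2_loo = 0.9, r2_yrand = -0.3, q2_yrand = -0.4,
               rmse_test = 0.05, r2_test = 0.95,
               qf1 = 0.9, qf2 = 0.9, qf3 = 0.9, ccc = 0.95)
  expect_true(all(evaluate_criteria(good)))
  # a weak external QF3 fails its criterion alone
  weak <- good; weak$qf3 <- 0.37
  crit <- evaluate_criteria(weak)
  expect_false(crit[["qf3"]])
  expect_false(crit[["overall"]])
  expect_true(all(crit[setdiff(names(crit), c("qf3", "overall"))]))
  # boundary values fail (strict inequality)
  edge <- good; edge$r2_test <- 0.6
  expect_false(evaluate_criteria(edge)[["r2"]])
  incomplete <- good; incomplete$ccc <- NULL
  expect_error(evaluate_criteria(incomplete), "incomplete")
})

test_that("validate_model assembles a coherent report on strong synthetic signal", {
  sim <- simulate_mixture_study(synthetic_config(seed = 42))
  dt <- build_design_table(sim$mixed)
  sp <- split_train_test(dt$X, dt$y, seed = 4)
  gs <- grid_search_fit(sp, "random_forest", small_grid$estimator_range,
                        small_grid$seed_range)
  rep <- validate_model(gs$model, sp,
                        yrand = list(n_iter = 2, seed = 1,
                                     estimator_range = 1:5, seed_range = 1:2))
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$qf2, rep$r2_test, tolerance = 1e-12)
  expect_equal(rep$n_train, 54L)
  expect_gt(rep$r2_test, 0.5)
  expect_lt(rep$r2_yrand, rep$r2_test)
  expect_named(rep$criteria_pass,
               c("q2_loo", "r2_yrand", "q2_yrand", "rmse", "r2",
                 "qf1", "qf2", "qf3", "ccc", "overall"))
})
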