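test_that("PLSR recovers an exact linear response at full rank", {
  set.seed(21)
  X <- matrix(rnorm(40 * 8), 40, 8)
  beta <- rnorm(8)
  y <- as.numeric(X %*% beta + 2)
  fit <- fit_plsr(X, y, n_lv = 8)
  rep <- model_report(y, predict(fit, X), subset = "calibration", lv = 8)
  expect_equal(rep$r2, 1)
  expect_lt(rep$rmse, 1e-10)
})

test_that("first weight vector is proportional to X'y (closed-form oracle)", {
  set.seed(22)
  # orthonormal centered X via QR
  M <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  M <- sweep(M, 2, colMeans(M))
  y <- rnorm(30)
  fit <- fit_plsr(M, y, n_lv = 1)
  w_oracle <- crossprod(M, y - mean(y))[, 1]
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(sum(fit$W[, 1] * w_oracle)), 1, tolerance = 1e-10)
})

test_that("coefficients concentrate on informative bands amid pure noise", {
  set.seed(23)
  n <- 120
  X <- matrix(rnorm(n * 202), n, 202)
  info <- c(50, 150)
  y <- as.numeric(X[, info] %*% c(2, -2) + rnorm(n, sd = 0.3))
  ic <- 1:80
  fit <- fit_plsr(X[ic, ], y[ic], n_lv = 5)
  # brute-force rank of |coef|
  top2 <- order(abs(fit$coef), decreasing = TRUE)[1:2]
  expect_setequal(top2, info)
  r2_val <- cor(y[-ic], predict(fit, X[-ic, ]))^2
  # noise-only baseline: permuted response
  set.seed(24)
  fitp <- fit_plsr(X[ic, ], sample(y[ic]), n_lv = 5)
  r2_null <- cor(y[-ic], predict(fitp, X[-ic, ]))^2
  expect_gt(r2_val, r2_null)
})

test_that("full-LV PLSR equals ordinary least squares predictions", {
  set.seed(25)
  for (i in 1:50) {
    n <- sample(20:40, 1); p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_plsr(X, y, n_lv = p)
    ols <- qr.fitted(qr(cbind(1, X)), y)
    pls <- predict(fit, X)
    expect_lt(max(abs(pls - ols)) / max(abs(ols)), 1e-6)
  }
})

test_that("scores are orthogonal and both prediction forms agree", {
  set.seed(26)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- as.numeric(X %*% rnorm(30) + rnorm(50))
  fit <- fit_plsr(X, y, n_lv = 10)
  G <- crossprod(fit$Tm)
  nrm <- sqrt(diag(G))
  off <- abs(G - diag(diag(G))) / tcrossprod(nrm)
  expect_lt(max(off), 1e-8)
  Xnew <- matrix(rnorm(20 * 30), 20, 30)
  expect_equal(predict(fit, Xnew, form = "coef"),
               predict(fit, Xnew, form = "components"), tolerance = 1e-8)
  # centering identity: the x_mean row predicts y_mean
  expect_equal(predict(fit, fit$x_mean), fit$y_mean)
})

test_that("requesting more LVs than the rank truncates with a recorded warning", {
  set.seed(27)
  X <- matrix(rnorm(10 * 50), 10, 50)
  y <- rnorm(10)
  fit <- fit_plsr(X, y, n_lv = 30)
  expect_lte(fit$n_lv, 9)
  expect_true(any(grepl("truncated", fit$warnings)))
  expect_error(fit_plsr(X, rep(1, 10), n_lv = 2), "zero-variance")
  expect_error(predict(fit, matrix(0, 2, 7)), "band mismatch")
})

test_that("VIP has unit mean square and flags informative bands", {
  set.seed(28)
  # single band: normalization forces VIP = 1
  x1 <- matrix(rnorm(20), 20, 1)
  f1 <- fit_plsr(x1, as.numeric(x1 * 2 + rnorm(20, sd = 0.1)), n_lv = 1)
  expect_equal(vip(f1), 1)

  for (i in 1:5) {
    n <- 60; p <- sample(10:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- as.numeric(X %*% rnorm(p) + rnorm(n))
    f <- fit_plsr(X, y, n_lv = min(6, p))
    expect_equal(mean(vip(f)^2), 1, tolerance = 1e-8)
  }

  # 2 informative + 50 noise bands: informative bands take the top-2 VIPs,
  # cross-checked against brute-force univariate correlations
  n <- 150
  X <- matrix(rnorm(n * 52), n, 52)
  y <- as.numeric(X[, c(7, 31)] %*% c(1.5, -1.5) + rnorm(n, sd = 0.2))
  f <- fit_plsr(X, y, n_lv = 4)
  v <- vip(f)
  expect_setequal(order(v, decreasing = TRUE)[1:2], c(7, 31))
  cors <- abs(cor(X, y))
  expect_setequal(order(cors, decreasing = TRUE)[1:2], c(7, 31))
})

test_that("report statistics match closed-form least squares", {
  # identity
  y <- c(1, 2, 3, 4)
  r <- model_report(y, y)
  expect_equal(unlist(r[c("r2", "rmse", "intercept", "slope", "bias")]),
               c(r2 = 1, rmse = 0, intercept = 0, slope = 1, bias = 0))
  # constant shift: y_pred = y_obs + 2
  r2 <- model_report(y, y + 2)
  expect_equal(r2$r2, 1)
  expect_equal(r2$rmse, 2)
  expect_equal(r2$bias, 2)
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, -2)

  # hand-computed OLS of y_obs on y_pred
  y_obs <- c(1, 2, 3, 4); y_pred <- c(1.1, 1.9, 3.2, 3.8)
  mx <- mean(y_pred); my <- mean(y_obs)
  sxy <- sum((y_pred - mx) * (y_obs - my)); sxx <- sum((y_pred - mx)^2)
  b <- sxy / sxx; a <- my - b * mx
  r3 <- model_report(y_obs, y_pred)
  expect_equal(r3$slope, b)
  expect_equal(r3$intercept, a)
  expect_equal(r3$r2, cor(y_obs, y_pred)^2)
  expect_equal(r3$rmse, sqrt(mean((y_obs - y_pred)^2)))
  expect_equal(r3$bias, mean(y_pred - y_obs))
  expect_equal(r3$min, 1); expect_equal(r3$max, 4)

  # degenerate: constant predictions give missing R2, not an error
  expect_true(is.na(model_report(y, rep(2, 4))$r2))
})

test_that("coefficient form agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(29)
  X <- matrix(rnorm(40 * 15), 40, 15,
              dimnames = list(NULL, paste0("b", 1:15)))
  y <- as.numeric(X %*% rnorm(15) + rnorm(40))
  ours <- fit_plsr(X, y, n_lv = 5)
  ref <- mixOmics::pls(X, y, ncomp = 5, mode = "regression", scale = FALSE)
  pref <- predict(ref, X)$predict[, 1, 5]
  expect_equal(unname(predict(ours, X)), unname(pref), tolerance = 1e-6)
})
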