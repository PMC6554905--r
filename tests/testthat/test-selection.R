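test_that("the 2/3 plant-level split has the documented sizes and determinism", {
  ids <- paste0("p", 1:192)
  sp <- split_calibration_validation(ids, seed = 5)
  expect_length(sp$calibration, 128)
  expect_length(sp$validation, 64)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), ids)
  expect_identical(sp, split_calibration_validation(ids, seed = 5))
  # replicated ids stay together
  sp2 <- split_calibration_validation(rep(ids, each = 3), seed = 5)
  expect_identical(sp2, sp)
  # near-degenerate fraction still leaves a validation plant
  sp3 <- split_calibration_validation(paste0("q", 1:3), frac = 1 - 1e-9)
  expect_gte(length(sp3$validation), 1)
  expect_error(split_calibration_validation(ids, frac = 1.2), "frac")
})

test_that("the CV curve bottoms out at the planted rank on noise-free data", {
  set.seed(31)
  n <- 60; p <- 30; r <- 4
  X <- matrix(rnorm(n * r), n, r) %*% matrix(rnorm(r * p), r, p)
  y <- as.numeric(X %*% rnorm(p))
  curve <- mc_cv_curve(X, y, lv_max = 10, folds = 10, reps = 5, seed = 1)
  expect_lt(curve$press[r] / curve$press[1], 1e-10)
  expect_error(mc_cv_curve(X[1:5, ], y[1:5], folds = 10), "exceeds samples")
})

test_that("pure-noise responses give non-decreasing CV error beyond LV 1", {
  # Monte-Carlo oracle: with y independent of X, extra components can only
  # overfit; averaged over seeds the press curve must trend upward
  set.seed(32)
  n <- 50; p <- 20
  curves <- sapply(1:25, function(s) {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    mc_cv_curve(X, y, lv_max = 8, folds = 5, reps = 2, seed = s)$press
  })
  avg <- rowMeans(curves)
  expect_gt(avg[8], avg[1])
  expect_true(mean(diff(avg) > 0) >= 0.7)
})

test_that("more Monte Carlo replicates shrink the curve's standard error", {
  set.seed(33)
  n <- 60; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n))
  c1 <- mc_cv_curve(X, y, lv_max = 5, folds = 5, reps = 4, seed = 2)
  c2 <- mc_cv_curve(X, y, lv_max = 5, folds = 5, reps = 40, seed = 2)
  expect_equal(mean(c1$press), mean(c2$press), tolerance = 0.2)
  expect_lt(mean(c2$press_se), mean(c1$press_se))
})

test_that("Adjusted Wold walks the curve as specified", {
  expect_identical(adjusted_wold(c(10, 4, 4.2, 4.1), threshold = 1), 2L)
  expect_identical(adjusted_wold(c(10, 9.95, 9.9, 9.85), threshold = 0.99), 1L)
  geo <- 10 * 0.5^(1:12)
  expect_identical(adjusted_wold(geo, threshold = 1), 12L)
  expect_error(adjusted_wold(5), "at least 2")
})

test_that("AW at threshold 0.99 never selects more LVs than at 1.0", {
  set.seed(34)
  for (i in 1:100) {
    press <- cumprod(runif(12, 0.7, 1.15)) * 10
    expect_lte(adjusted_wold(press, 0.99), adjusted_wold(press, 1.0))
  }
})

test_that("CARS retention schedule is exact and degenerates gracefully", {
  set.seed(35)
  n <- 40; p <- 25
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n, sd = 0.2))
  # n_runs = 1: the schedule starts at 1, so everything is retained
  s1 <- cars_select(X, y, n_runs = 1, seed = 1)
  expect_identical(s1$selected, 1:p)
  # schedule endpoints r_1 = 1 and r_n = 2/p to 1e-12
  s2 <- cars_select(X, y, n_runs = 20, seed = 1)
  expect_equal(s2$schedule[1], 1, tolerance = 1e-12)
  expect_equal(s2$schedule[20], 2 / p, tolerance = 1e-12)
  # strictly decreasing after run 1
  expect_true(all(diff(s2$schedule) < 0))
  # determinism per seed
  s3 <- cars_select(X, y, n_runs = 20, seed = 1)
  expect_identical(s2$selected, s3$selected)
  expect_true(all(diff(s2$selected) > 0))
  expect_error(cars_select(X[, 1, drop = FALSE], y), "at least 2 bands")
})

test_that("CARS recovers planted informative bands (spot check)", {
  hits <- vapply(1:5, function(s) {
    set.seed(4000 + s)
    n <- 150
    X <- matrix(rnorm(n * 103), n, 103)
    info <- c(10, 50, 90)
    y <- as.numeric(X[, info] %*% c(1, -1, 0.8) + rnorm(n, sd = 0.1))
    sub <- cars_select(X, y, seed = s)
    all(info %in% sub$selected)
  }, TRUE)
  expect_gte(sum(hits), 4)
})

test_that("VIP selection thresholds behave at the boundaries", {
  set.seed(36)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- as.numeric(X[, c(3, 17)] %*% c(1, -1) + rnorm(100, sd = 0.2))
  fit <- fit_plsr(X, y, n_lv = 4)
  expect_identical(vip_select(fit, threshold = 0)$selected, 1:30)
  expect_error(vip_select(fit, threshold = max(vip(fit)) + 0.01), "max VIP")
  sel <- vip_select(fit, 1.0)$selected
  expect_true(all(c(3, 17) %in% sel))
  # range reporting groups contiguous bands
  rng <- band_ranges_nm(vip_select(fit, 1.0), seq(550, 1700, length.out = 30))
  expect_true(all(rng$lo_nm <= rng$hi_nm))
  expect_identical(sum(rng$n_bands), length(sel))
})

test_that("band selection does not catastrophically hurt prediction", {
  set.seed(37)
  n <- 120; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  # planted informative bands among noise
  beta <- numeric(p); beta[c(12, 30, 48)] <- c(1.2, -1, 0.9)
  y <- as.numeric(X %*% beta + rnorm(n, sd = 0.3))
  ic <- 1:80
  rmse <- function(sel) {
    f <- fit_plsr(X[ic, sel, drop = FALSE], y[ic], n_lv = min(8, length(sel)))
    sqrt(mean((predict(f, X[-ic, sel, drop = FALSE]) - y[-ic])^2))
  }
  full <- rmse(1:p)
  f_full <- fit_plsr(X[ic, ], y[ic], n_lv = 8)
  expect_lte(rmse(vip_select(f_full, 1.0)$selected), full * 1.1)
  expect_lte(rmse(cars_select(X[ic, ], y[ic], seed = 2)$selected), full * 1.1)
})

test_that("the method harness behaves on exactly-linear and permuted data", {
  methods <- c("PLSR-AW", "PLSR-AW0.99", "PLSR-CARS", "PLSR-VIP",
               "GPR", "SVM", "RF", "MLR", "SMLR", "LASSO", "RMLR")
  exactly_linear <- c("PLSR-AW", "PLSR-AW0.99", "PLSR-CARS", "PLSR-VIP",
                      "MLR", "SMLR", "LASSO", "RMLR")
  set.seed(38)
  n <- 300; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p); beta[c(1, 6)] <- c(1, -0.8)   # on the every-5th basis
  y <- as.numeric(X %*% beta)
  ic <- 1:200
  rows <- lapply(methods, function(m) {
    suppressWarnings(run_method(m, X[ic, ], y[ic], X[-ic, ], y[-ic],
                                seed = 3, reps = 3))
  })
  tab <- do.call(rbind, rows)
  expect_identical(nrow(tab), 11L)
  expect_identical(tab$method, methods)
  expect_true(all(c("r2_cal", "rmse_cal", "r2_val", "rmse_val") %in% names(tab)))
  for (i in seq_along(methods)) {
    bound <- if (methods[i] %in% exactly_linear) 0.99 else 0.80
    expect_gt(tab$r2_val[i], bound)
  }
  expect_error(run_method("XGB", X, y, X, y), "unknown method")

  # permutation null: no method finds signal in shuffled responses
  set.seed(39)
  n <- 90; p <- 40
  Xn <- matrix(rnorm(n * p), n, p)
  yb <- as.numeric(Xn %*% rnorm(p, sd = 0.3))
  icn <- 1:60
  for (m in methods) {
    r2s <- vapply(1:3, function(s) {
      set.seed(600 + s)
      yp <- sample(yb)
      r2 <- suppressWarnings(run_method(m, Xn[icn, ], yp[icn], Xn[-icn, ],
                                        yp[-icn], seed = s, reps = 2))$r2_val
      if (is.na(r2)) 0 else r2   # degenerate constant predictions = no signal
    }, 1)
    expect_lte(mean(r2s), 0.15)
  }
})
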