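test_that("tissue contrasts reproduce the printed group arithmetic", {
  # paired vectors with group means pinned to the reported tissue means
  set.seed(51)
  dev <- rnorm(15); dev <- dev - mean(dev)
  ps_n <- 2.1 + 0.35 * dev
  bl_n <- 3.2 + 0.32 * dev + rnorm(15, sd = 0.05)
  bl_n <- bl_n - mean(bl_n) + 3.2
  cn <- tissue_contrast(ps_n, bl_n, "nitrogen")
  expect_equal(cn$diff, 1.1, tolerance = 1e-12)
  expect_lt(cn$p_value, 0.001)

  ps_s <- 153 + 53 * dev
  bl_s <- 60 + 18 * dev
  cs <- tissue_contrast(ps_s, bl_s, "sugars")
  expect_equal(cs$diff, -93, tolerance = 1e-12)   # BL - PS convention
  expect_equal(abs(cs$diff), 93)
  expect_lt(cs$p_value, 0.001)
})

test_that("contrasts are antisymmetric and handle degenerate pairs", {
  x <- c(1, 2, 3, 5); y <- c(2, 2.5, 4, 6)
  a <- tissue_contrast(x, y)
  b <- tissue_contrast(y, x)
  expect_equal(a$diff, -b$diff)
  eq <- tissue_contrast(x, x)
  expect_equal(eq$diff, 0)
  expect_equal(eq$p_value, 1)
  expect_error(tissue_contrast(1:4, 1:3), "paired")
  expect_error(tissue_contrast(1, 2), "at least 2")
})

test_that("relative partitioning matches the printed sugar means", {
  # LMW: PS 77, BL 43; HMW: PS 75, BL 17
  r <- relative_partitioning(77, 43, 75, 17)
  expect_equal(r, (43 / 77) / (17 / 75), tolerance = 1e-12)
  expect_equal(round(r, 1), 2.5)
  expect_equal(relative_partitioning(10, 10, 4, 4), 1)
  expect_equal(relative_partitioning(2, 1, 4, 1), 2)  # ratios 0.5 vs 0.25
  expect_equal(relative_partitioning(7.7, 4.3, 7.5, 1.7),
               relative_partitioning(77, 43, 75, 17))  # scale invariance
  expect_error(relative_partitioning(0, 1, 1, 1), "must be > 0")
})

test_that("crude protein conversion is nitrogen x 6.25", {
  expect_equal(crude_protein(0), 0)
  expect_equal(crude_protein(3.2), 20)
  expect_equal(crude_protein(1), 6.25)
  expect_error(crude_protein(-0.1), "negative")
})

test_that("PS~BL regression recovers slopes with honest uncertainty", {
  expect_equal(ps_bl_regression(1:5, 1:5)$slope, 1)
  expect_equal(ps_bl_regression(1:5, 1:5)$r2, 1)
  expect_lt(ps_bl_regression(1:5, 1:5)$rmse, 1e-12)
  col <- ps_bl_regression(c(1, 2, 3), c(5, 7, 9))
  expect_equal(col$slope, 2)
  expect_lt(col$rmse, 1e-12)
  set.seed(52)
  x <- runif(100, 0, 10)
  y <- 0.5 * x + rnorm(100, sd = 0.3)
  fit <- ps_bl_regression(x, y)
  expect_lt(abs(fit$slope - 0.5), 3 * fit$slope_se)
  expect_error(ps_bl_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(ps_bl_regression(1:2, 1:2), "at least 3")
})

test_that("canonical variates separate well-separated groups completely", {
  set.seed(53)
  n <- 20; p <- 234
  base <- matrix(rnorm(2 * n * p), 2 * n, p)
  shift <- rnorm(p)
  shift <- shift / sqrt(sum(shift^2)) * 10      # mean separation of 10 SDs
  base[1:n, ] <- base[1:n, ] + matrix(shift, n, p, byrow = TRUE)
  labels <- rep(c("PS", "BL"), each = n)
  proj <- tissue_cva(base, labels, stride = 2)
  s1 <- proj$scores[labels == "PS", 1]
  s2 <- proj$scores[labels == "BL", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))   # zero overlap
  # midpoint-rule misclassification is zero
  mid <- (mean(s1) + mean(s2)) / 2
  side <- sign(mean(s1) - mid)
  expect_true(all(sign(s1 - mid) == side) && all(sign(s2 - mid) == -side))
  expect_lt(proj$wilks_lambda, 0.05)
  expect_identical(nrow(proj$scores), as.integer(2 * n))
  expect_length(proj$band_index, 117)
})

test_that("identical group distributions give Wilks' lambda near 1", {
  # sample-rich regime (n >> bands) so the null statistic is well behaved
  lams <- vapply(1:10, function(s) {
    set.seed(700 + s)
    X <- matrix(rnorm(120 * 6), 120, 6)
    tissue_cva(X, rep(c("PS", "BL"), each = 60), stride = 1)$wilks_lambda
  }, 1)
  expect_true(all(lams >= 0.9 & lams <= 1))
})

test_that("CVA scores are invariant (up to sign) to common affine transforms", {
  set.seed(54)
  X <- matrix(rnorm(30 * 40), 30, 40)
  X[1:15, ] <- X[1:15, ] + 2
  labels <- rep(c("PS", "BL"), each = 15)
  p0 <- tissue_cva(X, labels, stride = 2)
  p1 <- tissue_cva(3 * X + 7, labels, stride = 2)
  c0 <- p0$scores[, 1] - mean(p0$scores[, 1])
  c1 <- p1$scores[, 1] - mean(p1$scores[, 1])
  expect_gt(abs(cor(c0, c1)), 1 - 1e-8)
  expect_error(tissue_cva(X, rep("PS", 30)), "2 groups")
})

test_that("generator PS and BL spectra separate along canonical variable 1", {
  sh <- shared_study()
  study <- sh$study
  units <- study$units
  sub <- units$plant_id %in% unique(units$plant_id)[1:10]
  X <- grasshsi:::snv_rows(study$X[sub, , drop = FALSE])
  labels <- units$tissue[sub]
  proj <- tissue_cva(X, labels, stride = 2)
  ps <- proj$scores[labels == "PS", 1]
  bl <- proj$scores[labels == "BL", 1]
  expect_true(max(ps) < min(bl) || max(bl) < min(ps))
})
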