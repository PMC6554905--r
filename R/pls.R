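#' Partial least squares regression (NIPALS, single response)
#'
#' Fits a PLS1 model by the NIPALS algorithm with deflation of X only.
#' X is mean-centered (optionally autoscaled); y is mean-centered. Components
#' are extracted until `n_lv` or until the residual X carries no covariance
#' with y, in which case the model is truncated and the event recorded in
#' `$warnings`.
#'
#' @param X Numeric matrix, samples x bands. No missing values.
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables requested.
#' @param scale Autoscale columns of X to unit variance? Default FALSE:
#'   SNV-preprocessed spectra are already on a common scale.
#' @param tol Convergence tolerance of the inner NIPALS iteration.
#' @param max_iter Iteration cap for one component.
#' @return A `pls_model` with centering/scaling vectors, per-component
#'   weights (`W`), X loadings (`P`), y loadings (`q`), scores (`Tm`),
#'   the regression vector `coef` on the centered (and scaled, if requested)
#'   X scale, and `n_lv` actually fitted.
#' @export
fit_plsr <- function(X, y, n_lv, scale = FALSE, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("nrow(X) = ", n, " but length(y) = ", length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(y) == 0) stop("zero-variance response")
  if (n_lv < 1) stop("n_lv must be >= 1")
  max_rank <- min(n - 1L, p)
  warnings <- character()
  if (n_lv > max_rank) {
    warnings <- c(warnings, paste0("n_lv = ", n_lv, " exceeds max rank ",
                                   max_rank, "; truncated"))
    n_lv <- max_rank
  }

  x_mean <- colMeans(X)
  x_sd <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (scale && any(x_sd == 0)) stop("cannot autoscale zero-variance bands: ",
                                    paste(which(x_sd == 0), collapse = ", "))
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  yc <- y - y_mean

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  Xd <- Xc
  x_scale0 <- sqrt(sum(Xc^2))
  a <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xd, yc)[, 1]
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < tol * max(1, x_scale0)) {
      warnings <- c(warnings, paste0("no residual covariance with y after ",
                                     a, " components; truncated"))
      break
    }
    w <- w / wn
    tvec <- Xd %*% w
    # inner iteration (single-response NIPALS converges immediately, but the
    # loop guards against pathological scaling)
    for (it in seq_len(max_iter)) {
      tt <- sum(tvec^2)
      if (tt == 0) break
      w_new <- crossprod(Xd, yc)[, 1]
      w_new <- w_new / sqrt(sum(w_new^2))
      t_new <- Xd %*% w_new
      if (sqrt(sum((t_new - tvec)^2)) < tol * sqrt(sum(tvec^2))) {
        w <- w_new; tvec <- t_new; break
      }
      w <- w_new; tvec <- t_new
    }
    tt <- sum(tvec^2)
    if (tt < (tol * x_scale0)^2) {
      warnings <- c(warnings, paste0("degenerate score vector at component ",
                                     k, "; truncated"))
      break
    }
    pvec <- crossprod(Xd, tvec)[, 1] / tt
    qk <- sum(yc * tvec) / tt
    W[, k] <- w; P[, k] <- pvec; Tm[, k] <- tvec; q[k] <- qk
    Xd <- Xd - tvec %*% t(pvec)
    a <- k
  }
  if (a == 0L) stop("no PLS component could be extracted (X orthogonal to y?)")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]

  # regression vector on the centered/scaled X: B = W (P'W)^-1 q
  coef <- W %*% solve(crossprod(P, W), q)

  structure(list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 W = W, P = P, q = q, Tm = Tm, n_lv = a,
                 coef = as.numeric(coef), scaled = scale,
                 warnings = warnings),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix (samples x bands) or a single spectrum.
#' @param form `"coef"` (default) predicts via the collapsed regression
#'   vector; `"components"` recomputes scores component by component. The two
#'   agree to numerical round-off and the agreement is a standing invariant
#'   of the test suite.
#' @param ... Unused.
#' @export
predict.pls_model <- function(object, newdata, form = c("coef", "components"), ...) {
  form <- match.arg(form)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("band mismatch: model has ", length(object$x_mean),
         " bands, newdata has ", ncol(X))
  }
  Xc <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, "/")
  if (form == "coef") {
    return(as.numeric(object$y_mean + Xc %*% object$coef))
  }
  # component form: regenerate scores with deflation
  yhat <- rep(object$y_mean, nrow(X))
  Xd <- Xc
  for (k in seq_len(object$n_lv)) {
    tk <- Xd %*% object$W[, k]
    yhat <- yhat + object$q[k] * tk[, 1]
    Xd <- Xd - tk %*% t(object$P[, k])
  }
  yhat
}

#' Variable importance in projection (VIP)
#'
#' Per-band importance of a fitted PLS model,
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a = q_a^2 t_a' t_a} the y-variance captured by component a.
#' The mean of squared VIP scores is identically 1, so a VIP >= 1 threshold
#' flags bands of above-average importance.
#'
#' @param model A `pls_model`.
#' @return Numeric vector of VIP scores, one per band.
#' @export
vip <- function(model) {
  p <- nrow(model$W)
  ssy <- model$q^2 * colSums(model$Tm^2)
  wnorm2 <- colSums(model$W^2)
  contrib <- sweep(model$W^2, 2, wnorm2, "/")      # (w_ja / ||w_a||)^2
  sqrt(p * as.numeric(contrib %*% ssy) / sum(ssy))
}

#' Fit statistics in the standard report shape
#'
#' Computes the per-subset statistics reported for every model: R-squared,
#' RMSE, n, response min/max/mean/SD, the validation regression
#' `y_measured = a + b * y_predicted` (OLS with standard errors), and bias
#' (mean of predicted minus observed).
#'
#' @param y_obs Observed response values.
#' @param y_pred Predicted values, same length (>= 3).
#' @param subset Label for this subset ("calibration"/"validation").
#' @param lv Number of latent variables of the model (NA for non-PLS methods).
#' @param r2_method `"cor"` (default): squared Pearson correlation, the
#'   chemometrics convention; `"cod"`: coefficient of determination
#'   1 - SS_res/SS_tot.
#' @return A one-row data.frame (`model_report`).
#' @export
model_report <- function(y_obs, y_pred, subset = "validation", lv = NA_integer_,
                         r2_method = c("cor", "cod")) {
  r2_method <- match.arg(r2_method)
  n <- length(y_obs)
  if (length(y_pred) != n) stop("y_obs and y_pred lengths differ")
  if (n < 3) stop("need at least 3 observations, got ", n)

  degenerate <- stats::var(y_obs) == 0 || stats::var(y_pred) == 0
  r2 <- if (degenerate) NA_real_
        else if (r2_method == "cor") stats::cor(y_obs, y_pred)^2
        else 1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  bias <- mean(y_pred - y_obs)

  if (!degenerate) {
    fit <- stats::lm(y_obs ~ y_pred)
    # summary warns on perfect fits; those are legitimate inputs here
    cf <- suppressWarnings(summary(fit))$coefficients
    intercept <- cf[1, 1]; intercept_se <- cf[1, 2]
    slope <- cf[2, 1]; slope_se <- cf[2, 2]
  } else {
    intercept <- intercept_se <- slope <- slope_se <- NA_real_
  }

  data.frame(subset = subset, n = n, lv = lv,
             r2 = r2, rmse = rmse,
             min = min(y_obs), max = max(y_obs),
             mean = mean(y_obs), sd = stats::sd(y_obs),
             intercept = intercept, intercept_se = intercept_se,
             slope = slope, slope_se = slope_se,
             bias = bias,
             stringsAsFactors = FALSE)
}
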