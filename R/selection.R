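#' Split plants into calibration and validation sets
#'
#' Plant-level random split: two-thirds of the plants calibrate the model,
#' the remaining third validates it. All rows (tissues, replicates) of one
#' plant stay on the same side, preventing leakage between the sets.
#'
#' @param plant_ids Vector of plant identifiers (duplicates allowed; the
#'   split is over unique plants).
#' @param frac Calibration fraction, in (0, 1); calibration size is
#'   `round(frac * n)`, guarded so both sides keep at least one plant.
#' @param seed Integer seed; same seed, same split.
#' @return List with `calibration` and `validation` (character vectors of
#'   plant ids, disjoint and exhaustive).
#' @export
split_calibration_validation <- function(plant_ids, frac = 2 / 3, seed = 1L) {
  if (frac <= 0 || frac >= 1) stop("frac must lie strictly inside (0, 1)")
  ids <- unique(plant_ids)
  n <- length(ids)
  if (n < 3) stop("need at least 3 plants to split, got ", n)
  n_cal <- round(frac * n)
  n_cal <- max(1L, min(n - 1L, n_cal))
  set.seed(as.integer(seed))
  cal <- sort(sample(ids, n_cal))
  list(calibration = cal, validation = sort(setdiff(ids, cal)))
}

# predictions at every LV 1..A from one fitted model, n x A
predict_all_lv <- function(model, X) {
  X <- as.matrix(X)
  Xc <- sweep(sweep(X, 2, model$x_mean), 2, model$x_sd, "/")
  out <- matrix(model$y_mean, nrow(X), model$n_lv)
  Xd <- Xc
  acc <- rep(model$y_mean, nrow(X))
  for (k in seq_len(model$n_lv)) {
    tk <- Xd %*% model$W[, k]
    acc <- acc + model$q[k] * tk[, 1]
    out[, k] <- acc
    Xd <- Xd - tk %*% t(model$P[, k])
  }
  out
}

#' Monte Carlo cross-validation error curve over latent variables
#'
#' For each Monte Carlo replicate, draws a fresh random k-fold partition of
#' the calibration samples, fits PLS on each training fold once, and pools
#' the held-out squared errors per LV over all folds and replicates. The
#' returned `press` is the per-LV mean squared CV error. Folds where the
#' model truncates below `lv_max` (rank deficiency) contribute their
#' highest-LV prediction to the larger LVs, so the curve is defined on the
#' full grid.
#'
#' @param X,y Calibration spectra matrix and response.
#' @param lv_max Largest LV evaluated (grid is 1..lv_max).
#' @param folds Folds per replicate (default tenfold).
#' @param reps Monte Carlo replicates (default 100).
#' @param seed Integer seed.
#' @return A `cv_curve`: `lv_grid`, `press` (mean squared error per LV),
#'   `press_se` (standard error over replicates), `folds`, `reps`, `seed`.
#' @export
mc_cv_curve <- function(X, y, lv_max = 50L, folds = 10L, reps = 100L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds > n) stop("folds (", folds, ") exceeds samples (", n, ")")
  if (folds < 2) stop("need at least 2 folds")
  if (lv_max < 1) stop("lv_max must be >= 1")
  set.seed(as.integer(seed))
  lv_max <- as.integer(lv_max)

  rep_mse <- matrix(NA_real_, reps, lv_max)
  for (r in seq_len(reps)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    sse <- numeric(lv_max); cnt <- 0L
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (all(test) || !any(test)) next
      fit <- fit_plsr(X[!test, , drop = FALSE], y[!test],
                      n_lv = min(lv_max, sum(!test) - 1L, ncol(X)))
      pred <- predict_all_lv(fit, X[test, , drop = FALSE])
      if (ncol(pred) < lv_max) {
        pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                   lv_max - ncol(pred)))
      }
      sse <- sse + colSums((pred - y[test])^2)
      cnt <- cnt + sum(test)
    }
    rep_mse[r, ] <- sse / cnt
  }
  press <- colMeans(rep_mse)
  press_se <- apply(rep_mse, 2, stats::sd) / sqrt(reps)
  structure(list(lv_grid = seq_len(lv_max), press = press, press_se = press_se,
                 folds = folds, reps = reps, seed = as.integer(seed)),
            class = "cv_curve")
}

#' Adjusted Wold's R criterion for latent-variable selection
#'
#' Walks the CV error curve and selects the smallest LV count k at which
#' adding one more component no longer improves the criterion:
#' `press(k+1) / press(k) >= threshold`. Threshold 1 stops at the first
#' non-improvement; 0.99 additionally demands each extra component buy at
#' least a 1\% error reduction, so it never selects more LVs than
#' threshold 1. If no k qualifies, the largest LV on the grid is returned.
#' A press value that has collapsed to numerical zero (noise-free data fit
#' exactly) is treated as converged at that k.
#'
#' @param curve A `cv_curve` (or bare numeric press vector).
#' @param threshold Ratio threshold (1 or 0.99 in practice).
#' @return Selected LV count (integer).
#' @export
adjusted_wold <- function(curve, threshold = 1.0) {
  press <- if (inherits(curve, "cv_curve")) curve$press else as.numeric(curve)
  K <- length(press)
  if (K < 2) stop("CV curve needs at least 2 LVs")
  eps <- 1e-12 * max(press[1], .Machine$double.eps)
  for (k in seq_len(K - 1)) {
    if (press[k] <= eps) return(k)
    if (press[k + 1] / press[k] >= threshold) return(k)
  }
  K
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Monte Carlo wavelength selection: each run fits PLS on a random
#' `mc_ratio` subsample of the calibration plants, ranks the surviving
#' bands by absolute regression coefficient, enforces an exponentially
#' decreasing retention ratio (from all bands at run 1 down to 2 bands at
#' the final run), then resamples the retained set with probability
#' proportional to coefficient magnitude (adaptive reweighted sampling).
#' Every run's band subset is scored by k-fold CV RMSE on the full
#' calibration set; the subset with minimum CV RMSE wins.
#'
#' @param X,y Calibration spectra and response.
#' @param n_runs Number of CARS runs (default 50).
#' @param mc_ratio Fraction of samples drawn per run (default 0.8).
#' @param folds CV folds used to score each run's subset (default 5).
#' @param n_lv LVs for the internal PLS fits (capped at the data rank).
#' @param seed Integer seed.
#' @return A `band_subset`: `method = "CARS"`, `selected` (increasing band
#'   positions), `criterion_value` (winning CV RMSE), `trace` (per-run
#'   retained count and CV RMSE).
#' @export
cars_select <- function(X, y, n_runs = 50L, mc_ratio = 0.8, folds = 5L,
                        n_lv = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 bands")
  set.seed(as.integer(seed))

  # retention schedule r_i = a e^{-k i} with r_1 = 1 and r_{n_runs} = 2/p
  if (n_runs > 1) {
    kk <- log(p / 2) / (n_runs - 1)
    aa <- exp(kk)
    ratio <- aa * exp(-kk * seq_len(n_runs))
  } else {
    ratio <- 1
  }

  retained <- seq_len(p)
  best <- list(rmse = Inf, selected = retained)
  trace <- data.frame(run = integer(), n_retained = integer(), cv_rmse = numeric())
  warn <- NULL
  for (i in seq_len(n_runs)) {
    if (length(retained) < 2) {
      warn <- paste0("band pool collapsed at run ", i, "; returning best so far")
      break
    }
    idx <- sample(n, max(2L, round(mc_ratio * n)))
    fit <- fit_plsr(X[idx, retained, drop = FALSE], y[idx],
                    n_lv = min(n_lv, length(idx) - 1L, length(retained)))
    w <- abs(fit$coef)
    keep_n <- max(2L, min(length(retained), ceiling(ratio[i] * p)))
    forced <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
    wf <- w[match(forced, retained)]
    # adaptive reweighted sampling within the forced set; when the weight
    # distribution is so skewed that resampling degenerates to <2 unique
    # bands, keep the forced set for this run instead. A retention ratio of
    # 1 (run 1) keeps the full band set untouched.
    if (ratio[i] >= 1 || all(wf == 0)) {
      sampled <- forced
    } else {
      sampled <- unique(sample(forced, size = keep_n, replace = TRUE, prob = wf))
      if (length(sampled) < 2) sampled <- forced
    }
    retained <- sort(sampled)
    rmse <- cv_rmse_subset(X[, retained, drop = FALSE], y, folds = folds,
                           n_lv = n_lv)
    trace <- rbind(trace, data.frame(run = i, n_retained = length(retained),
                                     cv_rmse = rmse))
    if (rmse < best$rmse) best <- list(rmse = rmse, selected = retained)
  }
  if (!is.null(warn)) warning(warn)
  structure(list(method = "CARS", selected = best$selected,
                 criterion_value = best$rmse, trace = trace,
                 schedule = ratio, seed = as.integer(seed)),
            class = "band_subset")
}

cv_rmse_subset <- function(Xs, y, folds = 5L, n_lv = 10L) {
  n <- nrow(Xs)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  sse <- 0; cnt <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test) || all(test)) next
    fit <- fit_plsr(Xs[!test, , drop = FALSE], y[!test],
                    n_lv = min(n_lv, sum(!test) - 1L, ncol(Xs)))
    pred <- predict(fit, Xs[test, , drop = FALSE])
    sse <- sse + sum((pred - y[test])^2)
    cnt <- cnt + sum(test)
  }
  sqrt(sse / cnt)
}

#' VIP-threshold wavelength selection
#'
#' Selects the bands whose VIP score reaches `threshold` (default 1, the
#' usual above-average-importance rule). Contiguous selected bands can be
#' reported as nm ranges via [band_ranges_nm()].
#'
#' @param model A fitted `pls_model`.
#' @param threshold VIP cutoff (inclusive).
#' @return A `band_subset` with `method = "VIP"`.
#' @export
vip_select <- function(model, threshold = 1.0) {
  v <- vip(model)
  sel <- which(v >= threshold)
  if (length(sel) == 0) {
    stop("no band reaches VIP >= ", threshold, " (max VIP = ",
         format(max(v), digits = 4), ")")
  }
  structure(list(method = "VIP", selected = sel, criterion_value = threshold,
                 vip = v),
            class = "band_subset")
}

#' Summarize selected bands as wavelength ranges
#'
#' Collapses runs of adjacent selected band positions into `lo-hi` nm
#' ranges, the conventional way key wavelength regions are reported.
#'
#' @param subset A `band_subset` (or integer positions).
#' @param wavelengths Full band grid, nm.
#' @return data.frame with `lo_nm`, `hi_nm`, `n_bands`.
#' @export
band_ranges_nm <- function(subset, wavelengths) {
  sel <- if (inherits(subset, "band_subset")) subset$selected else sort(subset)
  brk <- c(0, which(diff(sel) > 1), length(sel))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    run <- sel[(brk[i] + 1):brk[i + 1]]
    data.frame(lo_nm = wavelengths[min(run)], hi_nm = wavelengths[max(run)],
               n_bands = length(run))
  }))
  out
}

#' Fit and validate one regression method
#'
#' Uniform harness over the eleven chemometric methods compared for
#' attribute prediction: the four PLSR variants use this package's NIPALS
#' core with Adjusted Wold LV selection (and CARS/VIP band selection);
#' the generic learners delegate to standard implementations (kernlab
#' Gaussian process, e1071 SVM, randomForest, lm-family, glmnet lasso,
#' MASS robust regression) behind a common interface. MLR-family methods
#' are fit on every-5th-band subsampled spectra to keep the design matrix
#' full rank.
#'
#' @param method One of "PLSR-AW", "PLSR-AW0.99", "PLSR-CARS", "PLSR-VIP",
#'   "GPR", "SVM", "RF", "MLR", "SMLR", "LASSO", "RMLR" (case-insensitive).
#' @param X_cal,y_cal Calibration spectra and response.
#' @param X_val,y_val Validation spectra and response.
#' @param seed Integer seed driving CV partitions and stochastic learners.
#' @param lv_max Largest LV considered by the PLSR variants.
#' @param reps Monte Carlo CV replicates for LV selection.
#' @param mlr_stride Band stride for the MLR-family dimension reduction.
#' @return One-row data.frame: method, lv, n_bands, r2_cal, rmse_cal, n_cal,
#'   r2_val, rmse_val, n_val, intercept, slope, bias.
#' @export
run_method <- function(method, X_cal, y_cal, X_val, y_val, seed = 1L,
                       lv_max = 50L, reps = 20L, mlr_stride = 5L) {
  methods <- c("PLSR-AW", "PLSR-AW0.99", "PLSR-CARS", "PLSR-VIP",
               "GPR", "SVM", "RF", "MLR", "SMLR", "LASSO", "RMLR")
  mi <- match(toupper(method), toupper(methods))
  if (is.na(mi)) {
    stop("unknown method '", method, "'; valid: ", paste(methods, collapse = ", "))
  }
  method <- methods[mi]
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  set.seed(as.integer(seed))
  lv <- NA_integer_
  n_bands <- ncol(X_cal)
  lv_cap <- function(X) min(lv_max, nrow(X) - ceiling(nrow(X) / 10) - 1L, ncol(X))

  fit_plsr_aw <- function(Xc, Xv, threshold) {
    curve <- mc_cv_curve(Xc, y_cal, lv_max = lv_cap(Xc), folds = 10L,
                         reps = reps, seed = seed)
    a <- adjusted_wold(curve, threshold)
    fit <- fit_plsr(Xc, y_cal, n_lv = a)
    list(lv = fit$n_lv, cal = predict(fit, Xc), val = predict(fit, Xv))
  }

  res <- switch(method,
    "PLSR-AW" = fit_plsr_aw(X_cal, X_val, 1.0),
    "PLSR-AW0.99" = fit_plsr_aw(X_cal, X_val, 0.99),
    "PLSR-CARS" = {
      sub <- cars_select(X_cal, y_cal, seed = seed)
      n_bands <- length(sub$selected)
      fit_plsr_aw(X_cal[, sub$selected, drop = FALSE],
                  X_val[, sub$selected, drop = FALSE], 1.0)
    },
    "PLSR-VIP" = {
      curve <- mc_cv_curve(X_cal, y_cal, lv_max = lv_cap(X_cal), folds = 10L,
                           reps = reps, seed = seed)
      full <- fit_plsr(X_cal, y_cal, n_lv = adjusted_wold(curve, 1.0))
      sub <- vip_select(full, 1.0)
      n_bands <- length(sub$selected)
      fit_plsr_aw(X_cal[, sub$selected, drop = FALSE],
                  X_val[, sub$selected, drop = FALSE], 1.0)
    },
    "GPR" = {
      fit <- kernlab::gausspr(x = X_cal, y = y_cal)
      # kernlab ships its own predict generic for its S4 fit objects
      list(cal = as.numeric(kernlab::predict(fit, X_cal)),
           val = as.numeric(kernlab::predict(fit, X_val)))

    },
    "SVM" = {
      fit <- e1071::svm(X_cal, y_cal)
      list(cal = as.numeric(predict(fit, X_cal)),
           val = as.numeric(predict(fit, X_val)))
    },
    "RF" = {
      fit <- randomForest::randomForest(X_cal, y_cal, ntree = 300)
      list(cal = as.numeric(predict(fit, X_cal)),
           val = as.numeric(predict(fit, X_val)))
    },
    "MLR" = {
      idx <- mlr_basis(ncol(X_cal), nrow(X_cal), mlr_stride)
      n_bands <- length(idx)
      df_cal <- as.data.frame(X_cal[, idx, drop = FALSE])
      fit <- stats::lm(y_cal ~ ., data = df_cal)
      list(cal = unname(predict(fit, df_cal)),
           val = unname(predict(fit, as.data.frame(X_val[, idx, drop = FALSE]))))
    },
    "SMLR" = {
      idx <- mlr_basis(ncol(X_cal), nrow(X_cal), mlr_stride)
      sel <- stepwise_select(X_cal[, idx, drop = FALSE], y_cal,
                             p_enter = 0.05, p_exit = 0.10)
      n_bands <- length(sel)
      keep <- idx[sel]
      df_cal <- as.data.frame(X_cal[, keep, drop = FALSE])
      fit <- stats::lm(y_cal ~ ., data = df_cal)
      list(cal = unname(predict(fit, df_cal)),
           val = unname(predict(fit, as.data.frame(X_val[, keep, drop = FALSE]))))
    },
    "LASSO" = {
      cvfit <- glmnet::cv.glmnet(X_cal, y_cal, nfolds = 5)
      list(cal = as.numeric(predict(cvfit, X_cal, s = "lambda.min")),
           val = as.numeric(predict(cvfit, X_val, s = "lambda.min")))
    },
    "RMLR" = {
      idx <- mlr_basis(ncol(X_cal), nrow(X_cal), mlr_stride)
      n_bands <- length(idx)
      df_cal <- as.data.frame(X_cal[, idx, drop = FALSE])
      fit <- MASS::rlm(y_cal ~ ., data = df_cal, maxit = 100)
      list(cal = unname(predict(fit, df_cal)),
           val = unname(predict(fit, as.data.frame(X_val[, idx, drop = FALSE]))))
    }
  )
  if (!is.null(res$lv)) lv <- res$lv
  cal <- model_report(y_cal, res$cal, subset = "calibration", lv = lv)
  val <- model_report(y_val, res$val, subset = "validation", lv = lv)
  data.frame(method = method, lv = lv, n_bands = n_bands,
             r2_cal = cal$r2, rmse_cal = cal$rmse, n_cal = cal$n,
             r2_val = val$r2, rmse_val = val$rmse, n_val = val$n,
             intercept = val$intercept, slope = val$slope, bias = val$bias,
             stringsAsFactors = FALSE)
}

# every-stride-th band, thinned further if still wider than n - 2
mlr_basis <- function(p, n, stride) {
  idx <- subsample_index(p, stride, 0L)
  while (length(idx) > n - 2 && stride < p) {
    stride <- stride * 2L
    idx <- subsample_index(p, stride, 0L)
  }
  idx
}

# forward-backward stepwise on lm p-values
stepwise_select <- function(X, y, p_enter = 0.05, p_exit = 0.10, max_steps = 200L) {
  p <- ncol(X)
  current <- integer(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    cand <- setdiff(seq_len(p), current)
    if (length(cand) > 0 && length(current) < nrow(X) - 2) {
      pvals <- vapply(cand, function(j) {
        fit <- stats::lm(y ~ X[, c(current, j), drop = FALSE])
        cf <- summary(fit)$coefficients
        cf[nrow(cf), 4]
      }, numeric(1))
      if (min(pvals, na.rm = TRUE) < p_enter) {
        current <- c(current, cand[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward
    if (length(current) > 1) {
      fit <- stats::lm(y ~ X[, current, drop = FALSE])
      cf <- summary(fit)$coefficients
      pv <- cf[-1, 4]
      if (max(pv, na.rm = TRUE) > p_exit) {
        current <- current[-which.max(pv)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(current) == 0) current <- 1L  # degenerate guard: keep one band
  sort(current)
}
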