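#' Paired pseudostem-vs-blade contrast for one attribute
#'
#' Group means and SDs with the signed difference `mean(BL) - mean(PS)`
#' (positive when the attribute concentrates in the blades, as nitrogen
#' does; negative for the sugars), plus the standard error and p-value of a
#' paired two-sided t-test on the within-plant differences. PS and BL come
#' from the same plants, so the paired test is the appropriate one.
#'
#' @param ps,bl Paired tissue values, plant i in position i of both vectors.
#' @param attribute Attribute label carried through to the result.
#' @return A `tissue_contrast`: attribute, n, mean/sd per tissue, `diff`
#'   (BL - PS), `se_diff`, `p_value`.
#' @export
tissue_contrast <- function(ps, bl, attribute = NA_character_) {
  if (length(ps) != length(bl)) {
    stop("PS and BL values must be paired; lengths ", length(ps), " vs ", length(bl))
  }
  ok <- stats::complete.cases(ps, bl)
  ps <- ps[ok]; bl <- bl[ok]
  n <- length(ps)
  if (n < 2) stop("need at least 2 complete PS/BL pairs, got ", n)
  d <- bl - ps
  se <- stats::sd(d) / sqrt(n)
  if (se == 0) {
    p <- if (mean(d) == 0) 1 else 0   # all differences identical
  } else {
    p <- stats::t.test(d)$p.value
  }
  structure(list(attribute = attribute, n = n,
                 mean_ps = mean(ps), mean_bl = mean(bl),
                 sd_ps = stats::sd(ps), sd_bl = stats::sd(bl),
                 diff = mean(bl) - mean(ps), se_diff = se, p_value = p),
            class = "tissue_contrast")
}

#' Relative tissue partitioning of two sugar fractions
#'
#' Ratio of blade/pseudostem concentration ratios,
#' `(lmw_bl / lmw_ps) / (hmw_bl / hmw_ps)`: how much more strongly the
#' low-molecular-weight fraction partitions into the blades than the
#' high-molecular-weight fraction. Invariant to rescaling all four means by
#' a common factor.
#'
#' @param lmw_ps,lmw_bl,hmw_ps,hmw_bl Group mean concentrations (> 0).
#' @return The partitioning ratio (scalar).
#' @export
relative_partitioning <- function(lmw_ps, lmw_bl, hmw_ps, hmw_bl) {
  vals <- c(lmw_ps = lmw_ps, lmw_bl = lmw_bl, hmw_ps = hmw_ps, hmw_bl = hmw_bl)
  if (any(vals <= 0)) {
    stop("all group means must be > 0; got ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  (lmw_bl / lmw_ps) / (hmw_bl / hmw_ps)
}

#' Crude protein from total nitrogen
#'
#' The standard conversion: crude protein = total nitrogen x 6.25.
#'
#' @param total_nitrogen_percent Total nitrogen, \% (>= 0).
#' @return Crude protein, \%.
#' @export
crude_protein <- function(total_nitrogen_percent) {
  if (any(total_nitrogen_percent < 0)) stop("nitrogen content cannot be negative")
  total_nitrogen_percent * 6.25
}

#' Blade-on-pseudostem regression for one attribute
#'
#' Ordinary least squares of BL values on PS values with slope standard
#' error, correlation R-squared and residual RMSE — the plant-level
#' relationship showing that tissue concentrations track each other.
#'
#' @param x PS values (predictor).
#' @param y BL values (response), paired with `x`.
#' @return List: `slope`, `slope_se`, `intercept`, `r2`, `rmse`, `n`.
#' @export
ps_bl_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs, got ", n)
  if (stats::var(x) == 0) stop("zero variance in PS values; slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients   # exact fits are fine
  list(slope = cf[2, 1], slope_se = cf[2, 2], intercept = cf[1, 1],
       r2 = stats::cor(x, y)^2,
       rmse = sqrt(mean(stats::residuals(fit)^2)), n = n)
}

#' Canonical variate analysis of tissue spectra
#'
#' One-way MANOVA-style separation of pseudostem and blade mean spectra:
#' bands are first subsampled (every 2nd wavelength by default, the
#' 117-band grid), then the canonical directions maximizing
#' between-group over within-group variance are extracted from
#' `W^{-1} B`. The pooled within-group covariance is ridge-regularized by
#' `lambda * trace(W)/p` when sample count is small relative to bands.
#' Wilks' lambda (`prod 1/(1+eigenvalue)`) summarizes the separation
#' (near 1 = none, near 0 = complete).
#'
#' @param spectra Samples x bands matrix of SNV mean spectra.
#' @param labels Factor or character vector, "PS"/"BL" per row.
#' @param stride,offset Band subsampling passed to [subsample_bands()];
#'   `offset` defaults to 1 (the every-2nd-wavelength convention) except for
#'   `stride = 1`, where it is 0.
#' @param ridge Regularization fraction of mean diagonal (default 1e-6,
#'   raised automatically until the within matrix is invertible).
#' @return A `canonical_projection`: `directions` (bands x 2, unit norm),
#'   `scores` (n x 2), `wilks_lambda`, `labels`, `band_index` (positions
#'   used on the full grid).
#' @export
tissue_cva <- function(spectra, labels, stride = 2L, offset = NULL, ridge = 1e-6) {
  if (is.null(offset)) offset <- if (stride > 1) 1L else 0L
  X <- as.matrix(spectra)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  groups <- unique(labels)
  counts <- table(labels)
  if (length(groups) < 2 || any(counts < 2)) {
    stop("need at least 2 samples in each of 2 groups; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  idx <- subsample_index(ncol(X), stride, offset)
  Xs <- X[, idx, drop = FALSE]
  p <- ncol(Xs)
  n <- nrow(Xs)

  gm <- do.call(rbind, lapply(groups, function(g) colMeans(Xs[labels == g, , drop = FALSE])))
  overall <- colMeans(Xs)
  Wm <- matrix(0, p, p); Bm <- matrix(0, p, p)
  for (gi in seq_along(groups)) {
    rows <- Xs[labels == groups[gi], , drop = FALSE]
    cent <- sweep(rows, 2, gm[gi, ])
    Wm <- Wm + crossprod(cent)
    dmu <- gm[gi, ] - overall
    Bm <- Bm + nrow(rows) * tcrossprod(dmu)
  }

  lam <- ridge
  repeat {
    Wr <- Wm + diag(lam * sum(diag(Wm)) / p, p)
    sol <- tryCatch(solve(Wr, Bm), error = function(e) NULL)
    if (!is.null(sol)) break
    lam <- lam * 100
    if (lam > 1) stop("within-group covariance unrecoverably singular")
  }
  eg <- eigen(sol)
  ev <- Re(eg$values); V <- Re(eg$vectors)
  ord <- order(ev, decreasing = TRUE)
  ev <- ev[ord]; V <- V[, ord, drop = FALSE]
  k <- min(2L, p)
  dirs <- V[, seq_len(k), drop = FALSE]
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  if (k < 2) dirs <- cbind(dirs, 0)
  scores <- Xs %*% dirs
  wilks <- prod(1 / (1 + pmax(ev, 0)))

  structure(list(directions = dirs, scores = scores,
                 wilks_lambda = wilks, labels = labels,
                 band_index = idx, eigenvalues = ev),
            class = "canonical_projection")
}
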