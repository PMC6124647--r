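# ---- preprocessing ---------------------------------------------------------

#' Impute missing entries by column means
#'
#' Replaces every missing entry of a numeric matrix by the mean of the
#' observed values in its column; observed entries are unchanged. A
#' `design_matrix` may be passed, in which case its `X` is imputed.
#'
#' @param X Numeric matrix (or `design_matrix`) possibly containing `NA`.
#' @return Object of the same shape with no missing entries.
#' @export
impute_column_means <- function(X) {
  if (inherits(X, "design_matrix")) {
    X$X <- impute_column_means(X$X)
    return(X)
  }
  if (!any(is.na(X))) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  if (any(is.nan(mu))) {
    degenerate_error(sprintf("column '%s' is entirely missing",
                             colnames(X)[which(is.nan(mu))[1]]))
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' Centre and scale the columns of a matrix
#'
#' Autoscaling: each column is centred to mean zero and scaled to unit
#' standard deviation (denominator n - 1). Constant columns cannot be scaled;
#' they are set to all-zero, flagged, and a warning is emitted. The transform
#' is invertible through the returned parameters.
#'
#' @param M Complete numeric matrix.
#' @return List with `scaled` (matrix), `means`, `sds` (per column; constant
#'   columns keep `sd = 1` so the transform stays invertible) and `constant`
#'   (logical flags).
#' @export
autoscale <- function(M) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  sds <- apply(M, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sprintf("constant column(s) scaled to zero: %s",
                    paste(colnames(M)[const], collapse = ", ")), call. = FALSE)
    sds[const] <- 1
  }
  scaled <- sweep(sweep(M, 2, mu, "-"), 2, sds, "/")
  list(scaled = scaled, means = mu, sds = sds, constant = const)
}

# ---- NIPALS ----------------------------------------------------------------

#' Fit a PLS regression by NIPALS
#'
#' Sequential NIPALS extraction for a univariate response: after autoscaling
#' X and y, each component takes the unit-norm weight vector `w` maximising
#' the covariance of `Xw` with the current y residual (for a single response
#' the NIPALS inner iteration converges in one step, so `w` is simply the
#' normalised `X'y`), score `t = Xw`, X-loading `p = X't/(t't)` and Y-loading
#' `q = y't/(t't)`, then deflates X and y by the rank-one fit. Components are
#' oriented so that the largest-magnitude entry of each weight vector is
#' positive (component signs are otherwise arbitrary; predictions are
#' invariant). Extraction halts early when the residual X carries no further
#' variance, with the achieved number of components reported.
#'
#' Regression coefficients in standardised-predictor units are
#' `B = W (P'W)^{-1} q`; per-component fractions of (centred, scaled) X and Y
#' variance come from the deflation sums of squares.
#'
#' @param design A `design_matrix` (complete: impute first) or a numeric
#'   matrix X, in which case `y` must be supplied.
#' @param k Number of latent factors requested, `1 <= k <= min(n - 1, p)`.
#' @param y Response vector when `design` is a bare matrix.
#' @return A `pls_fit`: list with `k` (achieved), `W`, `P` (p x k), `q`
#'   (length k), `T` (n x k scores), `coef_std` (standardised coefficients at
#'   k factors), `x_var_frac`, `y_var_frac`, `center_scale` and
#'   `var_names`.
#' @export
#' @examples
#' d <- list(X = matrix(rnorm(60), 20), y = rnorm(20))
#' fit <- fit_nipals(d$X, 2, y = d$y)
#' fit$y_var_frac
fit_nipals <- function(design, k, y = NULL) {
  if (inherits(design, "design_matrix")) {
    X <- design$X; y <- design$y
  } else {
    X <- as.matrix(design)
    if (is.null(y)) schema_error("y must be supplied with a bare matrix")
  }
  if (anyNA(X) || anyNA(y)) schema_error("fit_nipals requires complete data; impute first")
  n <- nrow(X); p <- ncol(X)
  if (n < 3) degenerate_error("need n >= 3 rows")
  k <- as.integer(k)
  if (k < 1 || k > min(n - 1, p)) {
    config_error(sprintf("k must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  sx <- suppressWarnings(autoscale(X))
  sy <- autoscale(matrix(y, ncol = 1))
  if (sy$constant) degenerate_error("response is constant")

  Xa <- sx$scaled
  f <- as.numeric(sy$scaled)
  ssx_tot <- sum(Xa^2)
  ssy_tot <- sum(f^2)
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  q <- xvf <- yvf <- numeric(k)
  tol <- 1e-12
  achieved <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xa, f)
    wn <- sqrt(sum(w^2))
    if (wn < tol * max(1, ssy_tot)) break   # residual X orthogonal to y residual
    w <- w / wn
    t <- as.numeric(Xa %*% w)
    tt <- sum(t^2)
    if (tt < tol) break                      # rank exhausted
    pv <- as.numeric(crossprod(Xa, t)) / tt
    qa <- sum(f * t) / tt
    # deterministic orientation: largest-|w| entry positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t <- -t; pv <- -pv; qa <- -qa
    }
    Xa <- Xa - tcrossprod(t, pv)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    xvf[a] <- tt * sum(pv^2) / ssx_tot
    yvf[a] <- tt * qa^2 / ssy_tot
    achieved <- a
  }
  if (achieved == 0L) degenerate_error("no extractable PLS component")
  if (achieved < k) {
    warning(sprintf("rank exhausted: %d of %d components extracted",
                    achieved, k), call. = FALSE)
  }
  idx <- seq_len(achieved)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]
  q <- q[idx]; xvf <- xvf[idx]; yvf <- yvf[idx]
  coef_std <- as.numeric(W %*% solve(crossprod(P, W), q))
  vn <- colnames(X)
  if (is.null(vn)) vn <- sprintf("x%d", seq_len(p))
  structure(
    list(k = achieved, W = W, P = P, q = q, T = Tm,
         coef_std = setNames(coef_std, vn),
         x_var_frac = xvf, y_var_frac = yvf,
         center_scale = list(x_means = sx$means, x_sds = sx$sds,
                             x_constant = sx$constant,
                             y_mean = sy$means[1], y_sd = sy$sds[1]),
         var_names = vn, n = n),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d component(s), %d predictors, n = %d\n",
              x$k, length(x$var_names), x$n))
  cat(sprintf("  %% X variance: %s (total %.1f%%)\n",
              paste(sprintf("%.1f", 100 * x$x_var_frac), collapse = ", "),
              100 * sum(x$x_var_frac)))
  cat(sprintf("  %% Y variance: %s (total %.1f%%)\n",
              paste(sprintf("%.1f", 100 * x$y_var_frac), collapse = ", "),
              100 * sum(x$y_var_frac)))
  invisible(x)
}

#' Predict from a PLS fit
#'
#' Applies the stored centring/scaling, the standardised coefficient product
#' and the response back-transform. At `k = rank(X)` the in-sample
#' predictions coincide with ordinary least squares.
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix with the same predictor columns as the training X.
#' @param ... Unused.
#' @return Numeric vector of predicted responses on the raw Y scale.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  cs <- object$center_scale
  if (ncol(X) != length(cs$x_means)) {
    schema_error(sprintf("newdata has %d columns, fit expects %d",
                         ncol(X), length(cs$x_means)))
  }
  Xs <- sweep(sweep(X, 2, cs$x_means, "-"), 2, cs$x_sds, "/")
  as.numeric(cs$y_mean + cs$y_sd * (Xs %*% object$coef_std))
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ), where
#' SSY_a is the Y variance explained by component a. By construction the mean
#' of VIP^2 over predictors is exactly 1 (sum VIP_j^2 = p) for every fit; 0.8
#' is the conventional retention cut-off.
#'
#' @param fit A `pls_fit`.
#' @return Named non-negative numeric vector, one VIP per predictor.
#' @export
vip <- function(fit) {
  ssy <- fit$y_var_frac
  if (sum(ssy) <= 0) degenerate_error("fit explains zero Y variance")
  p <- nrow(fit$W)
  # W columns are unit norm, so w_ja / ||w_a|| = w_ja
  setNames(sqrt(p * as.numeric(fit$W^2 %*% ssy) / sum(ssy)), fit$var_names)
}

# ---- cross-validation ------------------------------------------------------

#' Leave-one-out PRESS curve
#'
#' For each candidate number of factors `k = 1..k_max`, the predictive
#' residual sum of squares PRESS(k) = sum_i (y_i - yhat_(-i),k)^2 on the raw
#' Y scale, with the entire model — mean imputation of missing predictor
#' entries, autoscaling, and the NIPALS extraction — re-estimated on every
#' leave-one-out training fold (no leakage). Fold-wise constant columns fall
#' under the [autoscale()] degenerate policy.
#'
#' @param design A `design_matrix`; `X` may contain missing entries, which
#'   are imputed per fold from the training rows.
#' @param k_max Largest candidate factor count, at most `min(n - 2, p)`.
#' @return A `press_curve`: list with `press` (named numeric, entries
#'   `1..k_max`) and `k_max`.
#' @seealso [choose_components()]
#' @export
loo_press <- function(design, k_max) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n < 3) degenerate_error("need n >= 3 rows")
  k_max <- as.integer(k_max)
  if (k_max < 1 || k_max > min(n - 2, p)) {
    config_error(sprintf("k_max must be in 1..min(n-2, p) = %d", min(n - 2, p)))
  }
  press <- numeric(k_max)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    mu_obs <- colMeans(Xtr, na.rm = TRUE)
    if (any(is.nan(mu_obs))) {
      degenerate_error("a column is entirely missing within a fold")
    }
    if (anyNA(Xtr)) {
      idx <- which(is.na(Xtr), arr.ind = TRUE)
      Xtr[idx] <- mu_obs[idx[, 2]]
    }
    xi <- X[i, ]
    xi[is.na(xi)] <- mu_obs[is.na(xi)]
    fit <- suppressWarnings(fit_nipals(Xtr, min(k_max, nrow(Xtr) - 1, p), y = ytr))
    yhat_k <- predict_per_k(fit, xi)
    # if the fold's rank ran out early, later k inherit the last prediction
    if (length(yhat_k) < k_max) {
      yhat_k <- c(yhat_k, rep(yhat_k[length(yhat_k)], k_max - length(yhat_k)))
    }
    press <- press + (y[i] - yhat_k[seq_len(k_max)])^2
  }
  structure(list(press = setNames(press, seq_len(k_max)), k_max = k_max),
            class = "press_curve")
}

# predictions of one row for every component count 1..fit$k
predict_per_k <- function(fit, x_new) {
  cs <- fit$center_scale
  xs <- (x_new - cs$x_means) / cs$x_sds
  out <- numeric(fit$k)
  for (kk in seq_len(fit$k)) {
    b <- fit$W[, 1:kk, drop = FALSE] %*%
      solve(crossprod(fit$P[, 1:kk, drop = FALSE], fit$W[, 1:kk, drop = FALSE]),
            fit$q[1:kk])
    out[kk] <- cs$y_mean + cs$y_sd * sum(xs * b)
  }
  out
}

#' @export
print.press_curve <- function(x, ...) {
  cat("<press_curve>\n")
  print(round(x$press, 4))
  invisible(x)
}

#' Choose the number of latent factors from a PRESS curve
#'
#' Returns the factor count minimising PRESS; ties break toward the smallest
#' k (plain-minimum rule).
#'
#' @param curve A `press_curve` (or bare named numeric of PRESS values).
#' @return Integer factor count.
#' @export
choose_components <- function(curve) {
  press <- if (inherits(curve, "press_curve")) curve$press else curve
  if (!length(press)) config_error("empty PRESS curve")
  as.integer(which.min(press))  # which.min takes the first (smallest k) on ties
}
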