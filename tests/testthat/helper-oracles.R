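# Independent oracles used across the suite. These deliberately re-derive the
# quantities along different code paths than the package (eigendecomposition
# instead of the NIPALS recursion, explicit per-fold double loops instead of
# the incremental LOO, closed-form normal equations instead of lm).

# PLS via eigendecomposition: each weight vector is the dominant eigenvector
# of M M' with M = X' y (cross-covariance), followed by the same rank-one
# deflation. Returns scores/loadings/coefficients on the autoscaled scale.
pls_eigen_oracle <- function(X, y, k) {
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  W <- P <- matrix(0, ncol(X), k)
  Tm <- matrix(0, nrow(X), k)
  q <- numeric(k)
  Xa <- Xs
  f <- ys
  for (a in seq_len(k)) {
    M <- crossprod(Xa, f)
    ev <- eigen(tcrossprod(M), symmetric = TRUE)
    w <- ev$vectors[, 1]
    t <- as.numeric(Xa %*% w)
    tt <- sum(t^2)
    p <- as.numeric(crossprod(Xa, t)) / tt
    qa <- sum(f * t) / tt
    Xa <- Xa - tcrossprod(t, p)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, T = Tm, q = q, coef = as.numeric(B))
}

# align oracle components to a fit's sign convention before comparing
align_signs <- function(ref, other) {
  for (a in seq_len(ncol(ref))) {
    if (sum(ref[, a] * other[, a]) < 0) other[, a] <- -other[, a]
  }
  other
}

# brute-force leave-one-out PRESS: a full refit per fold AND per candidate k,
# including fold-wise imputation and scaling, using plain loops
press_double_loop_oracle <- function(X, y, k_max) {
  n <- nrow(X)
  press <- numeric(k_max)
  for (k in seq_len(k_max)) {
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      ytr <- y[-i]
      mu <- colMeans(Xtr, na.rm = TRUE)
      for (j in seq_len(ncol(Xtr))) Xtr[is.na(Xtr[, j]), j] <- mu[j]
      xt <- X[i, ]
      xt[is.na(xt)] <- mu[is.na(xt)]
      cx <- colMeans(Xtr); sx <- apply(Xtr, 2, sd)
      sx[sx == 0] <- 1
      cy <- mean(ytr); sy <- sd(ytr)
      Xa <- sweep(sweep(Xtr, 2, cx), 2, sx, "/")
      f <- (ytr - cy) / sy
      W <- P <- matrix(0, ncol(X), k)
      q <- numeric(k)
      for (a in seq_len(k)) {
        w <- as.numeric(crossprod(Xa, f))
        w <- w / sqrt(sum(w^2))
        t <- as.numeric(Xa %*% w)
        tt <- sum(t^2)
        p <- as.numeric(crossprod(Xa, t)) / tt
        qa <- sum(f * t) / tt
        Xa <- Xa - tcrossprod(t, p)
        f <- f - t * qa
        W[, a] <- w; P[, a] <- p; q[a] <- qa
      }
      B <- W %*% solve(crossprod(P, W), q)
      yhat <- cy + sy * sum((xt - cx) / sx * B)
      press[k] <- press[k] + (y[i] - yhat)^2
    }
  }
  press
}

# random small regression design used by several blocks
random_design <- function(n, p, seed, missing = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta <- rnorm(p)
    y <- as.numeric(X %*% beta) + rnorm(n)
    if (missing > 0) X[sample(length(X), missing)] <- NA
    structure(list(X = X, y = y, row_ids = as.character(1:n), y_name = "y"),
              class = "design_matrix")
  })
}
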