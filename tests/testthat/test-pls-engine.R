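test_that("mean imputation fills exactly the missing cells", {
  X <- matrix(c(1, NA, 3, 4, 5, 6), ncol = 2)
  out <- impute_column_means(X)
  expect_equal(out[2, 1], 2)
  expect_equal(out[, 2], c(4, 5, 6))

  # complete matrix unchanged
  M <- matrix(rnorm(20), 5)
  expect_identical(impute_column_means(M), M)

  # imputation preserves the observed-value column means
  withr::with_seed(4, {
    Z <- matrix(rnorm(300), 30)
    obs_means <- colMeans(Z)
    Z[sample(length(Z), 90)] <- NA
    obs_means <- colMeans(Z, na.rm = TRUE)
    expect_equal(colMeans(impute_column_means(Z)), obs_means, tolerance = 1e-12)
  })

  expect_error(impute_column_means(matrix(c(NA, NA, 1, 2), ncol = 2)),
               class = "crpls_degenerate_error")
})

test_that("autoscale centres, scales and flags constant columns", {
  out <- autoscale(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.numeric(out$scaled), c(-1, 0, 1))
  expect_equal(out$means, 4, ignore_attr = TRUE)
  expect_equal(out$sds, 2, ignore_attr = TRUE)

  # idempotent on already-standardised input
  z <- as.numeric(scale(rnorm(20)))
  out2 <- autoscale(matrix(z, ncol = 1))
  expect_equal(as.numeric(out2$scaled), z, tolerance = 1e-12)

  expect_warning(out3 <- autoscale(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_true(out3$constant[["a"]])
  expect_equal(out3$scaled[, "a"], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("NIPALS recovers exact one-component structure", {
  # orthogonal, centred X with y equal to the first column (columns stay
  # orthogonal after autoscaling because each has mean 0 and equal norm)
  withr::with_seed(5, {
    Q <- qr.Q(qr(scale(matrix(rnorm(100), 20, 5), scale = FALSE)))
    colnames(Q) <- paste0("q", 1:5)
    y <- Q[, 1]
    fit <- fit_nipals(Q, 1, y = y)
    w <- fit$W[, 1]
    expect_equal(abs(w[1]), max(abs(w)))
    expect_gt(abs(w[1]), 0.99)
    expect_equal(fit$y_var_frac, 1, tolerance = 1e-8)
  })
})

test_that("NIPALS matches the eigendecomposition oracle on random instances", {
  for (i in 1:25) {
    n <- sample(8:30, 1)
    p <- sample(2:10, 1)
    d <- random_design(n, p, seed = 1000 + i)
    k <- sample(1:min(3, p), 1)
    fit <- fit_nipals(d, k)
    ora <- pls_eigen_oracle(d$X, d$y, k)
    W_o <- align_signs(fit$W, ora$W)
    P_o <- ora$P; T_o <- ora$T; q_o <- ora$q
    flip <- colSums(fit$W * ora$W) < 0
    P_o[, flip] <- -P_o[, flip]; T_o[, flip] <- -T_o[, flip]
    q_o[flip] <- -q_o[flip]
    expect_equal(fit$W, W_o, ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(fit$P, P_o, ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(fit$T, T_o, ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(fit$q, q_o, ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(unname(fit$coef_std), ora$coef, tolerance = 1e-8)
  }
})

test_that("PLS at full rank reproduces ordinary least squares", {
  for (i in 1:10) {
    n <- sample(12:30, 1)
    p <- sample(2:6, 1)
    d <- random_design(n, p, seed = 2000 + i)
    fit <- fit_nipals(d, p)
    ols <- lm(d$y ~ d$X)
    expect_equal(predict(fit, d$X), unname(fitted(ols)), tolerance = 1e-8)
  }
})

test_that("prediction honours centring and generalises a noiseless system", {
  d <- random_design(25, 4, seed = 31)
  fit <- fit_nipals(d, 2)
  mu_row <- matrix(colMeans(d$X), 1)
  expect_equal(predict(fit, mu_row), mean(d$y), tolerance = 1e-10)

  # noiseless linear response: held-out predictions exact at full rank
  withr::with_seed(32, {
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, letters[1:3]))
    y <- as.numeric(X %*% c(1, -2, 0.5))
    fit2 <- fit_nipals(X[1:30, ], 3, y = y[1:30])
    expect_equal(predict(fit2, X[31:40, ]), y[31:40], tolerance = 1e-8)
  })

  expect_error(predict(fit, matrix(0, 1, 7)), class = "crpls_schema_error")
})

test_that("score orthogonality and variance accounting hold on random fits", {
  for (i in 1:10) {
    d <- random_design(sample(10:25, 1), sample(3:8, 1), seed = 3000 + i)
    k <- min(3, ncol(d$X))
    fit <- suppressWarnings(fit_nipals(d, k))
    G <- crossprod(fit$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_lte(sum(fit$x_var_frac), 1 + 1e-8)
    expect_lte(sum(fit$y_var_frac), 1 + 1e-8)
    expect_true(all(fit$x_var_frac >= 0 & fit$y_var_frac >= 0))
    expect_true(all(diff(cumsum(fit$y_var_frac)) >= -1e-12))
  }
})

test_that("VIP follows its formula and normalisation", {
  # p = 1: forced to 1
  d1 <- random_design(15, 1, seed = 41)
  expect_equal(unname(vip(fit_nipals(d1, 1))), 1, tolerance = 1e-10)

  # two exchangeable predictors symmetric in y
  withr::with_seed(42, {
    f <- rnorm(60)
    X <- cbind(a = f + rnorm(60, 0, 1e-8), b = f + rnorm(60, 0, 1e-8))
    y <- f + rnorm(60, 0, 0.2)
    v <- vip(fit_nipals(X, 1, y = y))
    expect_equal(unname(v), c(1, 1), tolerance = 1e-3)
  })

  # direct evaluation of the formula from an independently fitted model
  d <- random_design(8, 4, seed = 43)
  fit <- fit_nipals(d, 2)
  ora <- pls_eigen_oracle(d$X, d$y, 2)
  ys <- as.numeric(scale(d$y))
  ssy <- vapply(1:2, function(a) {
    sum(ora$T[, a] * ys)^2 / sum(ora$T[, a]^2)
  }, numeric(1))
  wn <- sweep(ora$W, 2, sqrt(colSums(ora$W^2)), "/")
  vip_direct <- sqrt(4 * as.numeric(wn^2 %*% ssy) / sum(ssy))
  expect_equal(unname(vip(fit)), vip_direct, tolerance = 1e-8)

  # sum of squared VIP equals p for every fit
  for (i in 1:6) {
    di <- random_design(sample(10:30, 1), sample(2:9, 1), seed = 4000 + i)
    fi <- suppressWarnings(fit_nipals(di, min(3, ncol(di$X))))
    expect_equal(sum(vip(fi)^2), ncol(di$X), tolerance = 1e-10)
  }
})

test_that("leave-one-out PRESS equals the brute-force double loop", {
  for (i in 1:3) {
    n <- sample(12:40, 1)
    p <- sample(3:6, 1)
    d <- random_design(n, p, seed = 5000 + i, missing = round(0.05 * n * p))
    k_max <- min(3, p)
    curve <- loo_press(d, k_max)
    oracle <- press_double_loop_oracle(d$X, d$y, k_max)
    expect_equal(unname(curve$press), oracle, tolerance = 1e-10)
  }
})

test_that("PRESS behaviour at the noiseless and null extremes", {
  # noiseless response on two informative predictors: PRESS ~ 0 at k = 2
  withr::with_seed(51, {
    X <- matrix(rnorm(30 * 2), 30, 2)
    y <- as.numeric(X[, 1] - 2 * X[, 2])
    d <- structure(list(X = X, y = y), class = "design_matrix")
    curve <- loo_press(d, 2)
    ssy <- sum((y - mean(y))^2)
    expect_lt(curve$press[[2]] / ssy, 1e-10)
    expect_gt(curve$press[[1]], 1e3 * curve$press[[2]])
  })

  # y permuted against X: no k predicts, PRESS stays near total SS
  ratios <- withr::with_seed(52, {
    replicate(5, {
      X <- matrix(rnorm(25 * 4), 25, 4)
      y <- rnorm(25)
      d <- structure(list(X = X, y = y[sample(25)]), class = "design_matrix")
      min(loo_press(d, 3)$press) / sum((y - mean(y))^2)
    })
  })
  expect_gt(mean(ratios), 0.9)
})

test_that("factor-count choice minimises PRESS with smallest-k tie-break", {
  expect_equal(choose_components(c(`1` = 5, `2` = 3, `3` = 4)), 2L)
  expect_equal(choose_components(c(`1` = 5, `2` = 5)), 1L)
  expect_error(choose_components(numeric(0)), class = "crpls_config_error")
})

test_that("rank exhaustion halts extraction with the achieved k", {
  withr::with_seed(61, {
    X <- matrix(rnorm(20 * 2), 20, 2)
    X <- cbind(X, X[, 1] + X[, 2])  # rank 2
    y <- rnorm(20)
    expect_warning(fit <- fit_nipals(X, 3, y = y), "rank exhausted")
    expect_equal(fit$k, 2)
  })
})
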