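test_that("moment skewness follows the population-moment convention", {
  expect_equal(moment_skewness(c(-1, 0, 1)), 0)
  expect_equal(moment_skewness(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12)
  expect_error(moment_skewness(c(1, 2)), class = "crpls_degenerate_error")
  expect_error(moment_skewness(rep(3, 10)), class = "crpls_degenerate_error")

  skip_if_not_installed("e1071")
  withr::with_seed(42, {
    for (i in 1:5) {
      x <- rlnorm(50)
      expect_equal(moment_skewness(x), e1071::skewness(x, type = 1),
                   tolerance = 1e-12)
    }
  })
})

test_that("BMI residualisation matches closed-form least squares", {
  # exact power law: perfect fit, zero residuals
  bmi <- c(20, 22, 25, 28, 32)
  expect_equal(bmi_correct(bmi^1.7, bmi), rep(0, 5), tolerance = 1e-10)

  # worked 5-point set against the normal equations
  crp <- c(1, 1, 2, 3, 8)
  x <- log10(bmi); y <- log10(crp)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(bmi_correct(crp, bmi),
               y - (mean(y) - beta * mean(x)) - beta * x, tolerance = 1e-10)

  # residuals: zero mean, zero covariance with the regressor; NA alignment
  withr::with_seed(11, {
    bmi2 <- runif(40, 19, 35)
    crp2 <- rlnorm(40)
    bmi2[c(3, 17)] <- NA
    r <- bmi_correct(crp2, bmi2)
    expect_true(all(is.na(r[c(3, 17)])))
    ok <- !is.na(r)
    expect_lt(abs(mean(r[ok])), 1e-10)
    expect_lt(abs(sum(r[ok] * (log10(bmi2[ok]) - mean(log10(bmi2[ok]))))), 1e-10)
  })
  expect_error(bmi_correct(c(1, 2, 3), c(25, 25, 25)),
               class = "crpls_degenerate_error")
})

test_that("Cohen's d is the pooled-SD standardised difference", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 1, 2), c(1, 2, 3)), -1)
  expect_equal(cohens_d(c(1, 2, 3), c(0, 1, 2)), 1)
  withr::with_seed(9, {
    a <- rnorm(20); b <- rnorm(15)
    expect_equal(cohens_d(a, b), -cohens_d(b, a))  # antisymmetry
  })
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "crpls_degenerate_error")
})

test_that("rank-sum test: exact small-sample branch and tie-corrected Z", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  # identical multisets: Z = 0, p = 1
  r0 <- rank_sum_test(c(5, 6, 7, 8, 9, 10), c(5, 6, 7, 8, 9, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # large-sample Z^2 agrees with the tie-corrected kruskal-wallis chi-square
  # on two groups (independent implementation of the same statistic)
  withr::with_seed(21, {
    a <- sample(0:5, 40, replace = TRUE)
    b <- sample(1:6, 35, replace = TRUE)
    r1 <- rank_sum_test(a, b)
    kw <- kruskal.test(c(a, b), factor(rep(1:2, c(40, 35))))
    expect_equal(r1$statistic^2, unname(kw$statistic), tolerance = 1e-10)
  })

  # invariance under strictly monotone transforms of the pooled data
  withr::with_seed(22, {
    a <- rnorm(25); b <- rnorm(30, 0.5)
    r_raw <- rank_sum_test(a, b)
    r_tr <- rank_sum_test(exp(a), exp(b))
    expect_equal(r_raw$statistic, r_tr$statistic)
    expect_equal(r_raw$p_value, r_tr$p_value)
  })
  expect_error(rank_sum_test(c(1, 1), c(1, 1, 1)),
               class = "crpls_degenerate_error")
})

test_that("rank-sum power under a one-SD shift is high", {
  # Monte-Carlo check of the normal-approximation branch
  rej <- withr::with_seed(31, {
    mean(replicate(300, {
      rank_sum_test(rnorm(50), rnorm(50, 1))$p_value < 0.05
    }))
  })
  expect_gt(rej, 0.9)
})

test_that("one-way ANOVA matches the textbook sums-of-squares decomposition", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  dgn <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_equal(dgn$statistic, Inf)
  expect_equal(dgn$p_value, 0)
  expect_match(dgn$note, "degenerate")

  withr::with_seed(13, {
    groups <- lapply(c(8, 12, 9, 11), function(n) rnorm(n, rnorm(1)))
    res <- one_way_anova(groups)
    y <- unlist(groups); N <- length(y); k <- length(groups)
    gm <- mean(y)
    ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - gm)^2)
    ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
    f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
    expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
    expect_equal(res$df1, k - 1)
    expect_equal(res$df2, N - k)
    expect_equal(res$p_value, pf(f_oracle, k - 1, N - k, lower.tail = FALSE),
                 tolerance = 1e-12)
  })
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))),
               class = "crpls_degenerate_error")
})

test_that("Kruskal-Wallis H matches hand computation", {
  expect_equal(kruskal_wallis_test(list(c(1, 4), c(2, 3)))$statistic, 0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis_test(list(c(1, 2), c(3, 4)))$statistic, 2.4,
               tolerance = 1e-12)
  same <- kruskal_wallis_test(list(c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("likelihood-ratio G-test on the elevated-CRP threshold", {
  # balanced 2x2: no association
  crp <- rep(c(4, 1, 4, 1), times = c(10, 10, 10, 10))
  grp <- rep(c("a", "b"), each = 20)
  bal <- lr_chisq_threshold(crp, grp)
  expect_equal(bal$statistic, 0, tolerance = 1e-12)
  expect_equal(bal$p_value, 1)

  # [[15,5],[5,15]] table: G^2 = 2*(30 ln 1.5 + 10 ln 0.5) ~ 10.465
  crp2 <- c(rep(4, 15), rep(1, 5), rep(4, 5), rep(1, 15))
  grp2 <- rep(c("a", "b"), each = 20)
  r2 <- lr_chisq_threshold(crp2, grp2)
  expect_equal(r2$statistic, 2 * (30 * log(1.5) + 10 * log(0.5)),
               tolerance = 1e-10)
  expect_equal(r2$df1, 1)

  # all below threshold: degenerate, flagged
  dg <- lr_chisq_threshold(rep(1, 30), rep(c("a", "b", "c"), 10))
  expect_equal(dg$statistic, 0)
  expect_match(dg$note, "degenerate")

  # strict inequality at the boundary: 3 is not elevated
  r3 <- lr_chisq_threshold(c(3, 3, 3.01, 3.01), c("a", "a", "b", "b"))
  expect_gt(r3$statistic, 0)
})

test_that("Spearman correlation uses midranks and the t approximation", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  r <- spearman_rho(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "crpls_degenerate_error")
})

test_that("post hoc LSD t-tests agree with emmeans pairwise contrasts", {
  skip_if_not_installed("emmeans")
  withr::with_seed(17, {
    groups <- lapply(c(10, 14, 9), function(n) rnorm(n, rnorm(1)))
    res <- crpls:::lsd_t_test(groups, 1, 3, "g1 vs g3", "test")
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    em <- emmeans::emmeans(lm(y ~ g), ~g)
    ctr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
    row <- ctr[ctr$contrast == "g1 - g3", ]
    expect_equal(res$statistic, row$t.ratio, tolerance = 1e-8)
    expect_equal(res$p_value, row$p.value, tolerance = 1e-8)
    expect_equal(res$df1, row$df)
  })
})

test_that("the full battery reproduces the design's df arithmetic and gating", {
  co <- generate_cohort(cohort_config(seed = 7))
  ct <- run_group_contrasts(co)
  expect_s3_class(ct, "contrast_table")
  expect_identical(attr(ct, "multiplicity_correction"), "none")

  # pooled t on log10 CRP: 252 complete, df = 250
  row_log <- ct[ct$family == "log10_crp" & ct$comparison == "MDD vs healthy", ]
  expect_equal(row_log$df1, 250)

  # BMI-corrected analyses drop the 12 missing-BMI rows: pooled df = 238,
  # LSD pairwise df = 240 - 4 = 236
  row_bc <- ct[ct$family == "bmi_corrected_crp" &
                 ct$comparison == "MDD vs healthy", ]
  expect_equal(row_bc$df1, 238)
  expect_false(is.na(row_bc$effect_size_d))
  pair_bc <- ct[ct$family == "bmi_corrected_crp" &
                  ct$comparison == "resistant vs healthy", ]
  if (nrow(pair_bc)) expect_equal(pair_bc$df1, 236)

  # log10 pairwise LSD df = 252 - 4 = 248 (gated on a significant omnibus)
  pair_log <- ct[ct$family == "log10_crp" & grepl(" vs ", ct$comparison) &
                   ct$comparison != "MDD vs healthy", ]
  if (nrow(pair_log)) expect_true(all(pair_log$df1 == 248))

  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))

  # ungated battery always contains the 6 pairwise contrasts per family
  ct_all <- run_group_contrasts(co, gate_posthoc = FALSE)
  expect_gte(nrow(ct_all), nrow(ct))
  expect_equal(sum(ct_all$family == "raw_crp"), 1 + 1 + 6)
})

test_that("planted cohorts rank the resistant group's effect size first", {
  biggest <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(seed = 100 + s))
    bc <- bmi_correct(co$crp, co$bmi)
    d <- sapply(c("resistant", "responsive", "untreated"), function(g) {
      cohens_d(bc[co$group == g], bc[co$group == "healthy"])
    })
    names(which.max(d))
  })
  expect_gte(mean(biggest == "resistant"), 0.8)
})

test_that("single-group cohorts are rejected", {
  co <- generate_cohort(small_config(seed = 4))
  expect_error(run_group_contrasts(co[co$group == "healthy", ]),
               class = "crpls_schema_error")
})
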