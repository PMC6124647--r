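# ---- elementary statistics -------------------------------------------------

#' Moment skewness (g1)
#'
#' Sample skewness in the population-moment convention,
#' g1 = m3 / m2^(3/2) with central sample moments mk = mean((x - mean(x))^k).
#'
#' @param values Numeric vector; missing values are dropped.
#' @return Dimensionless skewness.
#' @export
#' @examples
#' moment_skewness(c(0, 0, 0, 1))  # 2/sqrt(3)
moment_skewness <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3) degenerate_error("moment skewness needs >= 3 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) degenerate_error("moment skewness undefined for zero variance")
  mean((x - m)^3) / m2^1.5
}

#' BMI-corrected CRP
#'
#' Regresses log10 CRP on log10 BMI by ordinary least squares over the
#' complete pairs and returns the residuals — the BMI-corrected CRP estimates
#' — aligned to the input order, with `NA` wherever either input is missing.
#' The residuals have mean zero and zero sample covariance with log10 BMI.
#'
#' @param crp CRP series, mg/L (> 0).
#' @param bmi BMI series, kg/m^2 (> 0), same length.
#' @return Numeric residual series of the same length as the inputs.
#' @export
bmi_correct <- function(crp, bmi) {
  if (length(crp) != length(bmi)) schema_error("crp and bmi must be paired")
  ok <- !is.na(crp) & !is.na(bmi)
  if (any(crp[ok] <= 0) || any(bmi[ok] <= 0)) {
    schema_error("crp and bmi must be strictly positive")
  }
  if (sum(ok) < 3) degenerate_error("need >= 3 complete (crp, bmi) pairs")
  lx <- log10(bmi[ok])
  if (var(lx) == 0) degenerate_error("BMI is constant: regression degenerate")
  fit <- lm(log10(crp[ok]) ~ lx)
  out <- rep(NA_real_, length(crp))
  out[ok] <- stats::residuals(fit)
  out
}

#' Cohen's d
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled`, with the
#' pooled SD `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric series (missing values dropped), each with >= 2 values.
#' @return Dimensionless effect size; antisymmetric in its arguments.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    degenerate_error("cohens_d needs >= 2 values per series")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) degenerate_error("zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

# ---- contrast result container ---------------------------------------------

contrast_result <- function(comparison, family, statistic_name, statistic,
                            df1 = NA_real_, df2 = NA_real_, p_value,
                            effect_size_d = NA_real_, n1 = NA_integer_,
                            n2 = NA_integer_, u = NA_real_, note = NA_character_) {
  structure(
    list(comparison = comparison, family = family,
         statistic_name = statistic_name, statistic = statistic,
         df1 = df1, df2 = df2, p_value = p_value,
         effect_size_d = effect_size_d, n1 = n1, n2 = n2, u = u, note = note),
    class = "contrast_result"
  )
}

#' @export
as.data.frame.contrast_result <- function(x, ...) {
  data.frame(comparison = x$comparison, family = x$family,
             statistic_name = x$statistic_name, statistic = x$statistic,
             df1 = x$df1, df2 = x$df2, p_value = x$p_value,
             effect_size_d = x$effect_size_d, n1 = x$n1, n2 = x$n2,
             note = x$note, stringsAsFactors = FALSE)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %s = %.4g", x$comparison, x$family,
              x$statistic_name, x$statistic))
  if (!is.na(x$df1)) {
    cat(sprintf(", d.f. = %s", paste(stats::na.omit(c(x$df1, x$df2)),
                                     collapse = ", ")))
  }
  cat(sprintf(", P = %.4g", x$p_value))
  if (!is.na(x$effect_size_d)) cat(sprintf(", d = %.3f", x$effect_size_d))
  if (!is.na(x$note)) cat(sprintf("  (%s)", x$note))
  cat("\n")
  invisible(x)
}

# ---- two-sample and k-sample tests -----------------------------------------

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The reported statistic is
#' the Z of the normal approximation with tie-corrected variance and no
#' continuity correction; when the pooled sample size is at most 10 and there
#' are no ties the p-value comes from exact enumeration instead (the Z is
#' still reported for reference). The test is invariant under strictly
#' monotone transforms of the pooled data.
#'
#' @param a,b Numeric series (missing values dropped).
#' @param comparison,family Labels stored in the result.
#' @return A `contrast_result` with `statistic_name = "Wilcoxon_Z"`; the
#'   Mann-Whitney U of the first sample is carried in field `u`.
#' @export
rank_sum_test <- function(a, b, comparison = "a vs b", family = "raw_crp") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 1 || n2 < 1) degenerate_error("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) degenerate_error("all pooled values are tied")
  z <- (u - n1 * n2 / 2) / sqrt(v)
  if (n <= 10 && tie_term == 0) {
    p <- wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  contrast_result(comparison, family, "Wilcoxon_Z", z, p_value = min(p, 1),
                  n1 = n1, n2 = n2, u = u)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA, F = MS_between / MS_within with
#' (k - 1, N - k) degrees of freedom, computed via `stats::anova` on a linear
#' model fit. A zero within-group variance with non-zero between-group
#' variance is reported as F = Inf, p = 0 with a `degenerate` note.
#'
#' @param groups List of numeric series, one per group (>= 2 groups, each with
#'   >= 2 values after dropping missings).
#' @param comparison,family Labels stored in the result.
#' @return A `contrast_result` with `statistic_name = "F"`; the within-group
#'   mean square and group means are attached as attribute `"fit"`.
#' @export
one_way_anova <- function(groups, comparison = "omnibus", family = "") {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    degenerate_error("one_way_anova needs >= 2 groups with >= 2 values each")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- suppressWarnings(anova(lm(y ~ g)))
  msw <- a$`Mean Sq`[2]
  msb <- a$`Mean Sq`[1]
  note <- NA_character_
  # a numerically-zero within-group mean square is a perfect fit
  if (msw <= 1e-12 * msb) {
    if (msb <= 1e-300) degenerate_error("zero within- and between-group variance")
    f <- Inf; p <- 0; note <- "degenerate: zero within-group variance"
  } else {
    f <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
  }
  res <- contrast_result(comparison, family, "F", f,
                         df1 = a$Df[1], df2 = a$Df[2], p_value = p,
                         n1 = length(y), note = note)
  attr(res, "fit") <- list(ms_within = msw, df_within = a$Df[2],
                           means = vapply(groups, mean, numeric(1)),
                           sizes = lengths(groups))
  res
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1 degrees of
#' freedom, via `stats::kruskal.test`.
#'
#' @inheritParams one_way_anova
#' @return A `contrast_result` with `statistic_name = "Kruskal_H"`.
#' @export
kruskal_wallis_test <- function(groups, comparison = "omnibus", family = "") {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2 || any(lengths(groups) < 1)) {
    degenerate_error("kruskal_wallis_test needs >= 2 non-empty groups")
  }
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1) {
    # all observations identical: mean ranks trivially equal
    return(contrast_result(comparison, family, "Kruskal_H", 0,
                           df1 = length(groups) - 1, p_value = 1,
                           n1 = length(y), note = "degenerate: all values tied"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- kruskal.test(y, g)
  contrast_result(comparison, family, "Kruskal_H",
                  unname(k$statistic), df1 = unname(k$parameter),
                  p_value = k$p.value, n1 = length(y))
}

#' Likelihood-ratio G-test of a clinically elevated CRP threshold
#'
#' Dichotomises CRP at a strict `> threshold` (default 3 mg/L, the
#' conventional clinically elevated cut-off), tabulates elevated status
#' against group and computes the likelihood-ratio statistic
#' G^2 = 2 sum O log(O/E) over non-zero cells, referred to chi-squared with
#' k - 1 degrees of freedom. A degenerate table (all participants on one side
#' of the threshold) yields G^2 = 0 with a note.
#'
#' @param crp CRP series, mg/L.
#' @param groups Group labels, same length as `crp`.
#' @param threshold Positive threshold, mg/L.
#' @param comparison Label stored in the result.
#' @return A `contrast_result` with `statistic_name = "LR_chisq"`.
#' @export
lr_chisq_threshold <- function(crp, groups, threshold = 3,
                               comparison = "omnibus") {
  if (threshold <= 0) config_error("threshold must be > 0")
  ok <- !is.na(crp) & !is.na(groups)
  crp <- crp[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) degenerate_error("need >= 2 groups")
  if (any(table(groups) == 0)) degenerate_error("a group has zero members")
  tab <- table(elevated = crp > threshold, group = groups)
  df <- nlevels(groups) - 1
  note <- NA_character_
  if (nrow(tab) < 2) {
    g2 <- 0; p <- 1
    note <- "degenerate: all participants on one side of the threshold"
  } else {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    g2 <- 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
    g2 <- max(g2, 0)
    p <- pchisq(g2, df, lower.tail = FALSE)
  }
  contrast_result(comparison, "elevated_crp", "LR_chisq", g2, df1 = df,
                  p_value = p, n1 = length(crp), note = note)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' asymptotic t approximation on n - 2 degrees of freedom
#' (via `stats::cor.test`).
#'
#' @param x,y Paired numeric series; incomplete pairs are dropped.
#' @return List with `rho`, `df` (n - 2) and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) degenerate_error("need >= 3 complete pairs")
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    degenerate_error("constant series: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), df = sum(ok) - 2, p_value = ct$p.value)
}

# Student's pooled two-sample t-test (equal variances), df = n1 + n2 - 2
pooled_t_test <- function(a, b, comparison, family, with_d = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- t.test(a, b, var.equal = TRUE)
  contrast_result(comparison, family, "t", unname(tt$statistic),
                  df1 = unname(tt$parameter), p_value = tt$p.value,
                  effect_size_d = if (with_d) cohens_d(a, b) else NA_real_,
                  n1 = length(a), n2 = length(b))
}

# Fisher-LSD style post hoc t-test between groups i and j, using the pooled
# within-group mean square from the omnibus ANOVA over ALL groups, so the
# degrees of freedom are N - k (e.g. 248 for pairwise contrasts among 252
# participants in 4 groups)
lsd_t_test <- function(groups, i, j, comparison, family, with_d = FALSE) {
  omni <- one_way_anova(groups, family = family)
  fit <- attr(omni, "fit")
  if (fit$ms_within == 0) degenerate_error("zero within-group variance")
  se <- sqrt(fit$ms_within * (1 / fit$sizes[i] + 1 / fit$sizes[j]))
  t <- (fit$means[i] - fit$means[j]) / se
  contrast_result(comparison, family, "t", unname(t),
                  df1 = fit$df_within, p_value = 2 * pt(-abs(t), fit$df_within),
                  effect_size_d = if (with_d) cohens_d(groups[[i]], groups[[j]])
                                  else NA_real_,
                  n1 = fit$sizes[[i]], n2 = fit$sizes[[j]])
}

# ---- the planned battery ---------------------------------------------------

#' Run the planned between-group CRP contrast battery
#'
#' Emits, in a documented fixed order, the planned analyses of a four-group
#' cohort: (1) pooled-MDD vs healthy and pairwise rank-sum tests on raw CRP
#' (pairwise gated on the Kruskal-Wallis omnibus); (2) Student's t-tests on
#' log10 CRP — pooled MDD vs healthy, the one-way ANOVA omnibus, and Fisher-LSD
#' pairwise t-tests (pooled residual variance, df = N - k) gated on the
#' omnibus; (3) the same battery on BMI-corrected CRP (complete-BMI cases
#' only, hence the reduced degrees of freedom) with Cohen's d attached; and
#' (4) likelihood-ratio G-tests of the proportion with CRP above `threshold`
#' mg/L: the 2 x 4 omnibus, pooled MDD vs healthy, and each patient group vs
#' healthy gated on the omnibus. Post hoc contrasts are only reported when
#' the corresponding omnibus test is significant at `alpha`, mirroring the
#' usual gating rule; no multiplicity correction is applied (recorded in the
#' table's metadata).
#'
#' @param cohort Cohort data frame with at least two groups including
#'   `healthy`.
#' @param alpha Gating level for post hoc contrasts.
#' @param gate_posthoc If `FALSE`, pairwise contrasts are emitted regardless
#'   of the omnibus outcome (useful for calibration studies).
#' @param threshold Clinically elevated CRP cut-off, mg/L.
#' @return A `contrast_table`: data frame of results with one row per test
#'   and attributes `alpha`, `gated`, `threshold` and
#'   `multiplicity_correction = "none"`.
#' @export
run_group_contrasts <- function(cohort, alpha = 0.05, gate_posthoc = TRUE,
                                threshold = 3) {
  g <- factor(cohort$group, levels = group_levels())
  present <- levels(g)[table(g) > 0]
  if (length(present) < 2 || !"healthy" %in% present) {
    schema_error("cohort must contain >= 2 groups including 'healthy'")
  }
  crp <- cohort$crp
  split_by <- function(v) split(v, g)[present]
  is_mdd <- g != "healthy"
  pairs <- utils::combn(present, 2, simplify = FALSE)
  rows <- list()
  add <- function(res) rows[[length(rows) + 1]] <<- as.data.frame(res)

  # (1) raw CRP, rank-based
  add(rank_sum_test(crp[is_mdd], crp[!is_mdd], "MDD vs healthy", "raw_crp"))
  kw <- kruskal_wallis_test(split_by(crp), family = "raw_crp")
  add(kw)
  if (!gate_posthoc || kw$p_value < alpha) {
    for (pr in pairs) {
      add(rank_sum_test(crp[g == pr[1]], crp[g == pr[2]],
                        sprintf("%s vs %s", pr[1], pr[2]), "raw_crp"))
    }
  }

  # (2) log10 CRP, Student's t
  lc <- log10(crp)
  add(pooled_t_test(lc[is_mdd], lc[!is_mdd], "MDD vs healthy", "log10_crp"))
  omni_l <- one_way_anova(split_by(lc), family = "log10_crp")
  add(omni_l)
  if (!gate_posthoc || omni_l$p_value < alpha) {
    for (pr in pairs) {
      add(lsd_t_test(split_by(lc), match(pr[1], present), match(pr[2], present),
                     sprintf("%s vs %s", pr[1], pr[2]), "log10_crp"))
    }
  }

  # (3) BMI-corrected CRP (complete-BMI cases), with Cohen's d
  bc <- bmi_correct(crp, cohort$bmi)
  add(pooled_t_test(bc[is_mdd], bc[!is_mdd], "MDD vs healthy",
                    "bmi_corrected_crp", with_d = TRUE))
  omni_b <- one_way_anova(split_by(bc), family = "bmi_corrected_crp")
  add(omni_b)
  if (!gate_posthoc || omni_b$p_value < alpha) {
    for (pr in pairs) {
      add(lsd_t_test(split_by(bc), match(pr[1], present), match(pr[2], present),
                     sprintf("%s vs %s", pr[1], pr[2]), "bmi_corrected_crp",
                     with_d = TRUE))
    }
  }

  # (4) clinically elevated CRP (> threshold mg/L), likelihood-ratio G-tests
  omni_e <- lr_chisq_threshold(crp, g, threshold)
  add(omni_e)
  add(lr_chisq_threshold(crp, ifelse(is_mdd, "MDD", "healthy"), threshold,
                         comparison = "MDD vs healthy"))
  if (!gate_posthoc || omni_e$p_value < alpha) {
    for (grp in setdiff(present, "healthy")) {
      keep <- g %in% c(grp, "healthy")
      add(lr_chisq_threshold(crp[keep], droplevels(g[keep]), threshold,
                             comparison = sprintf("%s vs healthy", grp)))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = alpha, gated = gate_posthoc, threshold = threshold,
            multiplicity_correction = "none",
            class = c("contrast_table", "data.frame"))
}
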