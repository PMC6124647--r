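# ---- step 1: VIP / coefficient screen --------------------------------------

#' Screen predictors by VIP and standardised coefficient
#'
#' Step one of the two-step variable-selection procedure: a predictor is
#' discarded only when it is unimportant by both conventional criteria —
#' VIP below `vip_cut` AND absolute standardised coefficient below
#' `coef_cut` — and retained otherwise (the conjunction used by the usual
#' variable-reduction heuristic; set `rule = "or"` to discard when either
#' criterion fails). Deterministic given the fit.
#'
#' @param fit A `pls_fit` over the full predictor set.
#' @param vip_cut VIP retention threshold (default 0.8).
#' @param coef_cut Standardised-coefficient magnitude threshold (default 0.05).
#' @param rule `"and"` (default) or `"or"` discard rule.
#' @return A `screening_result`: list with `retained` (ordered predictor
#'   names), `discarded`, `vip`, `coef_std` and `thresholds`.
#' @export
screen_variables <- function(fit, vip_cut = 0.8, coef_cut = 0.05,
                             rule = c("and", "or")) {
  rule <- match.arg(rule)
  v <- vip(fit)
  b <- fit$coef_std
  low_vip <- v < vip_cut
  low_coef <- abs(b) < coef_cut
  drop <- if (rule == "and") low_vip & low_coef else low_vip | low_coef
  structure(
    list(retained = fit$var_names[!drop], discarded = fit$var_names[drop],
         vip = v, coef_std = b,
         thresholds = list(vip_cut = vip_cut, coef_cut = coef_cut, rule = rule)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d retained / %d discarded (VIP < %g AND |coef| < %g)\n",
              length(x$retained), length(x$discarded),
              x$thresholds$vip_cut, x$thresholds$coef_cut))
  invisible(x)
}

# restrict a design matrix to named predictor columns
subset_design <- function(design, vars) {
  design$X <- design$X[, vars, drop = FALSE]
  design
}

# ---- step 2: bootstrap coefficient CIs -------------------------------------

#' Bootstrap percentile confidence intervals for standardised coefficients
#'
#' Step two of the selection procedure: rows (paired X, y) are resampled with
#' replacement `n_boot` times; each replicate is refit by NIPALS at the fixed
#' factor count `k` and its standardised coefficients recorded, after
#' aligning component signs to the point-estimate fit (the coefficients
#' themselves are invariant to component orientation, so the alignment
#' matters only for the attached weight summaries). Percentile intervals at
#' `level` are formed per predictor; predictors whose interval includes zero
#' are flagged for exclusion. Replicates whose rank collapses below `k` are
#' skipped and counted; more than 10% skips is an error.
#'
#' @param design A complete `design_matrix` (typically restricted to the
#'   screened predictors).
#' @param k Fixed number of latent factors.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; results are deterministic given it.
#' @return A `bootstrap_ci_result`: list with `lower`, `upper`, `estimate`
#'   (named per predictor), `excluded` (names whose CI includes zero),
#'   `n_boot`, `n_skipped`, `level` and `seed`.
#' @export
bootstrap_coefficient_cis <- function(design, k, n_boot = 1000, level = 0.95,
                                      seed = 1L) {
  fit0 <- suppressWarnings(fit_nipals(design, k))
  if (fit0$k < k) {
    degenerate_error("point-estimate fit does not support k components")
  }
  n <- nrow(design$X)
  alpha <- (1 - level) / 2
  coefs <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_boot, ncol(design$X))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_b <- tryCatch(
        suppressWarnings(fit_nipals(design$X[idx, , drop = FALSE], k,
                                    y = design$y[idx])),
        error = function(e) NULL
      )
      if (is.null(fit_b) || fit_b$k < k) next
      # component signs are pinned by the deterministic orientation rule and
      # the coefficients B = W (P'W)^{-1} q are invariant to per-component
      # sign flips, so replicate coefficients are already aligned with the
      # point estimate
      out[b, ] <- fit_b$coef_std
    }
    out
  })
  ok <- !is.na(coefs[, 1])
  n_skipped <- sum(!ok)
  if (n_skipped > 0.1 * n_boot) {
    degenerate_error(sprintf("%d of %d bootstrap replicates rank-collapsed",
                             n_skipped, n_boot))
  }
  lower <- apply(coefs[ok, , drop = FALSE], 2, quantile, probs = alpha)
  upper <- apply(coefs[ok, , drop = FALSE], 2, quantile, probs = 1 - alpha)
  names(lower) <- names(upper) <- fit0$var_names
  structure(
    list(lower = lower, upper = upper, estimate = fit0$coef_std,
         excluded = fit0$var_names[lower <= 0 & upper >= 0],
         n_boot = n_boot, n_skipped = n_skipped, level = level,
         seed = as.integer(seed)),
    class = "bootstrap_ci_result"
  )
}

#' @export
print.bootstrap_ci_result <- function(x, ...) {
  cat(sprintf("<bootstrap_ci_result> %d replicates (%d skipped), %g%% percentile CIs; %d of %d predictors cross zero\n",
              x$n_boot, x$n_skipped, 100 * x$level,
              length(x$excluded), length(x$lower)))
  invisible(x)
}

# ---- resampling null for variance explained --------------------------------

#' Resampling null distribution of the percentage of variance explained
#'
#' Assesses the statistical significance of a PLS model by decoupling the
#' response from the predictors: each iteration either permutes the y rows
#' (`mode = "permute"`, the default: both marginals preserved, coupling
#' destroyed) or resamples y with replacement independently of X
#' (`mode = "bootstrap"`), refits NIPALS at the fixed factor count `k` and
#' records the total percentage of X and Y variance captured. Reports null
#' means, percentile 95% intervals, and the empirical p-value
#' `(1 + #\{null >= observed\}) / (n_iter + 1)`.
#'
#' @param design A complete `design_matrix` (the final variable set).
#' @param k Fixed number of latent factors.
#' @param n_iter Number of null iterations (default 1000, minimum 20).
#' @param mode `"permute"` or `"bootstrap"`.
#' @param seed Integer seed.
#' @return A `null_variance_result`: observed and null percentages for X and
#'   Y with 95% intervals and empirical p-values, plus `n_iter`, `mode`,
#'   `seed`.
#' @export
null_variance_test <- function(design, k, n_iter = 1000,
                               mode = c("permute", "bootstrap"), seed = 1L) {
  mode <- match.arg(mode)
  if (n_iter < 20) config_error("n_iter must be >= 20")
  fit0 <- suppressWarnings(fit_nipals(design, k))
  obs_x <- 100 * sum(fit0$x_var_frac)
  obs_y <- 100 * sum(fit0$y_var_frac)
  n <- nrow(design$X)
  null_mat <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_iter, 2)
    for (it in seq_len(n_iter)) {
      y_star <- if (mode == "permute") design$y[sample.int(n)]
                else design$y[sample.int(n, n, replace = TRUE)]
      fit_it <- tryCatch(
        suppressWarnings(fit_nipals(design$X, k, y = y_star)),
        error = function(e) NULL
      )
      if (is.null(fit_it)) next
      out[it, ] <- c(100 * sum(fit_it$x_var_frac), 100 * sum(fit_it$y_var_frac))
    }
    out
  })
  null_mat <- null_mat[!is.na(null_mat[, 1]), , drop = FALSE]
  m <- nrow(null_mat)
  if (m < 20) degenerate_error("too few successful null iterations")
  ci <- function(v) unname(quantile(v, c(0.025, 0.975)))
  structure(
    list(observed_x_pct = obs_x, observed_y_pct = obs_y,
         null_mean_x_pct = mean(null_mat[, 1]), null_ci_x = ci(null_mat[, 1]),
         null_mean_y_pct = mean(null_mat[, 2]), null_ci_y = ci(null_mat[, 2]),
         empirical_p_x = (1 + sum(null_mat[, 1] >= obs_x)) / (m + 1),
         empirical_p_y = (1 + sum(null_mat[, 2] >= obs_y)) / (m + 1),
         n_iter = n_iter, mode = mode, seed = as.integer(seed)),
    class = "null_variance_result"
  )
}

#' @export
print.null_variance_result <- function(x, ...) {
  cat(sprintf("<null_variance_result> mode = %s, %d iterations\n", x$mode, x$n_iter))
  cat(sprintf("  %%var(X): observed %.1f vs null %.1f (95%% CI %.1f-%.1f), p = %.4g\n",
              x$observed_x_pct, x$null_mean_x_pct, x$null_ci_x[1],
              x$null_ci_x[2], x$empirical_p_x))
  cat(sprintf("  %%var(Y): observed %.1f vs null %.1f (95%% CI %.1f-%.1f), p = %.4g\n",
              x$observed_y_pct, x$null_mean_y_pct, x$null_ci_y[1],
              x$null_ci_y[2], x$empirical_p_y))
  invisible(x)
}

# ---- per-group component scores --------------------------------------------

#' Summarise PLS component scores by group
#'
#' Per-group mean and SD of each component's scores, a one-way ANOVA across
#' groups per component, and the group ordering by mean score. With a single
#' group only the summaries are returned.
#'
#' @param fit A `pls_fit` whose rows align with `groups`.
#' @param groups Group labels, one per fitted row.
#' @return List with `summary` (data frame: component, group, n, mean, sd),
#'   `anova` (list of `contrast_result`, one per component; `NULL` for a
#'   single group) and `ordering` (list of group names by decreasing mean
#'   score).
#' @export
scores_by_group <- function(fit, groups) {
  if (length(groups) != nrow(fit$T)) {
    schema_error(sprintf("got %d group labels for %d fitted rows",
                         length(groups), nrow(fit$T)))
  }
  g <- factor(groups, levels = intersect(group_levels(), unique(groups)))
  if (anyNA(g)) g <- factor(groups)
  comp_names <- sprintf("PLS%d", seq_len(fit$k))
  summaries <- list(); anovas <- list(); ordering <- list()
  for (a in seq_len(fit$k)) {
    sc <- split(fit$T[, a], g)
    summaries[[a]] <- data.frame(
      component = comp_names[a], group = names(sc),
      n = lengths(sc), mean = vapply(sc, mean, numeric(1)),
      sd = vapply(sc, sd, numeric(1)), row.names = NULL,
      stringsAsFactors = FALSE
    )
    ordering[[comp_names[a]]] <-
      names(sort(vapply(sc, mean, numeric(1)), decreasing = TRUE))
    if (nlevels(g) >= 2) {
      anovas[[comp_names[a]]] <- one_way_anova(
        sc, comparison = sprintf("%s scores across groups", comp_names[a]),
        family = "pls_scores")
    }
  }
  list(summary = do.call(rbind, summaries),
       anova = if (length(anovas)) anovas else NULL,
       ordering = ordering)
}

# ---- end-to-end workflow ---------------------------------------------------

#' Run the full PLS variable-selection workflow
#'
#' Executes, in order: mean imputation of missing predictor entries (the
#' leave-one-out stages re-impute inside each fold); an initial NIPALS fit of
#' the full predictor set at the factor count minimising leave-one-out PRESS;
#' the VIP/coefficient screen; bootstrap percentile CIs on the screened set
#' with exclusion of coefficients whose CI includes zero; a final refit on
#' the surviving variables with fresh PRESS factor selection; the resampling
#' null for the percentage of variance explained; and, when group labels are
#' given, per-group component score summaries with ANOVA. An empty variable
#' set after either selection step is reported as "no significant
#' multivariate structure", not an error. All seeds, thresholds and modes are
#' recorded so a report can be reproduced bit-identically.
#'
#' @param design A `design_matrix`; `X` may contain missing entries.
#' @param groups Optional group labels aligned with the design rows.
#' @param k_max Largest candidate factor count for PRESS selection (default
#'   `min(10, n - 2, p)`).
#' @param vip_cut,coef_cut,screen_rule Passed to [screen_variables()].
#' @param n_boot,level Passed to [bootstrap_coefficient_cis()].
#' @param n_null,null_mode Passed to [null_variance_test()].
#' @param seed Integer master seed; the bootstrap and null stages use
#'   `seed + 1` and `seed + 2`.
#' @return A `pls_workflow_report`: list with `initial_fit`, `initial_press`,
#'   `screening`, `bootstrap`, `final_vars`, `final_press`, `final_fit`,
#'   `null_test`, `group_scores`, `no_structure` flag and an `options` echo.
#' @export
run_pls_workflow <- function(design, groups = NULL,
                             k_max = NULL, vip_cut = 0.8, coef_cut = 0.05,
                             screen_rule = "and", n_boot = 1000, level = 0.95,
                             n_null = 1000, null_mode = "permute", seed = 1L) {
  n <- nrow(design$X); p <- ncol(design$X)
  if (is.null(k_max)) k_max <- min(10L, n - 2L, p)
  opts <- list(k_max = k_max, vip_cut = vip_cut, coef_cut = coef_cut,
               screen_rule = screen_rule, n_boot = n_boot, level = level,
               n_null = n_null, null_mode = null_mode, seed = as.integer(seed),
               n = n, p = p)
  design_imp <- impute_column_means(design)

  press0 <- loo_press(design, k_max)
  k0 <- choose_components(press0)
  fit0 <- suppressWarnings(fit_nipals(design_imp, k0))

  report <- structure(
    list(initial_fit = fit0, initial_press = press0, screening = NULL,
         bootstrap = NULL, final_vars = character(), final_press = NULL,
         final_fit = NULL, null_test = NULL, group_scores = NULL,
         no_structure = FALSE, options = opts),
    class = "pls_workflow_report"
  )

  scr <- screen_variables(fit0, vip_cut, coef_cut, screen_rule)
  report$screening <- scr
  if (!length(scr$retained)) {
    report$no_structure <- TRUE
    return(report)
  }

  d_scr <- impute_column_means(subset_design(design, scr$retained))
  k_scr <- min(k0, length(scr$retained))
  boot <- bootstrap_coefficient_cis(d_scr, k_scr, n_boot = n_boot,
                                    level = level, seed = seed + 1L)
  report$bootstrap <- boot
  final_vars <- setdiff(scr$retained, boot$excluded)
  report$final_vars <- final_vars
  if (!length(final_vars)) {
    report$no_structure <- TRUE
    return(report)
  }

  d_final_raw <- subset_design(design, final_vars)
  d_final <- impute_column_means(d_final_raw)
  k_max_f <- min(k_max, length(final_vars), n - 2L)
  press_f <- loo_press(d_final_raw, k_max_f)
  k_f <- choose_components(press_f)
  fit_f <- suppressWarnings(fit_nipals(d_final, k_f))
  report$final_press <- press_f
  report$final_fit <- fit_f
  report$null_test <- null_variance_test(d_final, k_f, n_iter = n_null,
                                         mode = null_mode, seed = seed + 2L)
  if (!is.null(groups)) report$group_scores <- scores_by_group(fit_f, groups)
  report
}

#' @export
print.pls_workflow_report <- function(x, ...) {
  cat("<pls_workflow_report>\n")
  cat(sprintf("  initial fit: k = %d over %d predictors\n",
              x$initial_fit$k, x$options$p))
  if (x$no_structure) {
    cat("  no significant multivariate structure retained\n")
    return(invisible(x))
  }
  cat(sprintf("  screening retained %d; bootstrap excluded %d; final set %d variables\n",
              length(x$screening$retained), length(x$bootstrap$excluded),
              length(x$final_vars)))
  cat(sprintf("  final fit: k = %d, %%var(X) = %.1f, %%var(Y) = %.1f\n",
              x$final_fit$k, 100 * sum(x$final_fit$x_var_frac),
              100 * sum(x$final_fit$y_var_frac)))
  if (!is.null(x$null_test)) {
    cat(sprintf("  null: %%var(Y) %.1f (p = %.4g)\n",
                x$null_test$null_mean_y_pct, x$null_test$empirical_p_y))
  }
  invisible(x)
}

#' Serialise a workflow report to JSON
#'
#' Nested sections (`initial_fit`, `screening`, `bootstrap`, `final_fit`,
#' `null_test`, `group_scores`, `options`) with all arrays labelled by
#' predictor or component names; contains every seed, threshold and mode
#' needed to re-run the workflow bit-identically.
#'
#' @param report A `pls_workflow_report`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
workflow_report_json <- function(report, path = NULL) {
  fit_block <- function(f) {
    if (is.null(f)) return(NULL)
    list(k = f$k,
         x_var_frac = as.list(setNames(f$x_var_frac,
                                       sprintf("PLS%d", seq_len(f$k)))),
         y_var_frac = as.list(setNames(f$y_var_frac,
                                       sprintf("PLS%d", seq_len(f$k)))),
         vip = as.list(vip(f)), coef_std = as.list(f$coef_std))
  }
  x <- report
  out <- list(
    options = x$options,
    initial_press = as.list(x$initial_press$press),
    initial_fit = fit_block(x$initial_fit),
    screening = if (!is.null(x$screening)) list(
      retained = x$screening$retained, discarded = x$screening$discarded,
      thresholds = x$screening$thresholds),
    bootstrap = if (!is.null(x$bootstrap)) list(
      lower = as.list(x$bootstrap$lower), upper = as.list(x$bootstrap$upper),
      estimate = as.list(x$bootstrap$estimate),
      excluded = x$bootstrap$excluded, n_boot = x$bootstrap$n_boot,
      n_skipped = x$bootstrap$n_skipped, level = x$bootstrap$level,
      seed = x$bootstrap$seed),
    final_vars = x$final_vars,
    final_press = if (!is.null(x$final_press)) as.list(x$final_press$press),
    final_fit = fit_block(x$final_fit),
    null_test = if (!is.null(x$null_test)) unclass(x$null_test),
    group_scores = if (!is.null(x$group_scores)) list(
      summary = x$group_scores$summary,
      ordering = x$group_scores$ordering,
      anova = lapply(x$group_scores$anova, function(a) as.data.frame(a))),
    no_structure = x$no_structure
  )
  if (is.null(path)) {
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
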