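#' Violin plot of log10 CRP by group
#'
#' Presentation helper (requires ggplot2, in Suggests): violin plus jittered
#' points of log10 CRP for the four study groups.
#'
#' @param cohort Cohort data frame.
#' @return A ggplot object.
#' @export
plot_crp_violin <- function(cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(group = factor(cohort$group, levels = group_levels()),
                   log10_crp = log10(cohort$crp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$log10_crp,
                                   fill = .data$group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, size = 0.5, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = expression(log[10] ~ "CRP (mg/L)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Violin plot of first-component PLS scores by group
#'
#' @param fit A `pls_fit` whose rows align with `groups`.
#' @param groups Group labels.
#' @param component Component index (default 1).
#' @return A ggplot object.
#' @export
plot_score_violin <- function(fit, groups, component = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(group = factor(groups, levels = group_levels()),
                   score = fit$T[, component])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, size = 0.5, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = sprintf("PLS%d score", component)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
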