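# Questionnaire instruments carried by the cohort: item counts, ordinal score
# ranges, cumulative probabilities used to discretise the Gaussian item latents,
# and the loading of each instrument on the shared depression-severity factor.
# HAM-D items are scored 0-4, CFS and BDI 0-3, CTQ 1-5, STAI and SHAPS 1-4.
instrument_table <- function() {
  list(
    hamd  = list(n_items = 21, min = 0, max = 4,
                 cut_p = c(0.55, 0.80, 0.92, 0.98),
                 severity_loading = 0.28, group_sep = 1.00),
    cfs   = list(n_items = 11, min = 0, max = 3,
                 cut_p = c(0.50, 0.80, 0.95),
                 severity_loading = 0.25, group_sep = 1.00),
    bdi   = list(n_items = 21, min = 0, max = 3,
                 cut_p = c(0.50, 0.80, 0.95),
                 severity_loading = 0.25, group_sep = 1.00),
    ctq   = list(n_items = 28, min = 1, max = 5,
                 cut_p = c(0.45, 0.70, 0.85, 0.95),
                 severity_loading = 0.10, group_sep = 1.00),
    stai  = list(n_items = 40, min = 1, max = 4,
                 cut_p = c(0.40, 0.70, 0.90),
                 severity_loading = 0.20, group_sep = 1.00),
    shaps = list(n_items = 14, min = 1, max = 4,
                 cut_p = c(0.50, 0.80, 0.95),
                 severity_loading = 0.22, group_sep = 1.00)
  )
}

#' Names of the questionnaire item columns
#'
#' One name per item of the six instruments (21 HAM-D, 11 CFS, 21 BDI, 28 CTQ,
#' 40 STAI, 14 SHAPS), in the fixed column order used throughout the package:
#' `hamd_01..hamd_21, cfs_01..cfs_11, bdi_01..bdi_21, ctq_01..ctq_28,
#' stai_01..stai_40, shaps_01..shaps_14`.
#'
#' @return Character vector of 135 item column names.
#' @export
item_names <- function() {
  ins <- instrument_table()
  unlist(lapply(names(ins), function(nm) {
    sprintf("%s_%02d", nm, seq_len(ins[[nm]]$n_items))
  }), use.names = FALSE)
}

#' Names of the predictor (X) columns of the design matrix
#'
#' The 139 predictors are the four demographic/anthropometric variables
#' (`gender`, `age`, `bmi`, `education`) followed by the 135 questionnaire
#' items from [item_names()].
#'
#' @return Character vector of 139 predictor names in design-matrix order.
#' @export
predictor_names <- function() {
  c("gender", "age", "bmi", "education", item_names())
}

#' Study group labels
#'
#' Factor levels used for the four recruitment groups, in reporting order:
#' treatment-resistant, treatment-responsive, untreated depression, healthy
#' volunteers.
#'
#' @return Character vector of the four group labels.
#' @export
group_levels <- function() c("resistant", "responsive", "untreated", "healthy")

# Full cohort CSV column order (external interface).
cohort_columns <- function() {
  c("participant_id", "group", "age", "gender", "education", "bmi", "crp",
    "n_failed_treatments", item_names())
}

# ordinal range of every item column, as a named list(min, max)
item_ranges <- function() {
  ins <- instrument_table()
  out <- list()
  for (nm in names(ins)) {
    for (j in seq_len(ins[[nm]]$n_items)) {
      out[[sprintf("%s_%02d", nm, j)]] <- c(ins[[nm]]$min, ins[[nm]]$max)
    }
  }
  out
}
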