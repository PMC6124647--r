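#' Assemble the PLS design matrix from a cohort
#'
#' Builds the response vector Y (high-sensitivity CRP, mg/L) and the predictor
#' matrix X with the 139 columns of [predictor_names()] — gender, age, BMI and
#' education level followed by the 135 questionnaire items — in that fixed,
#' documented order. Missing entries are preserved: imputation is a separate,
#' later step ([impute_column_means()]).
#'
#' @param cohort A `crp_cohort` or any data frame with the cohort schema
#'   columns.
#' @return A `design_matrix`: list with `X` (n x 139 numeric matrix with
#'   column names), `y` (length-n numeric), `row_ids` (participant ids) and
#'   `y_name`.
#' @export
#' @examples
#' d <- assemble_design(generate_cohort(cohort_config(seed = 7)))
#' dim(d$X)  # 252 x 139
assemble_design <- function(cohort) {
  if (nrow(cohort) < 1) schema_error("cohort is empty")
  needed <- c("participant_id", "crp", predictor_names())
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    schema_error(sprintf("cohort is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(cohort[, predictor_names()])
  storage.mode(X) <- "double"
  structure(
    list(X = X, y = as.numeric(cohort$crp),
         row_ids = as.character(cohort$participant_id), y_name = "crp"),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> X: %d x %d, y: %s (%d missing X entries)\n",
              nrow(x$X), ncol(x$X), x$y_name, sum(is.na(x$X))))
  invisible(x)
}

#' Write a cohort table to CSV
#'
#' Serialises the cohort in the fixed schema column order with empty fields
#' for missing values; the round trip through [read_cohort()] preserves all
#' values including missingness.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    schema_error(sprintf("cohort is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  write.csv(cohort[, cohort_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads a CSV in the cohort schema (header
#' `participant_id,group,age,gender,education,bmi,crp,n_failed_treatments,`
#' followed by the 135 item columns; empty field = missing) and validates it:
#' required columns present, `participant_id` unique, `group` one of
#' [group_levels()], `crp` strictly positive where present, and every item
#' score inside its declared ordinal range. Violations raise an error with a
#' row/column diagnostic. Unknown extra columns are accepted with a warning
#' and ignored (lenient-read policy).
#'
#' @param path CSV file path.
#' @return A `crp_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  tab <- tryCatch(
    read.csv(path, na.strings = "", stringsAsFactors = FALSE),
    error = function(e) schema_error(sprintf("malformed CSV '%s': %s",
                                             path, conditionMessage(e)))
  )
  missing_cols <- setdiff(cohort_columns(), names(tab))
  if (length(missing_cols)) {
    schema_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(tab), cohort_columns())
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    tab <- tab[, cohort_columns()]
  }
  validate_cohort(tab)
  structure(tab, class = c("crp_cohort", "data.frame"))
}

validate_cohort <- function(tab) {
  if (anyDuplicated(tab$participant_id)) {
    dup <- tab$participant_id[duplicated(tab$participant_id)][1]
    schema_error(sprintf("duplicate participant_id '%s'", dup))
  }
  bad_group <- which(!tab$group %in% group_levels())
  if (length(bad_group)) {
    schema_error(sprintf("row %d: unknown group '%s'",
                         bad_group[1], tab$group[bad_group[1]]))
  }
  bad_crp <- which(!is.na(tab$crp) & tab$crp <= 0)
  if (length(bad_crp)) {
    schema_error(sprintf("row %d, column crp: value %s is not > 0",
                         bad_crp[1], format(tab$crp[bad_crp[1]])))
  }
  ranges <- item_ranges()
  for (col in names(ranges)) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & (v < ranges[[col]][1] | v > ranges[[col]][2] |
                                v != round(v)))
    if (length(bad)) {
      schema_error(sprintf(
        "row %d, column %s: score %s outside ordinal range %d..%d",
        bad[1], col, format(v[bad[1]]), ranges[[col]][1], ranges[[col]][2]))
    }
  }
  invisible(tab)
}
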