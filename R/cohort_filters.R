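# Study-population construction: inclusion/exclusion filters with an
# auditable attrition log, treatment labelling from timed procedure codes,
# and derivation of the trauma-bay model matrix.

#' Apply the study inclusion/exclusion filters
#'
#' Keeps adults (age > 16, strict) with a blunt mechanism arriving in
#' hemorrhagic shock (arrival SBP <= 90 mmHg, inclusive, or >= 4 units of
#' RBCs within 4 h, inclusive), then excludes inter-facility transfers and
#' records missing age or length of stay. Rows with missing age survive the
#' age inclusion step and are removed at the dedicated missing-age step, so
#' the attrition log attributes every exclusion to a single criterion, in
#' filter order.
#'
#' @param encounters Data.frame of raw encounters. Required columns: `age`,
#'   `mechanism`, `sbp`, `rbc_units_4h`, `transfer_in`, `los_days`.
#' @return List with `cohort` (the filtered data.frame) and `attrition`
#'   (data.frame with `criterion`, `n_excluded`, `n_remaining`).
#' @export
apply_study_filters <- function(encounters) {
  required <- c("age", "mechanism", "sbp", "rbc_units_4h", "transfer_in",
                "los_days")
  absent <- setdiff(required, names(encounters))
  if (length(absent)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }

  log <- data.frame(criterion = "initial", n_excluded = 0L,
                    n_remaining = nrow(encounters),
                    stringsAsFactors = FALSE)
  step <- function(df, label, keep) {
    keep[is.na(keep)] <- FALSE
    out <- df[keep, , drop = FALSE]
    log <<- rbind(log, data.frame(criterion = label,
                                  n_excluded = nrow(df) - nrow(out),
                                  n_remaining = nrow(out),
                                  stringsAsFactors = FALSE))
    out
  }

  df <- encounters
  df <- step(df, "age > 16", is.na(df$age) | df$age > 16)
  df <- step(df, "blunt mechanism", df$mechanism == "blunt")
  df <- step(df, "hemorrhagic shock (SBP <= 90 or RBC >= 4 units in 4 h)",
             (!is.na(df$sbp) & df$sbp <= 90) |
               (!is.na(df$rbc_units_4h) & df$rbc_units_4h >= 4))
  df <- step(df, "not transferred within 24 h", df$transfer_in != 1)
  df <- step(df, "age recorded", !is.na(df$age))
  df <- step(df, "length of stay recorded", !is.na(df$los_days))

  rownames(df) <- NULL
  list(cohort = df, attrition = log)
}

#' Label REBOA treatment from timed procedure codes
#'
#' A record is treated iff any of its procedure codes belongs to the REBOA
#' code set with an hours-from-arrival timestamp within the window
#' (inclusive). Codes are encoded as `"CODE@HOURS"` entries separated by
#' `";"`; an empty string or `NA` means no procedures.
#'
#' @param procedure_codes Character vector of encoded procedure-code lists.
#' @param window_hours Time window from arrival (default 4).
#' @param code_set Character vector of qualifying ICD-10 procedure codes
#'   (default [REBOA_CODES]).
#' @return Integer vector of 0/1 treatment labels.
#' @export
label_reboa <- function(procedure_codes, window_hours = 4,
                        code_set = REBOA_CODES) {
  vapply(seq_along(procedure_codes), function(i) {
    s <- procedure_codes[i]
    if (is.na(s) || !nzchar(s)) return(0L)
    entries <- strsplit(s, ";", fixed = TRUE)[[1]]
    for (e in entries) {
      parts <- strsplit(e, "@", fixed = TRUE)[[1]]
      hrs <- if (length(parts) == 2) suppressWarnings(as.numeric(parts[2])) else NA
      if (length(parts) != 2 || is.na(hrs) || hrs < 0) {
        stop(sprintf("parse error in procedure codes at row %d: '%s'", i, e),
             call. = FALSE)
      }
      if (parts[1] %in% code_set && hrs <= window_hours) return(1L)
    }
    0L
  }, integer(1))
}

#' Derive the trauma-bay model matrix
#'
#' Computes BMI from height and weight where BMI is missing and both inputs
#' are present, then restricts the table to exactly the trauma-bay covariate
#' set (plus `id`, `reboa`, `death_24h` bookkeeping when present). Any other
#' column not recognized as standard cohort bookkeeping triggers a warning
#' and is excluded, so information not knowable at the treatment decision
#' (e.g. injury severity scores) cannot leak into training.
#'
#' @param cohort Cohort data.frame.
#' @return Data.frame with the model covariates and bookkeeping columns.
#' @export
derive_features <- function(cohort) {
  if (all(c("height", "weight") %in% names(cohort))) {
    hw <- !is.na(cohort$height) & !is.na(cohort$weight)
    if (any(hw & cohort$height <= 0)) {
      stop("value error: non-positive height", call. = FALSE)
    }
    if ("bmi" %in% names(cohort)) {
      fill <- is.na(cohort$bmi) & hw
      cohort$bmi[fill] <- round(
        cohort$weight[fill] / (cohort$height[fill] / 100)^2, 1)
    } else {
      cohort$bmi <- ifelse(hw, round(cohort$weight / (cohort$height / 100)^2, 1),
                           NA_real_)
    }
  }
  keep_extra <- intersect(c("id", "reboa", "death_24h"), names(cohort))
  model_cols <- intersect(MODEL_COVARIATES, names(cohort))
  unknown <- setdiff(names(cohort),
                     c(MODEL_COVARIATES, NON_MODEL_COLUMNS))
  if (length(unknown)) {
    warning(sprintf(
      "excluding column(s) not in the trauma-bay covariate set: %s",
      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cohort[, c(keep_extra, model_cols), drop = FALSE]
}

#' Write an attrition log
#'
#' @param attrition Attrition data.frame from [apply_study_filters()].
#' @param json_path,txt_path Output paths (either may be `NULL`).
#' @return Invisibly, the attrition table.
#' @export
write_attrition <- function(attrition, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(attrition, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    lines <- sprintf("%-55s excluded %7d, remaining %7d",
                     attrition$criterion, attrition$n_excluded,
                     attrition$n_remaining)
    writeLines(lines, txt_path)
  }
  invisible(attrition)
}
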