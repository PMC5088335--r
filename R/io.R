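#' @keywords internal
cohort_schema <- c("subject_id", "female", "race_black", "age_years",
                   "height_cm", "weight_kg", "waist_cm", "hip_cm",
                   "sample_weight", "followup_years", "died", "pregnant")

#' Load a cohort CSV
#'
#' Reads the standard cohort schema (comma-separated, UTF-8, header
#' mandatory, "." decimal, missing values as empty fields), validates rows
#' and applies the eligibility gate.  Rows with invalid or missing required
#' values are dropped; all exclusion counts are attached as the
#' \code{"exclusions"} attribute and reported via \code{message()}.
#'
#' @param path CSV file path.
#' @param apply_gate Apply [filter_eligible()] (default TRUE).
#' @return Cohort data frame.
#' @export
load_cohort <- function(path, apply_gate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty input: ", path)
  miss <- setdiff(cohort_schema, names(df))
  if (length(miss))
    stop("schema error, missing columns: ", paste(miss, collapse = ", "))
  req <- setdiff(cohort_schema, "subject_id")
  complete <- stats::complete.cases(df[, req])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (apply_gate) {
    df <- filter_eligible(df)
    excl <- attr(df, "exclusions")
  } else excl <- c(total = 0L)
  excl <- c(missing_values = n_dropped, excl)
  attr(df, "exclusions") <- excl
  message(sprintf("loaded %d records from %s (%d dropped: %s)",
                  nrow(df), path, n_dropped + excl[["total"]],
                  paste(names(excl), excl, sep = "=", collapse = ", ")))
  df
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_schema, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}
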