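# Readers/writers for the exchange formats: person records and count
# tables as UTF-8 RFC-4180 CSV with a mandatory header, configuration and
# results as JSON, transcripts as JSON lines (see write_transcript).

#' Read or write person-record tables
#'
#' CSV, UTF-8, comma-separated, header mandatory.  Columns are attribute
#' names from the quasi-identifier schema plus optional `exposure_class`,
#' `person_id` and `case`.
#'
#' @param path File path.
#' @param records Data frame of records.
#' @return `read_records` returns a data frame; `write_records` returns
#'   `path` invisibly.
#' @export
read_records <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 check.names = FALSE)
  abort_if(nrow(df) == 0, "no records in %s", path)
  df
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-class count tables
#'
#' CSV with columns `label`, `cases`, `noncases`, one row per exposure
#' class.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_class_counts <- function(path) {
  df <- read_records(path)
  normalize_class_counts(df)
}

#' Read SMR strata
#'
#' CSV with columns `age_group`, `deaths`, `rate`, `population`.
#'
#' @param path File path.
#' @return An [smr_strata()] data frame.
#' @export
read_smr_strata <- function(path) {
  df <- read_records(path)
  need <- c("deaths", "rate", "population")
  abort_if(!all(need %in% names(df)),
           "SMR strata file needs columns deaths, rate, population")
  smr_strata(df$deaths, df$rate, df$population,
             age_group = df$age_group %||% NULL)
}

#' Write a stratified result as JSON
#'
#' Full-precision statistics plus metadata (reference class, chi-squared
#' variant, alpha); the plain-text rendering with 2-decimal rounding is
#' the `print` method.
#'
#' @param result A `stratified_result` (from [stratified_rr()] or
#'   [run_protocol()]`$result`).
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_result_json <- function(result, path) {
  payload <- list(
    reference = attr(result, "reference"),
    chi2_variant = attr(result, "chi2_variant"),
    alpha = attr(result, "alpha"),
    rows = as.data.frame(result))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
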