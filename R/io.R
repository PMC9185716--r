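#' Read and write respondent-level survey data
#'
#' Comma-delimited UTF-8 text with a header row, one row per respondent:
#' QC metadata, demographics and the 34 item columns coded 0-3 with blank
#' cells for skipped items. Zip codes, state codes, record ids and
#' duplicate keys are kept as character (leading zeros matter).
#'
#' @param path CSV file path.
#' @return `read_respondents()` returns a data frame;
#'   `write_respondents()` invisibly returns `path`.
#' @export
read_respondents <- function(path) {
  first <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  classes <- stats::setNames(rep(NA, ncol(first)), names(first))
  chr <- intersect(c("record_id", "zip", "state", "duplicate_key",
                     paste0("open_text_", 1:5)), names(first))
  classes[chr] <- "character"
  utils::read.csv(path, colClasses = classes, na.strings = c("", "NA"),
                  check.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname read_respondents
#' @param records Respondent data frame.
#' @export
write_respondents <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
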