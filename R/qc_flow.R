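#' Read a zip/state lookup table
#'
#' Four columns: `zip`, `state`, `lat`, `long`. A miniature table covering
#' one zip per state region ships with the package for tests and examples
#' (`system.file("extdata", "zip_state_lookup.csv", package = "dascreen")`);
#' real deployments supply a complete table. No network calls are made.
#'
#' @param path CSV file path.
#' @return Data frame with character `zip`/`state` and numeric
#'   `lat`/`long`.
#' @export
read_zip_table <- function(path = system.file("extdata", "zip_state_lookup.csv",
                                              package = "dascreen")) {
  tab <- utils::read.csv(path, colClasses = c(zip = "character",
                                              state = "character"))
  need <- c("zip", "state", "lat", "long")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("zip table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

# Metadata columns every survey record must carry for QC.
qc_required_columns <- function() {
  c("record_id", "age_years", "us_resident", "dated_past_year",
    "prior_completion", "skipped_count", "timed_out", "consented",
    "zip", "state", "ip_country", "ip_lat", "ip_long",
    paste0("open_text_", 1:5), "duplicate_key")
}

check_qc_columns <- function(records, cols = qc_required_columns()) {
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0)
    stop("records are missing required QC column(s): ",
         paste(miss, collapse = ", "))
  invisible(records)
}

# Order in which eligibility rules are checked; the first failing rule is
# the record's primary exclusion reason, so per-reason counts partition the
# ineligible records.
eligibility_reasons <- function() {
  c("prior_completion", "no_dating", "age", "skipped_gt10", "non_us",
    "timed_out")
}

#' Eligibility screening
#'
#' A record is eligible iff the respondent is 11-21 years old, lives in the
#' U.S., reported a past-year dating relationship, had not already
#' completed the survey, skipped at most 10 questions, and did not time
#' out. Each excluded record is labelled with its first failing rule in the
#' fixed order `prior_completion`, `no_dating`, `age`, `skipped_gt10`,
#' `non_us`, `timed_out`.
#'
#' @param records Data frame of survey records carrying the QC metadata
#'   columns (see `Details` of [run_flow()]).
#' @param age_range Inclusive eligible age range. Default `c(11, 21)`.
#' @param max_skipped Maximum questions a respondent may skip. Default 10.
#' @return A list: `eligible` (records passing all rules), `excluded`
#'   (failing records with an `exclusion_reason` column), `counts` (named
#'   integer vector over the reasons, in rule order).
#' @export
eligibility_filter <- function(records, age_range = c(11L, 21L),
                               max_skipped = 10L) {
  check_qc_columns(records,
                   c("record_id", "age_years", "us_resident",
                     "dated_past_year", "prior_completion", "skipped_count",
                     "timed_out"))
  needed <- c("age_years", "us_resident", "dated_past_year",
              "prior_completion", "skipped_count", "timed_out")
  for (col in needed)
    if (anyNA(records[[col]]))
      stop("missing values in required field '", col, "' (record ids: ",
           paste(utils::head(records$record_id[is.na(records[[col]])], 5L),
                 collapse = ", "), ")")
  fails <- cbind(
    prior_completion = records$prior_completion == 1,
    no_dating = records$dated_past_year == 0,
    age = records$age_years < age_range[1] | records$age_years > age_range[2],
    skipped_gt10 = records$skipped_count > max_skipped,
    non_us = records$us_resident == 0,
    timed_out = records$timed_out == 1
  )
  first_fail <- apply(fails, 1, function(f) {
    i <- which(f)
    if (length(i) == 0) NA_character_ else colnames(fails)[i[1]]
  })
  eligible <- records[is.na(first_fail), , drop = FALSE]
  excluded <- records[!is.na(first_fail), , drop = FALSE]
  excluded$exclusion_reason <- first_fail[!is.na(first_fail)]
  counts <- vapply(eligibility_reasons(),
                   function(r) sum(first_fail == r, na.rm = TRUE), integer(1))
  list(eligible = eligible, excluded = excluded, counts = counts)
}

# A free-text answer counts as nonsense if, after trimming, it is empty,
# shorter than 2 characters, has no vowel, or is one repeated character.
is_nonsense_text <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  nchar(x) < 2L |
    !grepl("[aeiouAEIOU]", x) |
    vapply(strsplit(x, ""), function(ch) length(unique(ch)) == 1L, logical(1))
}

fraud_rules <- function() {
  c("zip_state_mismatch", "blank_or_nonsense_text", "foreign_ip",
    "duplicate", "geo_mismatch")
}

#' Survey-fraud flags
#'
#' Applies the five rule-based bot/fraud checks to each record:
#' \describe{
#'   \item{zip_state_mismatch}{reported zip code does not belong to the
#'     reported state (lookup-table based; a zip absent from the table is
#'     treated as a mismatch).}
#'   \item{blank_or_nonsense_text}{all five open-ended answers are blank or
#'     nonsense strings (no vowel, under 2 characters, or one repeated
#'     character).}
#'   \item{foreign_ip}{IP country is not \code{"US"}.}
#'   \item{duplicate}{the record's duplicate key was already seen on an
#'     earlier record (repeat submissions after the first are flagged).}
#'   \item{geo_mismatch}{great-circle distance between the IP coordinates
#'     and the reported zip's coordinates exceeds `geo_threshold_km`.}
#' }
#' A record is fraudulent iff at least one rule fires. Rules are pure:
#' the same records and tables always give the same flags.
#'
#' @param records Data frame of consented survey records.
#' @param zip_table Zip/state lookup, see [read_zip_table()].
#' @param geo_threshold_km Distance tolerance for `geo_mismatch`, in km.
#'   Default 300.
#' @param disabled_rules Character vector of rule names to skip.
#' @return Data frame of logicals, one column per rule plus `fraudulent`
#'   (any rule fired), `record_id` first.
#' @export
fraud_flags <- function(records, zip_table = read_zip_table(),
                        geo_threshold_km = 300, disabled_rules = character(0)) {
  check_qc_columns(records,
                   c("record_id", "zip", "state", "ip_country", "ip_lat",
                     "ip_long", paste0("open_text_", 1:5), "duplicate_key"))
  bad_rule <- setdiff(disabled_rules, fraud_rules())
  if (length(bad_rule) > 0)
    stop("unknown fraud rule(s): ", paste(bad_rule, collapse = ", "))
  unknown_state <- !(records$state %in% zip_table$state)
  if (any(unknown_state))
    stop("unknown state code(s) in records: ",
         paste(sprintf("%s (record %s)",
                       records$state[unknown_state],
                       records$record_id[unknown_state])[1:min(5, sum(unknown_state))],
               collapse = "; "))
  idx <- match(records$zip, zip_table$zip)
  zip_state <- zip_table$state[idx]
  flags <- data.frame(record_id = records$record_id)
  flags$zip_state_mismatch <- is.na(idx) | zip_state != records$state
  txt <- as.matrix(records[, paste0("open_text_", 1:5)])
  flags$blank_or_nonsense_text <-
    rowSums(matrix(is_nonsense_text(txt), nrow(records))) == 5L
  flags$foreign_ip <- records$ip_country != "US"
  flags$duplicate <- duplicated(records$duplicate_key)
  dist_km <- rep(NA_real_, nrow(records))
  has_zip <- !is.na(idx)
  if (any(has_zip)) {
    dist_km[has_zip] <- geosphere::distHaversine(
      cbind(records$ip_long[has_zip], records$ip_lat[has_zip]),
      cbind(zip_table$long[idx[has_zip]], zip_table$lat[idx[has_zip]])
    ) / 1000
  }
  flags$geo_mismatch <- !is.na(dist_km) & dist_km > geo_threshold_km
  for (r in disabled_rules) flags[[r]] <- FALSE
  flags$fraudulent <- Reduce(`|`, flags[fraud_rules()])
  flags
}

#' Run the full record-filtering flow
#'
#' Applies, in order: eligibility screening, the consent gate, and the
#' five fraud rules, and returns the analytic records together with a
#' stage-by-stage flow report. Required metadata columns:
#' `r paste0("\\code{", qc_required_columns(), "}", collapse = ", ")`.
#'
#' @inheritParams fraud_flags
#' @inheritParams eligibility_filter
#' @param records Data frame of all screened survey entries.
#' @return A list with `records` (the analytic sample), `report` (a
#'   `flow_report` object), and `flags` (per-record fraud flags among the
#'   consented).
#' @export
run_flow <- function(records, zip_table = read_zip_table(),
                     geo_threshold_km = 300, disabled_rules = character(0),
                     age_range = c(11L, 21L), max_skipped = 10L) {
  if (nrow(records) == 0L) {
    report <- new_flow_report(
      screened = 0L,
      ineligible = stats::setNames(integer(length(eligibility_reasons())),
                                   eligibility_reasons()),
      eligible = 0L, consented = 0L,
      fraud = stats::setNames(integer(length(fraud_rules())), fraud_rules()),
      fraud_flagged = 0L, final = 0L)
    return(list(records = records, report = report, flags = NULL))
  }
  check_qc_columns(records)
  elig <- eligibility_filter(records, age_range = age_range,
                             max_skipped = max_skipped)
  consented <- elig$eligible[elig$eligible$consented == 1, , drop = FALSE]
  flags <- fraud_flags(consented, zip_table = zip_table,
                       geo_threshold_km = geo_threshold_km,
                       disabled_rules = disabled_rules)
  analytic <- consented[!flags$fraudulent, , drop = FALSE]
  report <- new_flow_report(
    screened = nrow(records),
    ineligible = elig$counts,
    eligible = nrow(elig$eligible),
    consented = nrow(consented),
    fraud = vapply(fraud_rules(), function(r) sum(flags[[r]]), integer(1)),
    fraud_flagged = sum(flags$fraudulent),
    final = nrow(analytic)
  )
  list(records = analytic, report = report, flags = flags)
}

new_flow_report <- function(screened, ineligible, eligible, consented,
                            fraud, fraud_flagged, final) {
  structure(list(
    screened = as.integer(screened),
    ineligible = vapply(ineligible, as.integer, integer(1)),
    ineligible_total = as.integer(sum(ineligible)),
    eligible = as.integer(eligible),
    consented = as.integer(consented),
    non_consent = as.integer(eligible - consented),
    fraud = vapply(fraud, as.integer, integer(1)),
    fraud_flagged = as.integer(fraud_flagged),
    final = as.integer(final)
  ), class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("Record flow\n")
  cat(sprintf("  screened          %5d\n", x$screened))
  cat(sprintf("  ineligible        %5d\n", x$ineligible_total))
  for (r in names(x$ineligible))
    cat(sprintf("    %-16s %5d\n", r, x$ineligible[[r]]))
  cat(sprintf("  eligible          %5d\n", x$eligible))
  cat(sprintf("  consented         %5d  (non-consent %d)\n",
              x$consented, x$non_consent))
  cat(sprintf("  fraud-flagged     %5d\n", x$fraud_flagged))
  for (r in names(x$fraud))
    cat(sprintf("    %-22s %5d\n", r, x$fraud[[r]]))
  cat(sprintf("  final analytic    %5d\n", x$final))
  invisible(x)
}

#' Serialise a flow report to JSON
#'
#' @param report A `flow_report` from [run_flow()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
flow_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "flow_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
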