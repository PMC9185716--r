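#' Score the 34-item reference instrument
#'
#' Sums the 0-3 frequency codes over the 34 items and classifies each
#' respondent as a dating-abuse survivor when the total reaches the
#' cutpoint (default 6, the value used to dichotomise the reference
#' standard).
#'
#' @param responses A data frame with one row per respondent containing the
#'   34 item columns named in `schema$item_id`, coded 0-3, `NA` = skipped.
#' @param schema Instrument schema, see [marsha_schema()].
#' @param cutpoint Total score at or above which a respondent is
#'   reference-positive. Default 6.
#' @param missing_policy Either `"treat_as_zero"` (default: a skipped item
#'   contributes 0, respondents could skip any question) or
#'   `"reject_if_over_k"` (error if any respondent skipped more than
#'   `max_missing` items; records that skipped more than 10 questions are
#'   normally removed upstream by the eligibility filter).
#' @param max_missing Skip tolerance under `"reject_if_over_k"`. Default 10.
#' @return A data frame with columns `score` (integer) and `positive`
#'   (logical), one row per respondent; the cutpoint is kept as the
#'   `"cutpoint"` attribute.
#' @export
#' @examples
#' sch <- marsha_schema()
#' resp <- as.data.frame(matrix(0L, 2, 34, dimnames = list(NULL, sch$item_id)))
#' resp[2, 1:6] <- 1L
#' score_marsha(resp, sch)   # scores 0 and 6; second row positive
score_marsha <- function(responses, schema = marsha_schema(), cutpoint = 6L,
                         missing_policy = c("treat_as_zero", "reject_if_over_k"),
                         max_missing = 10L) {
  missing_policy <- match.arg(missing_policy)
  validate_schema(schema)
  m <- item_matrix(responses, schema$item_id)
  n_miss <- rowSums(is.na(m))
  if (missing_policy == "reject_if_over_k" && any(n_miss > max_missing)) {
    bad <- which(n_miss > max_missing)
    stop(length(bad), " respondent(s) skipped more than ", max_missing,
         " items (rows ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", ")")
  }
  score <- as.integer(rowSums(m, na.rm = TRUE))
  out <- data.frame(score = score, positive = score >= cutpoint)
  attr(out, "cutpoint") <- as.integer(cutpoint)
  out
}

#' Score the three-item screener
#'
#' One point per endorsed act, regardless of frequency; totals range 0-3.
#' A respondent screens positive when the total reaches the cutpoint.
#'
#' @param responses A data frame (or matrix) whose columns `items` hold
#'   the three screener answers, either binary 0/1 or frequency codes 0-3
#'   (any nonzero frequency counts as endorsement).
#' @param cutpoint Screener cutpoint, one of 1, 2 or 3. Default 1.
#' @param items Column names of the three screener items.
#' @return A data frame with columns `score` (0-3) and `positive`; cutpoint
#'   kept as attribute.
#' @export
score_marsha_c <- function(responses, cutpoint = 1L,
                           items = screener_items()) {
  if (!(length(cutpoint) == 1L && cutpoint %in% 1:3))
    stop("screener cutpoint must be 1, 2 or 3, got ", deparse(cutpoint))
  if (length(items) != 3L) stop("exactly 3 screener items are required")
  m <- item_matrix(responses, items)
  if (anyNA(m)) stop("screener responses must not be missing")
  score <- as.integer(rowSums(m > 0))
  out <- data.frame(score = score, positive = score >= cutpoint)
  attr(out, "cutpoint") <- as.integer(cutpoint)
  out
}

#' Derive screener answers from full-instrument responses
#'
#' On the full instrument the three screener acts are answered on the
#' frequency scale; on the stand-alone clinical form they are yes/no. Any
#' nonzero frequency maps to "yes".
#'
#' @inheritParams score_marsha
#' @param items Identifiers of the three screener items; must exist among
#'   the instrument's item columns.
#' @return A data frame with the three screener columns coded 0/1.
#' @export
derive_marsha_c <- function(responses, items = screener_items()) {
  if (length(items) != 3L) stop("exactly 3 screener items are required")
  miss <- setdiff(items, colnames(responses))
  if (length(miss) > 0)
    stop("unknown screener item identifier(s): ", paste(miss, collapse = ", "))
  m <- item_matrix(responses, items)
  out <- as.data.frame(1L * (m > 0))
  names(out) <- items
  out
}

#' Rank items by endorsement prevalence and pick screener candidates
#'
#' Returns the `k` items with the highest endorsement prevalence (any
#' nonzero frequency) after removing excluded identifiers. Ties are broken
#' lexicographically on the item identifier, so the result is deterministic
#' and invariant to the ordering of respondents.
#'
#' @inheritParams score_marsha
#' @param k Number of items to select. Default 3.
#' @param exclusions Item identifiers barred from selection; defaults to
#'   the schema's `screener_excluded` items.
#' @return Character vector of `k` item identifiers, most prevalent first.
#' @export
select_screener_items <- function(responses, schema = marsha_schema(),
                                  k = 3L, exclusions = NULL) {
  validate_schema(schema)
  if (nrow(responses) == 0L) stop("cohort must be nonempty")
  if (is.null(exclusions))
    exclusions <- schema$item_id[schema$screener_excluded]
  ids <- setdiff(schema$item_id, exclusions)
  if (k > length(ids))
    stop("k = ", k, " exceeds the ", length(ids), " non-excluded items")
  if (k == 0L) return(character(0))
  m <- item_matrix(responses, ids)
  prev <- colMeans(m > 0, na.rm = TRUE)
  ord <- order(-prev, ids)
  ids[ord][seq_len(k)]
}

#' Proportion of respondents endorsing at least one item per group
#'
#' Used both for the five psychometric subscales and for the reporting
#' categories (physical, sexual, emotional, technology-facilitated abuse).
#'
#' @inheritParams score_marsha
#' @param map Named character vector or two-column data frame mapping
#'   `item_id` to a group label; defaults to the schema's reporting
#'   categories.
#' @return Named numeric vector of proportions in \[0, 1\], one per group.
#' @export
subscale_prevalence <- function(responses, map = NULL,
                                schema = marsha_schema()) {
  if (nrow(responses) == 0L) stop("cohort must be nonempty")
  if (is.null(map)) {
    map <- stats::setNames(schema$category, schema$item_id)
  } else if (is.data.frame(map)) {
    map <- stats::setNames(map[[2L]], map[[1L]])
  }
  miss <- setdiff(names(map), colnames(responses))
  if (length(miss) > 0)
    stop("items absent from responses: ", paste(miss, collapse = ", "))
  groups <- sort(unique(unname(map)))
  out <- vapply(groups, function(g) {
    m <- item_matrix(responses, names(map)[map == g])
    mean(rowSums(m > 0, na.rm = TRUE) > 0)
  }, numeric(1))
  stats::setNames(out, groups)
}

#' Cronbach's alpha for a set of ordinal items
#'
#' Convenience internal-consistency summary for the full victimization
#' scale; listwise-deletes incomplete rows.
#'
#' @inheritParams score_marsha
#' @param items Item columns to include; default all schema items.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(responses, items = NULL,
                           schema = marsha_schema()) {
  if (is.null(items)) items <- schema$item_id
  m <- item_matrix(responses, items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 complete rows")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / stats::var(rowSums(m)))
}

# Pull item columns as a numeric matrix, validating codes are in 0..3.
item_matrix <- function(responses, ids) {
  miss <- setdiff(ids, colnames(responses))
  if (length(miss) > 0)
    stop("responses are missing item column(s): ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  m <- as.matrix(as.data.frame(responses)[, ids, drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- !is.na(m) & !(m %in% 0:3)
  if (any(bad))
    stop("item codes must be integers in 0..3 (or NA); offending value(s): ",
         paste(utils::head(unique(m[bad]), 5L), collapse = ", "))
  m
}
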