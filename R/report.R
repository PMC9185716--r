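#' Half-up decimal rounding
#'
#' The published tables round 0.5 upward; R's `round()` rounds half to
#' even, so report rendering uses this instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places. Default 0.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a printed percentage
#'
#' @param p Proportion in \[0, 1\] (or `NA`).
#' @param digits Decimal places (half-up rounding). Default 1.
#' @return Character, e.g. `"83.8%"`; `"NA (zero denominator)"` for `NA`.
#' @export
fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA (zero denominator)",
         sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits)))
}

fmt_pct_ci <- function(v, digits = 1) {
  if (is.na(v$estimate)) return("NA (zero denominator)")
  sprintf("%s (%s-%s)", fmt_pct(v$estimate, digits),
          fmt_pct(v$lower, digits), fmt_pct(v$upper, digits))
}

#' Screener accuracy table across cutpoints
#'
#' One row per screener cutpoint with the screen-positive rate and
#' sensitivity, specificity, PPV and NPV, each formatted as
#' `"estimate% (lower%-upper%)"` with exact confidence intervals, plus
#' likelihood ratios and post-test odds. Percentages are rounded half-up to
#' one decimal, matching the publication style.
#'
#' @param reference Logical reference classes.
#' @param score Integer screener scores (0-3).
#' @param cutpoints Cutpoints to tabulate. Default 1:3.
#' @param level Confidence level.
#' @return A list with `formatted` (character data frame) and `numeric`
#'   (unrounded values, same rows) and `metrics` (per-cutpoint
#'   [dx_metrics()] objects).
#' @export
render_cutpoint_table <- function(reference, score, cutpoints = 1:3,
                                  level = 0.95) {
  mets <- lapply(cutpoints, function(cp) {
    dx_metrics(confusion_table(reference, score >= cp), level = level)
  })
  names(mets) <- as.character(cutpoints)
  fm <- do.call(rbind, lapply(seq_along(cutpoints), function(i) {
    m <- mets[[i]]
    data.frame(
      cutpoint = cutpoints[i],
      pct_screen_positive = fmt_pct(m$screen_positive_rate),
      sensitivity = fmt_pct_ci(m$sensitivity),
      specificity = fmt_pct_ci(m$specificity),
      ppv = fmt_pct_ci(m$ppv),
      npv = fmt_pct_ci(m$npv),
      lr_positive = ifelse(is.finite(m$lr_positive),
                           sprintf("%.2f", round_half_up(m$lr_positive, 2)),
                           "Inf"),
      post_test_odds = ifelse(is.finite(m$post_test_odds),
                              sprintf("%.2f", round_half_up(m$post_test_odds, 2)),
                              "Inf")
    )
  }))
  num <- do.call(rbind, lapply(seq_along(cutpoints), function(i) {
    m <- mets[[i]]
    data.frame(
      cutpoint = cutpoints[i],
      screen_positive_rate = m$screen_positive_rate,
      sensitivity = m$sensitivity$estimate,
      sensitivity_lower = m$sensitivity$lower,
      sensitivity_upper = m$sensitivity$upper,
      specificity = m$specificity$estimate,
      specificity_lower = m$specificity$lower,
      specificity_upper = m$specificity$upper,
      ppv = m$ppv$estimate, ppv_lower = m$ppv$lower, ppv_upper = m$ppv$upper,
      npv = m$npv$estimate, npv_lower = m$npv$lower, npv_upper = m$npv$upper,
      accuracy = m$accuracy$estimate,
      lr_positive = m$lr_positive,
      lr_negative = m$lr_negative,
      post_test_odds = m$post_test_odds
    )
  }))
  list(formatted = fm, numeric = num, metrics = mets)
}

#' Subgroup accuracy table at a fixed cutpoint
#'
#' Formats a [subgroup_analysis()] result publication-style: percentages to
#' one decimal (half-up), single-cutpoint ROC areas to three decimals.
#'
#' @param sub A [subgroup_analysis()] result.
#' @return A list with `formatted` (character data frame) and `numeric`
#'   (the input, unrounded).
#' @export
render_subgroup_table <- function(sub) {
  fm <- data.frame(
    group = sub$group,
    n = sub$n,
    prevalence = fmt_pct(sub$prevalence),
    screen_positive_rate = fmt_pct(sub$screen_positive_rate),
    sensitivity = fmt_pct(sub$sensitivity),
    specificity = fmt_pct(sub$specificity),
    roc_area = ifelse(is.na(sub$roc_area_single), "NA (zero denominator)",
                      sprintf("%.3f", round_half_up(sub$roc_area_single, 3))),
    ppv = fmt_pct(sub$ppv),
    npv = fmt_pct(sub$npv),
    accuracy = fmt_pct(sub$accuracy),
    exploratory = ifelse(sub$exploratory, "yes", "no")
  )
  list(formatted = fm, numeric = sub)
}

#' Write a rendered table as CSV and JSON
#'
#' Both files carry identical numbers: the CSV holds the formatted table,
#' the JSON holds both the formatted strings and the unrounded numeric
#' values.
#'
#' @param rendered A [render_cutpoint_table()] or [render_subgroup_table()]
#'   result.
#' @param stem Output path without extension; `<stem>.csv` and
#'   `<stem>.json` are written.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(rendered, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(rendered$formatted, csv, row.names = FALSE)
  payload <- list(formatted = rendered$formatted,
                  numeric = as.data.frame(rendered$numeric))
  jsonlite::write_json(payload, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
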