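#' Build a 2x2 confusion table from paired classifications
#'
#' @param reference Logical (or 0/1) vector of reference-standard classes.
#' @param screen Logical (or 0/1) vector of screener classes, same length.
#' @return An object of class `confusion_table`: a list with integer counts
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_table(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_table <- function(reference, screen) {
  if (length(reference) != length(screen))
    stop("reference and screen classifications must have equal length (",
         length(reference), " vs ", length(screen), ")")
  if (anyNA(reference) || anyNA(screen))
    stop("classifications must not contain NA")
  r <- as.logical(reference); s <- as.logical(screen)
  new_confusion_table(sum(r & s), sum(r & !s), sum(!r & s), sum(!r & !s))
}

#' @rdname confusion_table
#' @param tp,fn,fp,tn Non-negative integer cell counts (true positive,
#'   false negative, false positive, true negative).
#' @export
new_confusion_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion-table cells must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(reference = c("positive", "negative"),
                              screen = c("positive", "negative")))
  cat("2x2 confusion table (n = ", sum(unlist(x)), ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities through the beta quantile
#' function. At the boundaries the one-sided convention applies: zero
#' successes give a lower bound of 0, all successes an upper bound of 1.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level, default 0.95.
#' @return A list with `estimate`, `lower`, `upper`, `level`.
#' @export
#' @examples
#' exact_binomial_ci(98, 117)   # lower ~0.758, upper ~0.899
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  list(estimate = successes / trials, lower = lower, upper = upper,
       level = level)
}

#' Diagnostic-accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy, each with a Clopper-Pearson interval on its own denominator,
#' plus likelihood ratios, post-test odds, the screen-positive rate and the
#' single-cutpoint ROC area (sensitivity + specificity) / 2.
#'
#' A metric whose denominator is zero is reported as `NA` with the reason
#' recorded in `undefined`, never silently as 0 or 1.
#'
#' @param table A [confusion_table()].
#' @param level Confidence level for the intervals. Default 0.95.
#' @param prevalence Pre-test prevalence used for the post-test odds;
#'   defaults to the sample reference prevalence (tp + fn) / n.
#' @return An object of class `dx_metrics`: a list of per-metric lists
#'   (`estimate`, `lower`, `upper`, `successes`, `trials`) plus
#'   `lr_positive`, `lr_negative`, `post_test_odds`, `prevalence`,
#'   `screen_positive_rate`, `roc_area_single`, `n` and `undefined`.
#' @export
dx_metrics <- function(table, level = 0.95, prevalence = NULL) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop("cannot compute metrics on an empty table")
  undefined <- character(0)
  prop <- function(x, d, what) {
    if (d == 0) {
      undefined <<- c(undefined, sprintf("%s (zero denominator)", what))
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  successes = x, trials = d))
    }
    ci <- exact_binomial_ci(x, d, level)
    list(estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
         successes = x, trials = d)
  }
  sens <- prop(tp, tp + fn, "sensitivity")
  spec <- prop(tn, tn + fp, "specificity")
  ppv  <- prop(tp, tp + fp, "ppv")
  npv  <- prop(tn, tn + fn, "npv")
  acc  <- prop(tp + tn, n, "accuracy")
  if (is.null(prevalence)) prevalence <- (tp + fn) / n
  lr <- likelihood_ratios(table, prevalence = prevalence)
  roc1 <- if (is.na(sens$estimate) || is.na(spec$estimate)) NA_real_
          else (sens$estimate + spec$estimate) / 2
  structure(list(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    accuracy = acc,
    lr_positive = lr$lr_positive, lr_negative = lr$lr_negative,
    post_test_odds = lr$post_test_odds,
    prevalence = prevalence,
    screen_positive_rate = (tp + fp) / n,
    roc_area_single = roc1,
    n = n, level = level, table = table, undefined = undefined
  ), class = "dx_metrics")
}

#' @export
print.dx_metrics <- function(x, ...) {
  cat("Diagnostic accuracy (n = ", x$n, ", ", round(100 * x$level),
      "% exact CIs)\n", sep = "")
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    v <- x[[m]]
    if (is.na(v$estimate)) {
      cat(sprintf("  %-11s NA (zero denominator)\n", m))
    } else {
      cat(sprintf("  %-11s %s (%s-%s)  [%d/%d]\n", m,
                  fmt_pct(v$estimate), fmt_pct(v$lower), fmt_pct(v$upper),
                  v$successes, v$trials))
    }
  }
  cat(sprintf("  LR+ %.2f, LR- %.2f, post-test odds %.2f (prevalence %s)\n",
              x$lr_positive, x$lr_negative, x$post_test_odds,
              fmt_pct(x$prevalence)))
  cat(sprintf("  screen-positive rate %s, single-cutpoint ROC area %.3f\n",
              fmt_pct(x$screen_positive_rate), x$roc_area_single))
  invisible(x)
}

#' Likelihood ratios and post-test odds
#'
#' `LR+ = sensitivity / (1 - specificity)` (reported as `Inf` when
#' specificity is 1), `LR- = (1 - sensitivity) / specificity`, and the
#' positive post-test odds are the pre-test odds multiplied by LR+.
#'
#' @inheritParams dx_metrics
#' @return A list with `lr_positive`, `lr_negative`, `post_test_odds`,
#'   `prevalence`.
#' @export
likelihood_ratios <- function(table, prevalence = NULL) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  lr_pos <- if (is.na(sens) || is.na(spec)) NA_real_
            else if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (is.na(sens) || is.na(spec)) NA_real_
            else if (spec == 0) Inf else (1 - sens) / spec
  if (is.null(prevalence)) {
    n <- tp + fn + fp + tn
    prevalence <- if (n > 0) (tp + fn) / n else NA_real_
  }
  pre_odds <- prevalence / (1 - prevalence)
  list(lr_positive = lr_pos, lr_negative = lr_neg,
       post_test_odds = pre_odds * lr_pos, prevalence = prevalence)
}

#' ROC curve over integer screener cutpoints
#'
#' One (sensitivity, false-positive-rate) point per cutpoint; the empirical
#' AUC is the trapezoidal area through (0,0), the cutpoint points ordered
#' by FPR then sensitivity, and (1,1).
#'
#' @param score Integer screener scores in 0..3 (or 0..max cutpoint).
#' @param reference Logical/0-1 reference classes, same length.
#' @param cutpoints Integer cutpoints to evaluate. Default 1:3.
#' @return An object of class `roc_analysis`: list with `points` (data
#'   frame: cutpoint, sensitivity, specificity, fpr), `auc_empirical`, and
#'   the input counts.
#' @export
roc_curve <- function(score, reference, cutpoints = 1:3) {
  if (length(score) != length(reference))
    stop("score and reference must have equal length")
  r <- as.logical(reference)
  if (all(r) || !any(r))
    stop("reference must contain both positives and negatives")
  pts <- do.call(rbind, lapply(sort(unique(as.integer(cutpoints))), function(cp) {
    tab <- confusion_table(r, score >= cp)
    data.frame(cutpoint = cp,
               sensitivity = tab$tp / (tab$tp + tab$fn),
               specificity = tab$tn / (tab$tn + tab$fp),
               fpr = tab$fp / (tab$tn + tab$fp))
  }))
  path <- rbind(data.frame(fpr = 0, sensitivity = 0),
                pts[order(pts$fpr, pts$sensitivity), c("fpr", "sensitivity")],
                data.frame(fpr = 1, sensitivity = 1))
  auc <- sum(diff(path$fpr) *
               (utils::head(path$sensitivity, -1) + utils::tail(path$sensitivity, -1)) / 2)
  structure(list(points = pts, auc_empirical = auc,
                 n_positive = sum(r), n_negative = sum(!r)),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("ROC over cutpoints (", x$n_positive, " positives, ", x$n_negative,
      " negatives)\n", sep = "")
  print(x$points, row.names = FALSE)
  cat(sprintf("empirical (trapezoidal) AUC: %.3f\n", x$auc_empirical))
  invisible(x)
}

#' Select the optimal screener cutpoint from a ROC analysis
#'
#' `"closest_to_corner"` (default) minimises the Euclidean distance of the
#' ROC point to the top-left corner (FPR 0, sensitivity 1);
#' `"youden"` maximises sensitivity + specificity - 1. Ties resolve to the
#' smaller cutpoint.
#'
#' @param roc A [roc_curve()] result.
#' @param rule Selection rule.
#' @return The selected integer cutpoint.
#' @export
select_cutpoint <- function(roc, rule = c("closest_to_corner", "youden")) {
  rule <- match.arg(rule)
  stopifnot(inherits(roc, "roc_analysis"))
  pts <- roc$points
  if (nrow(pts) == 0L) stop("ROC analysis has no cutpoint points")
  crit <- switch(rule,
    closest_to_corner = sqrt(pts$fpr^2 + (1 - pts$sensitivity)^2),
    youden = -(pts$sensitivity + pts$specificity - 1)
  )
  pts$cutpoint[order(crit, pts$cutpoint)][1L]
}

#' Diagnostic accuracy by demographic subgroup
#'
#' Recomputes the screener-vs-reference confusion table within each level
#' of a demographic variable at a fixed cutpoint, plus a full-sample row.
#' Groups smaller than `min_n` are flagged exploratory (by default the
#' sample-size requirement for estimating sensitivity to a 0.10 margin at
#' the study's anticipated values, see [required_total()]). A group with no
#' positives or no negatives keeps its row with the affected metrics `NA`.
#'
#' @param data Data frame with one row per respondent.
#' @param group Name of the grouping column in `data`.
#' @param reference,score Names of the columns holding the reference class
#'   (logical/0-1) and the screener score (0-3).
#' @param cutpoint Screener cutpoint. Default 1.
#' @param min_n Minimum group size to be considered adequately powered.
#' @param level Confidence level.
#' @return A data frame with one row per group (full sample first):
#'   `group`, `n`, `prevalence` (reference), `screen_positive_rate`,
#'   `sensitivity`, `specificity`, `roc_area_single`, `ppv`, `npv`,
#'   `accuracy`, `exploratory`. The per-group `dx_metrics` objects are
#'   attached as the `"metrics"` attribute.
#' @export
subgroup_analysis <- function(data, group, reference = "ref_positive",
                              score = "screen_score", cutpoint = 1L,
                              min_n = required_total(), level = 0.95) {
  for (col in c(group, reference, score))
    if (!col %in% names(data)) stop("column not found: ", col)
  groups <- c(list(`Full sample` = data),
              split(data, data[[group]]))
  rows <- list(); mets <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    tab <- confusion_table(d[[reference]], d[[score]] >= cutpoint)
    m <- dx_metrics(tab, level = level)
    mets[[g]] <- m
    rows[[g]] <- data.frame(
      group = g, n = m$n, prevalence = m$prevalence,
      screen_positive_rate = m$screen_positive_rate,
      sensitivity = m$sensitivity$estimate,
      specificity = m$specificity$estimate,
      roc_area_single = m$roc_area_single,
      ppv = m$ppv$estimate, npv = m$npv$estimate,
      accuracy = m$accuracy$estimate,
      exploratory = g != "Full sample" && m$n < min_n
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "metrics") <- mets
  attr(out, "cutpoint") <- as.integer(cutpoint)
  out
}

#' Reconstruct an integer 2x2 table from printed rounded metrics
#'
#' Searches every integer table with the given total `n` and number of
#' reference positives, scoring each candidate by the maximum absolute
#' deviation of its metrics from the printed (rounded) values, and returns
#' the minimiser. Used to recover the study's cutpoint-1 table from the
#' published percentages; the search also reports whether the minimiser is
#' unique.
#'
#' @param n Total sample size.
#' @param positives Number of reference positives.
#' @param targets Named numeric vector of printed metric values (as
#'   proportions) among `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`.
#' @return The best [confusion_table()]; attributes `max_deviation` (its
#'   deviation score) and `unique` (no other table ties within 1e-12).
#' @export
#' @examples
#' reconstruct_confusion_table(224, 117,
#'   c(sensitivity = 0.838, specificity = 0.907, ppv = 0.907,
#'     npv = 0.836, accuracy = 0.871))
reconstruct_confusion_table <- function(n, positives, targets) {
  negatives <- n - positives
  if (negatives < 0) stop("positives cannot exceed n")
  ok <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  if (!all(names(targets) %in% ok))
    stop("unknown target metric(s): ",
         paste(setdiff(names(targets), ok), collapse = ", "))
  grid <- expand.grid(tp = 0:positives, fp = 0:negatives)
  tp <- grid$tp; fp <- grid$fp
  fn <- positives - tp; tn <- negatives - fp
  cand <- cbind(
    sensitivity = tp / positives,
    specificity = tn / negatives,
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    npv = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_),
    accuracy = (tp + tn) / n
  )
  dev <- apply(abs(cand[, names(targets), drop = FALSE] -
                     rep(targets, each = nrow(cand))), 1, max)
  dev[is.na(dev)] <- Inf
  best <- which.min(dev)
  out <- new_confusion_table(tp[best], fn[best], fp[best], tn[best])
  attr(out, "max_deviation") <- dev[best]
  attr(out, "unique") <- sum(dev <= dev[best] + 1e-12) == 1L
  out
}
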