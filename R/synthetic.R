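#' Generator configuration for synthetic respondent cohorts
#'
#' The generator draws a single standard-normal latent severity per
#' respondent; item `j` is endorsed when `a_j * z + e_j` exceeds a
#' calibrated threshold (`e_j` independent standard normal — a one-factor
#' probit model), and endorsed items receive frequency categories 1-3 by
#' equal-probability splits of the endorsed region. Demographics are drawn
#' independently of severity from the configured categorical margins.
#'
#' Item thresholds are calibrated so that the marginal endorsement
#' prevalences hit the published values for the four named items and the
#' category-level any-endorsement totals (physical 17%, sexual 25%,
#' emotional 35%, technology-facilitated 43%) for the placeholder items.
#'
#' @param n Cohort size. Default 224, the study's analytic sample size.
#' @param schema Instrument schema, see [marsha_schema()].
#' @param discrimination Factor loading(s) `a` of the items on the latent
#'   severity: a scalar or one value per item. The default (`NULL`) uses
#'   2.4 for the three screener items and 0.7 for the rest, values fixed by
#'   a one-off calibration run so the cutpoint-1 sensitivity and
#'   specificity of the derived screener sit near the study's estimates
#'   (0.84 and 0.91).
#' @param category_targets Named vector of any-endorsement targets for the
#'   reporting categories whose placeholder-item prevalences are
#'   calibrated.
#' @param demo_margins Named list of categorical demographic margins, see
#'   [study_demo_margins()].
#' @param zip_table Zip/state lookup used to fabricate consistent QC
#'   metadata, see [read_zip_table()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 224L, schema = marsha_schema(),
                             discrimination = NULL,
                             category_targets = c(physical = 0.17,
                                                  sexual = 0.25,
                                                  emotional = 0.35,
                                                  technology = 0.43),
                             demo_margins = study_demo_margins(),
                             zip_table = read_zip_table()) {
  validate_schema(schema)
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer")
  if (is.null(discrimination))
    discrimination <- ifelse(schema$screener, 2.4, 0.7)
  if (any(discrimination < 0)) stop("discrimination must be >= 0")
  if (!(length(discrimination) %in% c(1L, nrow(schema))))
    stop("discrimination must be a scalar or one value per item")
  if (any(category_targets <= 0 | category_targets >= 1))
    stop("category targets must lie strictly in (0, 1)")
  free <- is.na(schema$target_prevalence)
  uncovered <- setdiff(unique(schema$category[free]), names(category_targets))
  if (length(uncovered) > 0)
    stop("items without a prevalence target in category(ies) without a ",
         "category target: ", paste(uncovered, collapse = ", "))
  for (m in demo_margins) {
    if (abs(sum(m) - 1) > 1e-9)
      stop("each demographic margin must sum to 1")
    if (any(m < 0)) stop("demographic margins must be non-negative")
  }
  structure(list(n = as.integer(n), schema = schema,
                 discrimination = rep(discrimination,
                                      length.out = nrow(schema)),
                 category_targets = category_targets,
                 demo_margins = demo_margins, zip_table = zip_table),
            class = "generator_config")
}

#' Demographic margins of the study sample
#'
#' Categorical distributions matching the published full-sample
#' demographics: age band, gender, race/ethnicity, sexual orientation,
#' census region and relationship status. Margins are normalised to sum
#' to 1.
#'
#' @return Named list of named probability vectors.
#' @export
study_demo_margins <- function() {
  norm <- function(x) x / sum(x)
  list(
    age_band = norm(c(`11-16` = 21.4, `17-21` = 78.6)),
    gender = norm(c(male = 20.1, female = 76.8, nonbinary_or_other = 3.1)),
    race_ethnicity = norm(c(asian = 19.5, black = 11.6, latinx = 18.1,
                            white = 40.5, multiracial = 7.4, other = 2.8)),
    sexual_orientation = norm(c(lgb = 29.5, heterosexual = 70.5)),
    region = norm(c(northeast = 65.3, midwest = 3.6, south = 17.6,
                    west = 13.5)),
    relationship_status = norm(c(single = 79.4, cohabiting = 9.6,
                                 other = 11.0))
  )
}

# Closed-form marginal endorsement probability of one item:
# P(a z + e > tau) with z, e iid N(0,1).
marginal_prevalence <- function(tau, a) {
  stats::pnorm(tau / sqrt(1 + a^2), lower.tail = FALSE)
}

# P(at least one of the items with thresholds `taus` and loadings `a`
# endorsed), integrating the shared latent factor out numerically.
any_endorsed_prob <- function(taus, a) {
  a <- rep(a, length.out = length(taus))
  f <- function(z) {
    lp <- matrix(taus, nrow = length(z), ncol = length(taus), byrow = TRUE) -
      z %o% a                                 # tau_j - a_j z, rows = z
    stats::dnorm(z) * exp(rowSums(stats::pnorm(lp, log.p = TRUE)))
  }
  1 - stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Calibrate item thresholds to the prevalence targets
#'
#' Each item's endorsement threshold is found by monotone root-finding on
#' its marginal endorsement probability under the latent model. Items with
#' a fixed `target_prevalence` are calibrated directly; placeholder items
#' (`NA` target) share a per-category prevalence that is solved in an outer
#' root-find so the category's any-endorsement probability matches its
#' target. Frequency-category cutoffs split each item's endorsed region
#' into three equal-probability slices.
#'
#' @param config A [generator_config()].
#' @param tolerance Maximum allowed |achieved - target| per item. Default
#'   0.005.
#' @param max_iter Iteration cap for each root-find. Default 200.
#' @return An object of class `calibration_result`: data frame `items`
#'   (item_id, target, threshold, cut1, cut2, achieved), plus
#'   `category_achieved` and `max_abs_deviation`.
#' @export
calibrate_thresholds <- function(config, tolerance = 0.005, max_iter = 200L) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  a <- config$discrimination
  s <- sqrt(1 + a^2)

  solve_tau <- function(p, i) {
    stats::uniroot(function(tau) marginal_prevalence(tau, a[i]) - p,
                   interval = c(-12, 12) * s[i], tol = 1e-12,
                   maxiter = max_iter)$root
  }

  target <- schema$target_prevalence
  # Outer solve: shared prevalence of each category's free items so the
  # category any-endorsement probability hits its target.
  for (cat in names(config$category_targets)) {
    in_cat <- schema$category == cat
    free <- in_cat & is.na(target)
    if (!any(free)) next
    pinned_idx <- which(in_cat & !is.na(target))
    free_idx <- which(free)
    g <- function(p) {
      taus <- c(vapply(pinned_idx, function(i) solve_tau(target[i], i),
                       numeric(1)),
                vapply(free_idx, function(i) solve_tau(p, i), numeric(1)))
      any_endorsed_prob(taus, a[c(pinned_idx, free_idx)]) -
        config$category_targets[[cat]]
    }
    lo <- 1e-6; hi <- config$category_targets[[cat]]
    if (g(hi) < 0 || g(lo) > 0)
      stop("category '", cat, "' target ", config$category_targets[[cat]],
           " is not attainable given its pinned item prevalences")
    target[free_idx] <- stats::uniroot(g, c(lo, hi), tol = 1e-9,
                                       maxiter = max_iter)$root
  }
  if (anyNA(target))
    stop("items without prevalence target after category calibration: ",
         paste(schema$item_id[is.na(target)], collapse = ", "))

  tau <- vapply(seq_len(nrow(schema)),
                function(i) solve_tau(target[i], i), numeric(1))
  achieved <- marginal_prevalence(tau, a)
  dev <- abs(achieved - target)
  if (any(dev > tolerance))
    stop("calibration failed for item(s): ",
         paste(schema$item_id[dev > tolerance], collapse = ", "))
  items <- data.frame(
    item_id = schema$item_id, target = target, threshold = tau,
    cut1 = s * stats::qnorm(1 - 2 * target / 3),
    cut2 = s * stats::qnorm(1 - target / 3),
    achieved = achieved
  )
  cat_achieved <- vapply(names(config$category_targets), function(cat) {
    idx <- which(schema$category == cat)
    any_endorsed_prob(tau[idx], a[idx])
  }, numeric(1))
  structure(list(items = items, category_achieved = cat_achieved,
                 max_abs_deviation = max(dev)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Threshold calibration: max |achieved - target| = ",
      format(x$max_abs_deviation, digits = 3), "\n", sep = "")
  cat("Category any-endorsement rates:\n")
  print(round(x$category_achieved, 4))
  invisible(x)
}

#' Generate a synthetic respondent cohort
#'
#' Draws `config$n` clean, eligible, consenting records: latent-trait item
#' responses (see [generator_config()]), demographics from the configured
#' margins, and internally consistent QC metadata (zip/state/coordinates
#' from the lookup table, US IP, plausible open-text answers, unique
#' duplicate keys). Fully reproducible: the same seed and configuration
#' give an identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param calibration Optional pre-computed [calibrate_thresholds()] result
#'   (saves recomputation across repeated draws).
#' @return A data frame with one row per respondent: QC metadata,
#'   demographics (`age_years`, `gender`, `race_ethnicity`,
#'   `sexual_orientation`, `region`, `relationship_status`) and the 34 item
#'   columns coded 0-3. The calibration is attached as the `"calibration"`
#'   attribute and the configuration as `"config"`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L,
                            calibration = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(calibration)) calibration <- calibrate_thresholds(config)
  n <- config$n
  schema <- config$schema
  set.seed(seed)

  items <- matrix(0L, nrow = n, ncol = nrow(schema),
                  dimnames = list(NULL, schema$item_id))
  if (n > 0) {
    z <- stats::rnorm(n)
    for (j in seq_len(nrow(schema))) {
      sj <- config$discrimination[j] * z + stats::rnorm(n)
      cal <- calibration$items[j, ]
      items[, j] <- (sj > cal$threshold) + (sj > cal$cut1) + (sj > cal$cut2)
    }
  }

  demo <- draw_demographics(n, config$demo_margins)
  qc <- draw_clean_metadata(n, config$zip_table)
  out <- cbind(qc, demo, as.data.frame(items))
  attr(out, "calibration") <- calibration
  attr(out, "config") <- config
  out
}

draw_demographics <- function(n, margins) {
  draw <- function(m) {
    if (n == 0) return(character(0))
    sample(names(m), n, replace = TRUE, prob = m)
  }
  band <- draw(margins$age_band)
  # Within-band age weights skew older, reproducing the study's mean age
  # (about 18.6 years) under the published band margins.
  age <- integer(n)
  young <- band == "11-16"
  if (any(young))
    age[young] <- sample(11:16, sum(young), replace = TRUE,
                         prob = c(1, 1, 2, 3, 4, 5))
  if (any(!young))
    age[!young] <- sample(17:21, sum(!young), replace = TRUE,
                          prob = c(1, 2, 3, 4, 5))
  data.frame(
    age_years = age,
    age_band = band,
    gender = draw(margins$gender),
    race_ethnicity = draw(margins$race_ethnicity),
    sexual_orientation = draw(margins$sexual_orientation),
    region = draw(margins$region),
    relationship_status = draw(margins$relationship_status)
  )
}

clean_text_phrases <- function() {
  c("we mostly get along fine", "my partner is usually kind to me",
    "sometimes we argue about small things", "i met them at school",
    "we have been together about a year", "they help me with homework",
    "we like watching movies together", "i feel safe with them",
    "we text every day after class", "nothing else to add really")
}

draw_clean_metadata <- function(n, zip_table) {
  zi <- sample(nrow(zip_table), n, replace = TRUE)
  txt <- matrix(sample(clean_text_phrases(), 5 * n, replace = TRUE), n, 5)
  out <- data.frame(
    record_id = sprintf("r%06d", seq_len(n)),
    us_resident = rep(1L, n),
    dated_past_year = rep(1L, n),
    prior_completion = rep(0L, n),
    skipped_count = sample(0:3, n, replace = TRUE,
                           prob = c(0.7, 0.15, 0.1, 0.05)),
    timed_out = rep(0L, n),
    consented = rep(1L, n),
    zip = zip_table$zip[zi],
    state = zip_table$state[zi],
    ip_country = rep("US", n),
    ip_lat = zip_table$lat[zi] + stats::runif(n, -0.3, 0.3),
    ip_long = zip_table$long[zi] + stats::runif(n, -0.3, 0.3),
    duplicate_key = sprintf("key-%06d", seq_len(n))
  )
  for (k in 1:5) out[[paste0("open_text_", k)]] <- txt[, k]
  out
}

#' Contamination profile matching the published recruitment flow
#'
#' Per-category record counts reproducing the recruitment diagram: 162
#' ineligible entries (19 prior completions, 90 without a past-year dating
#' relationship, 18 out of the age range, 26 skipping more than 10
#' questions, 2 non-US residents, 7 timeouts), 8 eligible non-consenters,
#' and 177 fraud-flagged responses. The diagram gives only the fraud total;
#' the per-rule split used here (45/40/35/30/27) is a package convention.
#'
#' @return A list with integer vectors `ineligible` and `fraud` and scalar
#'   `non_consent`.
#' @export
study_contamination <- function() {
  list(
    ineligible = c(prior_completion = 19L, no_dating = 90L, age = 18L,
                   skipped_gt10 = 26L, non_us = 2L, timed_out = 7L),
    non_consent = 8L,
    fraud = c(zip_state_mismatch = 45L, blank_or_nonsense_text = 40L,
              foreign_ip = 35L, duplicate = 30L, geo_mismatch = 27L)
  )
}

#' Append contaminated records to a clean cohort
#'
#' Fabricates records that each violate exactly one eligibility rule,
#' withhold consent, or trigger exactly one fraud rule, and are otherwise
#' indistinguishable from clean records. Contaminated records are appended
#' after the cohort (duplicate-key copies therefore flag the appended
#' record, not its clean original). With an all-zero contamination spec the
#' cohort is returned unchanged.
#'
#' @param cohort A cohort from [generate_cohort()] (its `"config"`
#'   attribute supplies the generator settings for the fabricated records).
#' @param contamination A spec shaped like [study_contamination()].
#' @param seed Integer seed for the fabricated records.
#' @return The augmented data frame; the contamination spec is attached as
#'   the `"contamination"` attribute.
#' @export
inject_contamination <- function(cohort, contamination = study_contamination(),
                                 seed = 2L) {
  config <- attr(cohort, "config")
  if (is.null(config))
    stop("cohort must carry a \"config\" attribute (see generate_cohort)")
  if (any(contamination$ineligible < 0) || any(contamination$fraud < 0) ||
      contamination$non_consent < 0)
    stop("contamination counts must be non-negative")
  total <- sum(contamination$ineligible) + contamination$non_consent +
    sum(contamination$fraud)
  if (total == 0L) return(cohort)

  base_cfg <- config
  base_cfg$n <- total
  extra <- generate_cohort(base_cfg, seed = seed,
                           calibration = attr(cohort, "calibration"))
  extra$record_id <- sprintf("c%06d", seq_len(total))
  extra$duplicate_key <- sprintf("ckey-%06d", seq_len(total))

  set.seed(seed + 1L)
  i <- 0L
  take <- function(k) {
    rows <- i + seq_len(k); i <<- i + k; rows
  }
  r <- take(contamination$ineligible[["prior_completion"]])
  extra$prior_completion[r] <- 1L
  r <- take(contamination$ineligible[["no_dating"]])
  extra$dated_past_year[r] <- 0L
  r <- take(contamination$ineligible[["age"]])
  extra$age_years[r] <- sample(c(8:10, 22:30), length(r), replace = TRUE)
  r <- take(contamination$ineligible[["skipped_gt10"]])
  extra$skipped_count[r] <- sample(11:30, length(r), replace = TRUE)
  r <- take(contamination$ineligible[["non_us"]])
  extra$us_resident[r] <- 0L
  r <- take(contamination$ineligible[["timed_out"]])
  extra$timed_out[r] <- 1L
  r <- take(contamination$non_consent)
  extra$consented[r] <- 0L

  zt <- config$zip_table
  r <- take(contamination$fraud[["zip_state_mismatch"]])
  for (j in r) {
    others <- setdiff(unique(zt$state), extra$state[j])
    extra$state[j] <- sample(others, 1L)
  }
  r <- take(contamination$fraud[["blank_or_nonsense_text"]])
  for (k in 1:5) extra[[paste0("open_text_", k)]][r] <- ""
  r <- take(contamination$fraud[["foreign_ip"]])
  extra$ip_country[r] <- sample(c("CA", "GB", "IN", "NG"), length(r),
                                replace = TRUE)
  r <- take(contamination$fraud[["duplicate"]])
  extra$duplicate_key[r] <- sample(cohort$duplicate_key, length(r),
                                   replace = TRUE)
  r <- take(contamination$fraud[["geo_mismatch"]])
  extra$ip_lat[r] <- extra$ip_lat[r] + 15
  extra$ip_long[r] <- extra$ip_long[r] + 20

  out <- rbind(cohort, extra)
  attr(out, "calibration") <- attr(cohort, "calibration")
  attr(out, "config") <- config
  attr(out, "contamination") <- contamination
  out
}

#' Generate the full screened sample, contamination included
#'
#' Convenience wrapper: a clean analytic-size cohort plus the published
#' contamination profile, yielding the full set of screened entries the QC
#' flow starts from.
#'
#' @inheritParams generate_cohort
#' @param contamination See [inject_contamination()].
#' @return Data frame of screened records.
#' @export
generate_study_sample <- function(config = generator_config(), seed = 1L,
                                  contamination = study_contamination()) {
  cohort <- generate_cohort(config, seed = seed)
  inject_contamination(cohort, contamination, seed = seed + 1000L)
}

#' Repeated end-to-end accuracy recovery
#'
#' Repeatedly generates a cohort, scores the reference instrument and the
#' derived screener, computes diagnostic accuracy at the given cutpoint and
#' selects the optimal cutpoint from the ROC, summarising the sampling
#' distribution of each metric.
#'
#' @inheritParams generate_cohort
#' @param reps Number of replicate cohorts.
#' @param cutpoint Screener cutpoint for the accuracy metrics. Default 1.
#' @param rule Cutpoint-selection rule, see [select_cutpoint()].
#' @return A list with `per_rep` (one row per replicate: sensitivity,
#'   specificity, accuracy, prevalence, roc_area_single, auc_empirical,
#'   selected_cutpoint), `summary` (mean and Monte-Carlo sd per metric) and
#'   `selection_rate` (proportion of replicates selecting each cutpoint).
#' @export
end_to_end_recovery <- function(config = generator_config(), reps = 50L,
                                seed = 1L, cutpoint = 1L,
                                rule = "closest_to_corner") {
  calibration <- calibrate_thresholds(config)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    cohort <- generate_cohort(config, seed = seed + r,
                              calibration = calibration)
    ref <- score_marsha(cohort, config$schema)
    scr <- score_marsha_c(derive_marsha_c(cohort), cutpoint = cutpoint)
    tab <- confusion_table(ref$positive, scr$positive)
    m <- dx_metrics(tab)
    roc <- roc_curve(scr$score, ref$positive)
    rows[[r]] <- data.frame(
      rep = r,
      sensitivity = m$sensitivity$estimate,
      specificity = m$specificity$estimate,
      accuracy = m$accuracy$estimate,
      prevalence = m$prevalence,
      roc_area_single = m$roc_area_single,
      auc_empirical = roc$auc_empirical,
      selected_cutpoint = select_cutpoint(roc, rule = rule)
    )
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), c("rep", "selected_cutpoint"))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_rep[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_rep[[m]]), numeric(1))
  )
  rownames(summary) <- NULL
  sel <- table(factor(per_rep$selected_cutpoint, levels = 1:3)) / reps
  list(per_rep = per_rep, summary = summary,
       selection_rate = stats::setNames(as.numeric(sel), names(sel)))
}
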