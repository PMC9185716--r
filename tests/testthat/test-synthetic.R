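test_that("threshold calibration matches the closed-form probit marginal", {
  # discrimination 0: threshold sits at the noise median for a 50% target
  sch <- default_schema
  sch$target_prevalence[] <- 0.5
  cfg0 <- generator_config(schema = sch, discrimination = 0,
                           category_targets = c(physical = 0.9)[0])
  expect_error(calibrate_thresholds(cfg0), NA)
  cal0 <- calibrate_thresholds(cfg0)
  expect_equal(cal0$items$threshold, rep(0, 34), tolerance = 1e-8)

  # closed form: tau = qnorm(1 - p) * sqrt(1 + a^2)
  sch$target_prevalence[] <- 0.28
  cfg1 <- generator_config(schema = sch, discrimination = 1)
  cal1 <- calibrate_thresholds(cfg1)
  expect_equal(cal1$items$threshold,
               rep(stats::qnorm(0.72) * sqrt(2), 34), tolerance = 1e-8)

  # random target/discrimination pairs: achieved marginal within tolerance
  set.seed(3)
  for (rep in 1:10) {
    p <- stats::runif(1, 0.05, 0.9); a <- stats::runif(1, 0, 3)
    sch$target_prevalence[] <- p
    cal <- calibrate_thresholds(generator_config(schema = sch,
                                                 discrimination = a))
    expect_equal(cal$items$achieved, rep(p, 34), tolerance = 0.005)
    expect_equal(stats::pnorm(cal$items$threshold[1] / sqrt(1 + a^2),
                              lower.tail = FALSE), p, tolerance = 1e-8)
  }

  # default config: category any-endorsement totals hit their targets
  expect_equal(default_calibration$category_achieved,
               c(physical = 0.17, sexual = 0.25, emotional = 0.35,
                 technology = 0.43), tolerance = 1e-6)
  expect_lt(default_calibration$max_abs_deviation, 0.005)
})

test_that("an unattainable category target fails loudly", {
  sch <- default_schema
  cfg <- generator_config(schema = sch,
                          category_targets = c(physical = 0.17,
                                               sexual = 0.25,
                                               emotional = 0.27,  # below the pinned 0.28 item
                                               technology = 0.43))
  expect_error(calibrate_thresholds(cfg), "emotional")
})

test_that("cohorts are reproducible and seeds matter", {
  a <- draw_default_cohort(80, seed = 9)
  b <- draw_default_cohort(80, seed = 9)
  expect_identical(a, b)
  c <- draw_default_cohort(80, seed = 10)
  expect_false(identical(a, c))
  # byte-identical on disk too
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_respondents(a, fa); write_respondents(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  roundtrip <- read_respondents(fa)
  expect_equal(roundtrip$m_yelled, a$m_yelled)
  expect_equal(roundtrip$zip, a$zip)
})

test_that("n = 0 gives an empty, well-formed cohort", {
  cfg <- default_config; cfg$n <- 0L
  empty <- generate_cohort(cfg, seed = 1, calibration = default_calibration)
  expect_equal(nrow(empty), 0L)
  expect_true(all(default_schema$item_id %in% names(empty)))
  expect_true(all(qc_required_columns() %in% names(empty)))
})

test_that("zero discrimination yields independent Bernoulli items", {
  sch <- default_schema
  sch$target_prevalence[] <- 0.3
  cfg <- generator_config(n = 10000, schema = sch, discrimination = 0)
  co <- generate_cohort(cfg, seed = 17)
  endorsed <- as.matrix(co[, sch$item_id]) > 0
  expect_equal(unname(colMeans(endorsed)), rep(0.3, 34), tolerance = 0.02)
  cors <- stats::cor(endorsed[, 1:8])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
})

test_that("marginal prevalences converge to the probit closed form", {
  co <- draw_default_cohort(1e5, seed = 23)
  emp <- colMeans(as.matrix(co[, default_schema$item_id]) > 0)
  expected <- default_calibration$items$achieved
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(emp - expected) < 3 * se + 1e-12))
})

test_that("contamination appends records violating exactly one rule each", {
  cohort <- draw_default_cohort(50, seed = 41)
  expect_identical(inject_contamination(cohort, list(
    ineligible = c(prior_completion = 0L, no_dating = 0L, age = 0L,
                   skipped_gt10 = 0L, non_us = 0L, timed_out = 0L),
    non_consent = 0L,
    fraud = c(zip_state_mismatch = 0L, blank_or_nonsense_text = 0L,
              foreign_ip = 0L, duplicate = 0L, geo_mismatch = 0L))),
    cohort)

  spec <- list(
    ineligible = c(prior_completion = 2L, no_dating = 3L, age = 4L,
                   skipped_gt10 = 2L, non_us = 1L, timed_out = 2L),
    non_consent = 2L,
    fraud = c(zip_state_mismatch = 3L, blank_or_nonsense_text = 2L,
              foreign_ip = 5L, duplicate = 2L, geo_mismatch = 3L))
  aug <- inject_contamination(cohort, spec, seed = 6)
  expect_equal(nrow(aug),
               50L + sum(spec$ineligible) + spec$non_consent +
                 sum(spec$fraud))
  elig <- eligibility_filter(aug)
  expect_equal(elig$counts, spec$ineligible)
  consented <- elig$eligible[elig$eligible$consented == 1, ]
  expect_equal(nrow(elig$eligible) - nrow(consented), 2L)
  fl <- fraud_flags(consented, test_zip_table)
  expect_equal(sum(fl$foreign_ip), 5L)
  for (rule in names(spec$fraud))
    expect_equal(sum(fl[[rule]]), unname(spec$fraud[[rule]]))
  # each fraudulent record fires exactly one rule
  fired <- rowSums(as.matrix(fl[, names(spec$fraud)]))
  expect_true(all(fired[fl$fraudulent] == 1L))
  expect_equal(sum(fl$fraudulent), sum(spec$fraud))
})

test_that("higher discrimination ties an item closer to the reference class", {
  cors <- vapply(c(0.3, 1.0, 2.5), function(a_item) {
    sch <- default_schema
    a <- rep(0.7, 34)
    a[sch$item_id == "m_yelled"] <- a_item
    cfg <- generator_config(n = 20000, schema = sch, discrimination = a)
    co <- generate_cohort(cfg, seed = 55)
    ref <- score_marsha(co, sch)
    stats::cor(as.integer(co$m_yelled > 0), as.integer(ref$positive))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("end-to-end recovery reflects the generator's signal strength", {
  # With zero discrimination the screener items are independent of the
  # rest of the scale, so screening is at chance against a reference built
  # from the remaining 31 items. (Against the full 34-item score the area
  # exceeds 0.5 mechanically: the three screener items are part of it.)
  cfg0 <- generator_config(n = 2000, discrimination = 0)
  cal0 <- calibrate_thresholds(cfg0)
  areas <- vapply(1:50, function(r) {
    co <- generate_cohort(cfg0, seed = 100 + r, calibration = cal0)
    rest <- co
    rest[, screener_items()] <- 0L
    ref <- score_marsha(rest)
    scr <- score_marsha_c(derive_marsha_c(co))
    dx_metrics(confusion_table(ref$positive, scr$positive))$roc_area_single
  }, numeric(1))
  expect_lt(abs(mean(areas) - 0.5), 0.03)

  # strong shared signal: subset score tracks the full score
  cfg2 <- generator_config(n = 1000, discrimination = 2)
  strong <- end_to_end_recovery(cfg2, reps = 10, seed = 200)
  expect_gt(strong$summary$mean[strong$summary$metric == "sensitivity"], 0.8)
  expect_gt(strong$summary$mean[strong$summary$metric == "specificity"], 0.8)
})
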