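# Integer 2x2 table recovered from the published full-sample percentages;
# uniqueness of the reconstruction is asserted in the first block below.
study_table <- new_confusion_table(tp = 98, fn = 19, fp = 10, tn = 97)

test_that("confusion tables count paired classifications", {
  tab <- confusion_table(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(tab), c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  empty <- confusion_table(logical(0), logical(0))
  expect_true(all(unlist(empty) == 0L))
  expect_error(dx_metrics(empty), "empty table")
  expect_error(confusion_table(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(new_confusion_table(-1, 0, 0, 1), "non-negative")
})

test_that("the published metrics identify a unique integer table", {
  rec <- reconstruct_confusion_table(
    224, 117,
    c(sensitivity = 0.838, specificity = 0.907, ppv = 0.907,
      npv = 0.836, accuracy = 0.871))
  expect_equal(unlist(rec), unlist(study_table))
  expect_true(attr(rec, "unique"))
  # the winning table reproduces every printed percentage to 1 decimal
  expect_lt(attr(rec, "max_deviation"), 0.0005)
})

test_that("accuracy metrics and exact intervals match direct arithmetic", {
  m <- dx_metrics(study_table)
  expect_equal(m$sensitivity$estimate, 98 / 117)
  expect_equal(m$specificity$estimate, 97 / 107)
  expect_equal(m$ppv$estimate, 98 / 108)
  expect_equal(m$npv$estimate, 97 / 116)
  expect_equal(m$accuracy$estimate, 195 / 224)
  expect_equal(round(m$sensitivity$estimate, 3), 0.838)
  expect_equal(round(m$specificity$estimate, 3), 0.907)
  expect_equal(round(m$ppv$estimate, 3), 0.907)
  expect_equal(round(m$npv$estimate, 3), 0.836)
  expect_equal(round(m$accuracy$estimate, 3), 0.871)
  expect_equal(m$screen_positive_rate, 108 / 224)
  expect_equal(m$roc_area_single, (98 / 117 + 97 / 107) / 2)

  perfect <- dx_metrics(new_confusion_table(1, 0, 0, 1))
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(perfect[[nm]]$estimate, 1)

  cut2 <- dx_metrics(new_confusion_table(51, 66, 0, 107))
  expect_equal(round(cut2$sensitivity$estimate, 3), 0.436)
  expect_equal(cut2$specificity$estimate, 1)
  expect_equal(cut2$lr_positive, Inf)
})

test_that("zero denominators are reported as undefined, not 0 or 1", {
  no_neg <- dx_metrics(new_confusion_table(3, 0, 0, 0))
  expect_true(is.na(no_neg$specificity$estimate))
  expect_true(is.na(no_neg$npv$estimate))
  expect_match(paste(no_neg$undefined, collapse = "; "), "specificity")
  expect_false(is.na(no_neg$sensitivity$estimate))
})

test_that("Clopper-Pearson intervals agree with binom.test across a grid", {
  for (n in c(1, 7, 107, 117, 224)) {
    for (x in unique(pmin(n, c(0, 1, floor(n / 3), n - 1, n)))) {
      ours <- exact_binomial_ci(x, n)
      ref <- stats::binom.test(x, n)$conf.int
      expect_equal(ours$lower, ref[1], tolerance = 1e-12)
      expect_equal(ours$upper, ref[2], tolerance = 1e-12)
    }
  }
  expect_equal(exact_binomial_ci(0, 10)$lower, 0)
  expect_equal(exact_binomial_ci(10, 10)$upper, 1)
  expect_error(exact_binomial_ci(5, 4), "successes")
  expect_error(exact_binomial_ci(1, 2, level = 1), "level")
})

test_that("likelihood ratios convert to the published post-test statement", {
  lr <- likelihood_ratios(study_table)
  expect_equal(round(lr$lr_positive, 2), 8.96)
  expect_equal(round(lr$lr_positive), 9)
  uninformative <- likelihood_ratios(new_confusion_table(1, 1, 1, 1))
  expect_equal(uninformative$lr_positive, 1)
  perfect_spec <- likelihood_ratios(new_confusion_table(51, 66, 0, 107))
  expect_equal(perfect_spec$lr_positive, Inf)
  # overridable pre-test prevalence
  lr2 <- likelihood_ratios(study_table, prevalence = 0.1)
  expect_equal(lr2$post_test_odds, (0.1 / 0.9) * lr$lr_positive)
})

test_that("ROC points over cutpoints match the reconstructed score distribution", {
  score <- c(rep(0, 19), rep(1, 47), rep(2, 29), rep(3, 22),   # positives
             rep(0, 97), rep(1, 10))                           # negatives
  ref <- rep(c(TRUE, FALSE), c(117, 107))
  roc <- roc_curve(score, ref)
  expect_equal(roc$points$sensitivity, c(98, 51, 22) / 117)
  expect_equal(roc$points$fpr, c(10, 0, 0) / 107)
  # monotone in the cutpoint
  expect_true(all(diff(roc$points$sensitivity) <= 0))
  expect_true(all(diff(roc$points$fpr) <= 0))
  expect_true(roc$auc_empirical >= 0 && roc$auc_empirical <= 1)
  expect_error(roc_curve(score, rep(TRUE, length(score))), "both positives")
  # perfect separation
  perfect <- roc_curve(c(3, 3, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc_empirical, 1)
})

test_that("trapezoidal AUC equals the pairwise probability interpretation", {
  # brute-force oracle over all positive/negative pairs, small n; checked
  # against an all-threshold ROC, where the equivalence is exact
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    ref <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
    if (all(ref) || !any(ref)) next
    score <- sample(0:3, n, replace = TRUE) + ifelse(ref, sample(0:1, n, TRUE), 0)
    pos <- score[ref]; neg <- score[!ref]
    pairs <- outer(pos, neg, `-`)
    oracle <- mean((pairs > 0) + 0.5 * (pairs == 0))
    roc <- roc_curve(score, ref, cutpoints = seq_len(max(score)))
    expect_equal(roc$auc_empirical, oracle, tolerance = 1e-12)
  }
})

test_that("AUC is near 0.5 when scores are independent of the reference", {
  set.seed(7)
  score <- sample(0:3, 2000, replace = TRUE)
  ref <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  roc <- roc_curve(score, ref)
  expect_lt(abs(roc$auc_empirical - 0.5), 0.05)
})

test_that("our empirical AUC matches pROC on integer scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- sample(0:3, 300, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  ref <- stats::runif(300) < (0.2 + 0.2 * score)
  roc <- roc_curve(score, ref)
  reference <- as.numeric(pROC::auc(pROC::roc(ref, score, quiet = TRUE,
                                              direction = "<")))
  expect_equal(roc$auc_empirical, reference, tolerance = 1e-12)
})

test_that("cutpoint selection reproduces the study's choice under both rules", {
  score <- c(rep(0, 19), rep(1, 47), rep(2, 29), rep(3, 22),
             rep(0, 97), rep(1, 10))
  ref <- rep(c(TRUE, FALSE), c(117, 107))
  roc <- roc_curve(score, ref)
  expect_equal(select_cutpoint(roc, "closest_to_corner"), 1L)
  expect_equal(select_cutpoint(roc, "youden"), 1L)
  # the corner distances and Youden indices behind that choice
  d <- sqrt(roc$points$fpr^2 + (1 - roc$points$sensitivity)^2)
  expect_equal(round(d, 3), c(0.187, 0.564, 0.812))
  j <- roc$points$sensitivity + roc$points$specificity - 1
  expect_equal(round(j, 3), c(0.744, 0.436, 0.188))
  # ties resolve to the smaller cutpoint
  tie <- structure(list(points = data.frame(
    cutpoint = c(1L, 2L), sensitivity = c(0.8, 0.8),
    specificity = c(0.9, 0.9), fpr = c(0.1, 0.1))),
    class = "roc_analysis")
  expect_equal(select_cutpoint(tie), 1L)
  single <- structure(list(points = data.frame(
    cutpoint = 2L, sensitivity = 0.7, specificity = 0.9, fpr = 0.1)),
    class = "roc_analysis")
  expect_equal(select_cutpoint(single), 2L)
})

test_that("Bayes and accuracy identities hold exactly on random tables", {
  set.seed(5)
  for (rep in 1:200) {
    cells <- stats::rmultinom(1, size = sample(20:400, 1),
                              prob = stats::runif(4, 0.05, 1))
    tab <- new_confusion_table(cells[1], cells[2], cells[3], cells[4])
    if ((tab$tp + tab$fn) == 0 || (tab$fp + tab$tn) == 0 ||
        (tab$tp + tab$fp) == 0 || (tab$tn + tab$fn) == 0) next
    m <- dx_metrics(tab)
    pi <- m$prevalence
    sens <- m$sensitivity$estimate; spec <- m$specificity$estimate
    expect_equal(m$ppv$estimate,
                 sens * pi / (sens * pi + (1 - spec) * (1 - pi)),
                 tolerance = 1e-12)
    expect_equal(m$accuracy$estimate, sens * pi + spec * (1 - pi),
                 tolerance = 1e-12)
  }
})

test_that("raising the cutpoint never raises sensitivity nor lowers specificity", {
  set.seed(9)
  for (rep in 1:100) {
    n <- sample(30:300, 1)
    score <- sample(0:3, n, replace = TRUE)
    ref <- stats::runif(n) < 0.2 + 0.15 * score
    if (all(ref) || !any(ref)) next
    roc <- roc_curve(score, ref)
    expect_true(all(diff(roc$points$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$points$specificity) >= -1e-12))
  }
})

test_that("subgroup analysis keeps degenerate groups and flags small ones", {
  cohort <- draw_default_cohort(600, seed = 21)
  ref <- score_marsha(cohort)
  scr <- score_marsha_c(derive_marsha_c(cohort))
  d <- data.frame(ref_positive = ref$positive, screen_score = scr$score,
                  gender = cohort$gender)
  sub <- subgroup_analysis(d, "gender")
  expect_equal(sub$group[1], "Full sample")
  expect_false(sub$exploratory[1])
  expect_true(sub$exploratory[sub$group == "nonbinary_or_other"])
  # a group identical to the full sample reproduces the full-sample row
  d2 <- d; d2$all <- "everyone"
  sub2 <- subgroup_analysis(d2, "all")
  expect_equal(unlist(sub2[1, -1]), unlist(sub2[2, -1]), ignore_attr = TRUE)
  # zero-negative group: metrics NA-marked, row kept
  d3 <- d
  d3$odd <- ifelse(d3$ref_positive, "allpos", "mixed")
  sub3 <- subgroup_analysis(d3, "odd")
  row <- sub3[sub3$group == "allpos", ]
  expect_true(is.na(row$specificity))
  expect_false(is.na(row$sensitivity))
  expect_error(subgroup_analysis(d, "nope"), "column not found")
})

test_that("generator-identical subgroups show homogeneous accuracy", {
  # same generating process in every group: between-group sensitivity
  # spread stays small (the subgroup-homogeneity property standing in for
  # the unrecoverable published subgroup tables)
  cohort <- draw_default_cohort(15000, seed = 31)
  ref <- score_marsha(cohort)
  scr <- score_marsha_c(derive_marsha_c(cohort))
  d <- data.frame(ref_positive = ref$positive, screen_score = scr$score,
                  site = rep_len(c("site_a", "site_b", "site_c"),
                                 nrow(cohort)))
  sub <- subgroup_analysis(d, "site")
  grp <- sub[sub$group != "Full sample", ]
  expect_lt(diff(range(grp$sensitivity)), 0.05)
  expect_lt(diff(range(grp$specificity)), 0.05)
})
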