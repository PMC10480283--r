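test_that("orientation averages within the stratum and flips risk scores", {
  scores <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 2),
    reader_id = rep(c("a", "b"), 2),
    method = "five_point",
    score = c(1, 5, 3, 3))
  v <- orient_scores(scores, "five_point")
  expect_equal(v$value, c(3, 3))
  expect_equal(attr(v, "orientation"), "as-is")

  four <- dplyr::mutate(scores, method = "four_point", score = c(0, 4, 2, 2))
  v4 <- orient_scores(four, "four_point")
  expect_equal(v4$value, c(-2, -2))
  expect_equal(attr(v4, "orientation"), "negated")

  sub <- orient_scores(scores, "five_point", readers = "a")
  expect_equal(sub$value, c(1, 3))

  gap <- scores
  gap$score[gap$patient_id == "P2"] <- NA
  expect_error(orient_scores(gap, "five_point"), "without any")
})

test_that("AUC agrees with brute-force pair counting and known edge cases", {
  # brute force over the 4 (positive, negative) pairs: 3 wins + 1 tie
  expect_equal(roc_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_equal(roc_auc(c(5, 4, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both outcome classes")
})

test_that("Mann-Whitney and trapezoidal AUC are identical on random instances", {
  withr::local_seed(2024)
  for (i in 1:500) {
    n <- sample(6:40, 1)
    value <- sample(1:6, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.25)
    outcome <- runif(n) < 0.5
    if (!any(outcome) || all(outcome)) outcome[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(value, outcome, "mann_whitney"),
                 roc_auc(value, outcome, "trapezoid"), tolerance = 1e-12)
  }
})

test_that("AUC is rank-invariant and flips under orientation reversal", {
  withr::local_seed(5)
  value <- rnorm(60)
  outcome <- runif(60) < 0.4
  outcome[1:2] <- c(TRUE, FALSE)
  a <- roc_auc(value, outcome)
  expect_equal(roc_auc(exp(2 * value) + 1, outcome), a, tolerance = 1e-12)
  expect_equal(roc_auc(-value, outcome), 1 - a, tolerance = 1e-12)
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(77)
  for (i in 1:20) {
    value <- c(rnorm(30, 0.8), rnorm(40))
    outcome <- rep(c(TRUE, FALSE), c(30, 40))
    ref <- as.numeric(pROC::auc(pROC::roc(outcome, value, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(value, outcome), ref, tolerance = 1e-12)
  }
})

test_that("bootstrap AUC interval is seeded, sane, and degenerate when perfect", {
  value <- c(5, 5, 4, 2, 1, 1)
  outcome <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_bootstrap_ci(value, outcome, n_boot = 500, seed = 1),
               c(1, 1))
  withr::local_seed(3)
  v <- rnorm(50)
  o <- runif(50) < 0.5
  o[1:2] <- c(TRUE, FALSE)
  ci1 <- auc_bootstrap_ci(v, o, n_boot = 500, seed = 9)
  expect_identical(ci1, auc_bootstrap_ci(v, o, n_boot = 500, seed = 9))
  expect_lt(ci1[1], roc_auc(v, o))
  expect_gt(ci1[2], roc_auc(v, o))
  expect_error(auc_bootstrap_ci(v, o, n_boot = 100), "at least 500")
})

test_that("bootstrap AUC interval covers a known generating AUC", {
  # positives N(1,1) vs negatives N(0,1): true AUC = pnorm(1/sqrt(2))
  true_auc <- pnorm(1 / sqrt(2))
  hits <- withr::with_seed(1234, {
    vapply(1:100, function(r) {
      value <- c(rnorm(50, 1), rnorm(50))
      outcome <- rep(c(TRUE, FALSE), each = 50)
      ci <- auc_bootstrap_ci(value, outcome, n_boot = 500,
                             seed = sample.int(1e6, 1))
      ci[1] <= true_auc && true_auc <= ci[2]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Youden-optimal cutoff matches exhaustive search and the published split", {
  # positives concentrated at 4-5 on a 1..5 scale: cutoff falls between 3 and 4
  value <- c(4, 5, 4, 5, 1, 2, 3, 3, 2, 1)
  outcome <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE)
  best <- optimal_cutoff(value, outcome)
  expect_equal(best$cutoff, 3.5)
  expect_equal(best$youden_j, 1)

  withr::local_seed(11)
  value <- sample(1:10, 200, replace = TRUE)
  outcome <- runif(200) < plogis((value - 5) / 2)
  if (!any(outcome) || all(outcome)) outcome[1:2] <- c(TRUE, FALSE)
  best <- optimal_cutoff(value, outcome)
  # brute force over a fine threshold grid
  grid <- seq(min(value) - 1, max(value) + 1, by = 0.01)
  js <- vapply(grid, function(t) {
    pred <- value > t
    sum(pred & outcome) / sum(outcome) + sum(!pred & !outcome) / sum(!outcome) - 1
  }, numeric(1))
  expect_equal(best$youden_j, max(js), tolerance = 1e-12)
})

test_that("confusion metrics compute the five ratios with division guards", {
  m <- confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  perfect <- confusion_metrics(tp = 4, fp = 0, fn = 0, tn = 6)
  expect_true(all(unlist(perfect) == 1))
  no_pos_calls <- confusion_metrics(tp = 0, fp = 0, fn = 2, tn = 3)
  expect_true(is.na(no_pos_calls$ppv))
  expect_error(confusion_metrics(0, 0, 0, 0), "all confusion counts")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("performance table is deterministic and exact in the noiseless limit", {
  study <- tiny_study(seed = 19, feature_error = zero_error)
  outcomes <- study$truth[c("patient_id", "ncr")]
  tab <- performance_table(study$scores, outcomes, study$panel, n_boot = 500,
                           seed = 2)
  tab2 <- performance_table(study$scores, outcomes, study$panel, n_boot = 500,
                            seed = 2)
  expect_identical(tab, tab2)
  # noiseless: stratum AUCs equal the truth-reader AUC exactly
  truth_scores <- score_assessments(study$truth)
  lab <- setNames(study$truth$ncr, study$truth$patient_id)
  for (m in unique(tab$method)) {
    v <- orient_scores(truth_scores, m)
    truth_auc <- roc_auc(v$value, lab[v$patient_id])
    expect_true(all(tab$auc[tab$method == m] == truth_auc))
  }
  expect_true(all(tab$n_readers[tab$stratum == "expert"] == 2))
})

test_that("paired AUC comparison is null under identity and powered under separation", {
  withr::local_seed(21)
  value <- rnorm(80)
  outcome <- runif(80) < 0.5
  outcome[1:2] <- c(TRUE, FALSE)
  same <- compare_aucs(value, value, outcome, n_boot = 2000, seed = 5)
  expect_equal(same$delta_auc, 0)
  expect_gte(same$p_value, 0.9)

  outcome2 <- rep(c(TRUE, FALSE), each = 100)
  perfect <- c(rnorm(100, 5), rnorm(100))
  noise <- rnorm(200)
  strong <- compare_aucs(perfect, noise, outcome2, n_boot = 2000, seed = 5)
  expect_lt(strong$p_value, 0.01)
  expect_identical(strong$p_value,
                   compare_aucs(perfect, noise, outcome2, n_boot = 2000,
                                seed = 5)$p_value)
  expect_error(compare_aucs(1:3, 1:4, c(TRUE, FALSE, TRUE)), "same patients")
})
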