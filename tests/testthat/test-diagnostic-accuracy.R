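test_that("confusion counts match a brute-force loop on a hand fixture", {
  totals <- c(0, 3, 5, 7, 7, 9, 12, 20, 26, 4)
  dx <- c(0, 0, 0, 1, 0, 1, 1, 1, 1, 0)
  cm <- confusion_at_cutoff(totals, dx, 7)
  # exhaustive loop oracle
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(totals)) {
    pos <- totals[i] >= 7
    if (pos && dx[i] == 1) tp <- tp + 1
    if (pos && dx[i] == 0) fp <- fp + 1
    if (!pos && dx[i] == 0) tn <- tn + 1
    if (!pos && dx[i] == 1) fn <- fn + 1
  }
  expect_equal(cm$tp, tp); expect_equal(cm$fp, fp)
  expect_equal(cm$tn, tn); expect_equal(cm$fn, fn)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 10)
  # vacuous cutoffs
  c0 <- confusion_at_cutoff(totals, dx, 0)
  expect_equal(c0$fn, 0); expect_equal(c0$fp, sum(dx == 0))
  c27 <- confusion_at_cutoff(totals, dx, 27)
  expect_equal(c27$tp + c27$fp, 0)
})

test_that("ROC endpoints and orientation behave as a screening curve should", {
  fx <- random_score_fixture(150, seed = 71)
  roc <- roc_curve(fx$totals, fx$diagnosis, 26)
  expect_equal(nrow(roc$points), 28)
  expect_true(all(diff(roc$points$sensitivity) <= 0))  # non-increasing in cutoff
  expect_true(all(diff(roc$points$specificity) >= 0))  # non-decreasing
  expect_equal(roc$points$sensitivity[1], 1)
  expect_equal(roc$points$specificity[28], 1)
  # perfect separation
  sep <- roc_curve(c(rep(2, 30), rep(20, 30)), c(rep(0, 30), rep(1, 30)), 26)
  expect_equal(sep$auc, 1)
  expect_error(roc_curve(1:5, rep(1, 5)), class = "screenval_validation_error")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair count exactly", {
  for (s in 1:25) {
    fx <- random_score_fixture(sample(20:200, 1), seed = 700 + s)
    roc <- roc_curve(fx$totals, fx$diagnosis, 26)
    expect_equal(roc$auc, auc_pair_oracle(fx$totals, fx$diagnosis),
                 tolerance = 1e-12)
  }
})

test_that("null-signal AUC sits within 3 SE of one half", {
  set.seed(72)
  totals <- rbinom(10000, 26, 0.4)
  dx <- rbinom(10000, 1, 0.3)
  roc <- roc_curve(totals, dx, 26)
  expect_lt(abs(roc$auc - 0.5), 3 * roc$auc_se)
})

test_that("AUC agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  fx <- random_score_fixture(200, seed = 73)
  roc <- roc_curve(fx$totals, fx$diagnosis, 26)
  oracle <- as.numeric(pROC::auc(pROC::roc(fx$diagnosis, fx$totals,
                                           quiet = TRUE, direction = "<")))
  expect_equal(roc$auc, oracle, tolerance = 1e-12)
})

test_that("prevalence adjustment reproduces the published operating point", {
  got <- adjust_to_prevalence(0.9054, 0.5993, 0.3566)
  expect_equal(round(100 * got$ppv, 1), 55.6)
  expect_equal(round(100 * got$npv, 1), 92.0)
  expect_equal(round(100 * got$accuracy, 2), 70.85)
})

test_that("prevalence adjustment obeys its identities and boundary conventions", {
  # perfect test
  perf <- adjust_to_prevalence(1, 1, 0.25)
  expect_equal(unlist(perf), c(ppv = 1, npv = 1, accuracy = 1))
  # uninformative test: PPV equals prevalence
  expect_equal(adjust_to_prevalence(0.5, 0.5, 0.37)$ppv, 0.37, tolerance = 1e-12)
  # undefined predictive value marked NA, not NaN-by-accident
  expect_true(is.na(adjust_to_prevalence(0, 1, 0.3)$ppv))
  expect_error(adjust_to_prevalence(0.9, 0.6, 1.5), class = "screenval_validation_error")
  # accuracy identity at arbitrary points
  set.seed(74)
  for (i in 1:50) {
    se <- runif(1); sp <- runif(1); pr <- runif(1, 0.01, 0.99)
    a <- adjust_to_prevalence(se, sp, pr)
    expect_equal(a$accuracy, pr * se + (1 - pr) * sp, tolerance = 1e-12)
    # Bayes identity: PPV * P(screen+) = prev * sens
    ppos <- pr * se + (1 - pr) * (1 - sp)
    if (ppos > 0) expect_equal(a$ppv * ppos, pr * se, tolerance = 1e-12)
  }
})

test_that("expected cost is the four-product sum, linear and scale-equivariant", {
  w <- cost_weights()
  # perfect-test corner forced by the formula
  expect_equal(expected_cost(1, 1, 0.3566, w),
               0.89 * 0.3566 + 0.001 * 0.6434, tolerance = 1e-12)
  # published operating point, direct arithmetic oracle
  direct <- 0.89 * 0.3566 * 0.9054 + 1.0 * 0.3566 * (1 - 0.9054) +
    0.001 * 0.6434 * 0.5993 + 0.03 * 0.6434 * (1 - 0.5993)
  expect_equal(expected_cost(0.9054, 0.5993, 0.3566, w), direct, tolerance = 1e-12)
  expect_equal(expected_cost(0.7, 0.6, 0.2, suppressWarnings(cost_weights(0, 0, 0, 0))), 0)
  expect_error(cost_weights(c_fn = -1), class = "screenval_validation_error")
  # linearity in weights
  set.seed(75)
  for (i in 1:20) {
    w1 <- cost_weights(runif(1), runif(1), runif(1), runif(1))
    w2 <- cost_weights(runif(1), runif(1), runif(1), runif(1))
    se <- runif(1); sp <- runif(1); pr <- runif(1, 0.05, 0.95)
    wsum <- cost_weights(w1$c_tp + w2$c_tp, w1$c_tn + w2$c_tn,
                         w1$c_fp + w2$c_fp, w1$c_fn + w2$c_fn)
    expect_equal(expected_cost(se, sp, pr, wsum),
                 expected_cost(se, sp, pr, w1) + expected_cost(se, sp, pr, w2),
                 tolerance = 1e-12)
    wscaled <- cost_weights(3 * w1$c_tp, 3 * w1$c_tn, 3 * w1$c_fp, 3 * w1$c_fn)
    expect_equal(expected_cost(se, sp, pr, wscaled),
                 3 * expected_cost(se, sp, pr, w1), tolerance = 1e-12)
  }
})

test_that("optimal cut-off equals an exhaustive scan and honours the tie rule", {
  for (s in 1:50) {
    fx <- random_score_fixture(sample(30:150, 1), seed = 7600 + s)
    set.seed(7600 + s)
    w <- cost_weights(runif(1), runif(1, 0, 0.1), runif(1, 0, 0.3), runif(1, 0.5, 1.5))
    pr <- runif(1, 0.05, 0.6)
    roc <- roc_curve(fx$totals, fx$diagnosis, 26)
    got <- suppressMessages(optimal_cutoff(roc, pr, w))
    # independent scan: recompute sens/spec per cutoff from the raw data
    costs <- vapply(0:27, function(cc) {
      cm <- confusion_at_cutoff(fx$totals, fx$diagnosis, cc)
      expected_cost(cm$tp / (cm$tp + cm$fn), cm$tn / (cm$tn + cm$fp), pr, w)
    }, numeric(1))
    best <- which(costs <= min(costs) + 1e-12)[1] - 1L
    expect_equal(got$cutoff, best)
    expect_equal(got$metrics$expected_cost, min(costs), tolerance = 1e-10)
  }
})

test_that("degenerate cost weights select the expected extremes", {
  fx <- random_score_fixture(120, seed = 77)
  roc <- roc_curve(fx$totals, fx$diagnosis, 26)
  # FN-only cost: maximal sensitivity (cutoff 0 screens everyone positive)
  fn_only <- suppressMessages(
    optimal_cutoff(roc, 0.3, suppressWarnings(cost_weights(0, 0, 0, 1))))
  expect_equal(fn_only$metrics$sensitivity,
               max(roc$points$sensitivity))
  # FP-only cost: maximal specificity
  fp_only <- suppressMessages(
    optimal_cutoff(roc, 0.3, suppressWarnings(cost_weights(0, 0, 1, 0))))
  expect_equal(fp_only$metrics$specificity, max(roc$points$specificity))
  # ties break toward the lower cutoff and are messaged
  expect_message(optimal_cutoff(roc, 0.3, suppressWarnings(cost_weights(0, 0, 0, 0))),
                 "tie")
})

test_that("the metrics table spans the grid and repeats prevalence-free columns", {
  fx <- random_score_fixture(200, seed = 78)
  grid <- c(0.05, 0.10, 0.20, 0.3566, 0.40)
  tab <- metrics_table(fx$totals, fx$diagnosis, grid, max_score = 26)
  expect_equal(nrow(tab), 5 * 28)
  expect_equal(tab$accuracy,
               tab$prevalence * tab$sensitivity + (1 - tab$prevalence) * tab$specificity,
               tolerance = 1e-12)
  # sens/spec identical across prevalences at the same cutoff
  sens_by_cut <- split(tab$sensitivity, tab$cutoff)
  expect_true(all(vapply(sens_by_cut, function(v) diff(range(v)) == 0, logical(1))))
  expect_equal(sum(tab$optimal), length(unique(tab$prevalence)))
  # plug-in check: at the sample prevalence the adjusted PPV equals the
  # confusion-table PPV
  pr_hat <- mean(fx$diagnosis)
  cm <- confusion_at_cutoff(fx$totals, fx$diagnosis, 10)
  adj <- adjust_to_prevalence(cm$tp / (cm$tp + cm$fn), cm$tn / (cm$tn + cm$fp), pr_hat)
  expect_equal(adj$ppv, cm$tp / (cm$tp + cm$fp), tolerance = 1e-12)
  expect_equal(adj$npv, cm$tn / (cm$tn + cm$fn), tolerance = 1e-12)
})

test_that("optimal cut-offs do not rise as prevalence rises under default weights", {
  coh <- generate_cohort(default_irt_params(), 600, seed = 1234)
  totals <- rowSums(coh$responses)
  roc <- roc_curve(totals, coh$diagnosis, 26)
  cuts <- vapply(c(0.05, 0.10, 0.20, 0.3566, 0.40), function(pr)
    suppressMessages(optimal_cutoff(roc, pr))$cutoff, numeric(1))
  expect_true(all(diff(cuts) <= 0))
})
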