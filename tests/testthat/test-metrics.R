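test_that("the published confusion matrix reproduces the full reported panel", {
  rep <- diagnostic_report(confusion_matrix(54, 65, 13, 253))
  expected <- tibble::tribble(
    ~metric,        ~pt,  ~lo,  ~hi,
    "sensitivity",   81,   71,   90,
    "specificity",   80,   75,   84,
    "prevalence",    17,   14,   21,
    "ppv",           45,   36,   54,
    "npv",           95,   93,   98,
    "accuracy",      80,   76,   84
  )
  got <- dplyr::inner_join(tidy(rep), expected, by = "metric")
  expect_equal(nrow(got), 6)
  expect_equal(round(100 * got$estimate), got$pt)
  expect_equal(round(100 * got$conf.low), got$lo)
  expect_equal(round(100 * got$conf.high), got$hi)
})

test_that("confusion tallies predictions against truth and validates ids", {
  truth <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:6),
    true_class = rep(c("cancer", "non-cancer"), each = 3)
  )
  perfect <- tibble::tibble(patient_id = truth$patient_id,
                            predicted_class = truth$true_class)
  cm <- confusion(perfect, truth)
  expect_equal(c(cm$fp, cm$fn), c(0, 0))
  expect_equal(c(cm$tp, cm$tn), c(3, 3))

  # all-negative predictor on the published margins
  truth385 <- tibble::tibble(
    patient_id = sprintf("Q%03d", 1:385),
    true_class = rep(c("cancer", "non-cancer"), c(67, 318))
  )
  allneg <- tibble::tibble(patient_id = truth385$patient_id,
                           predicted_class = "non-cancer")
  cm2 <- confusion(allneg, truth385)
  expect_equal(c(cm2$tp, cm2$fn, cm2$fp, cm2$tn), c(0, 67, 0, 318))

  expect_error(confusion(perfect[-1, ], truth), regexp = "P01",
               class = "spectriage_format_error")
  expect_error(confusion(perfect[c(1, 1, 2:6), ], truth),
               class = "spectriage_format_error")
  expect_error(confusion_matrix(0, 0, 0, 0), class = "spectriage_input_error")
  expect_error(confusion_matrix(-1, 0, 0, 5), class = "spectriage_input_error")
})

test_that("degenerate denominators are flagged as NA, never silent zeros", {
  cm <- confusion_matrix(0, 0, 0, 5)  # no disease, no positive calls
  expect_warning(rep <- diagnostic_report(cm), regexp = "sensitivity")
  t <- tidy(rep)
  expect_true(is.na(t$estimate[t$metric == "sensitivity"]))
  expect_true(is.na(t$estimate[t$metric == "ppv"]))
  expect_equal(t$estimate[t$metric == "specificity"], 1)

  one <- diagnostic_report(confusion_matrix(1, 0, 0, 1))
  t1 <- tidy(one)
  expect_equal(t1$estimate[t1$metric != "prevalence"], rep(1, 5))
  expect_equal(t1$estimate[t1$metric == "prevalence"], 0.5)
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  withr::local_seed(61)
  for (i in 1:20) {
    cnt <- as.integer(rmultinom(1, 200, runif(4, 0.05, 1))) + 1L
    rep <- tidy(diagnostic_report(confusion_matrix(cnt[1], cnt[2], cnt[3],
                                                   cnt[4])))
    est <- setNames(rep$estimate, rep$metric)
    expect_equal(
      est[["accuracy"]],
      est[["prevalence"]] * est[["sensitivity"]] +
        (1 - est[["prevalence"]]) * est[["specificity"]],
      tolerance = 1e-12
    )
  }
})

test_that("binomial intervals behave at the boundaries and across methods", {
  expect_equal(unname(wald_ci(0, 50)), c(0, 0))
  expect_equal(unname(wald_ci(1, 50)), c(1, 1))
  ci <- wald_ci(0.8, 67)
  expect_true(ci[["lo"]] < 0.8 && 0.8 < ci[["hi"]])
  wl <- wilson_ci(0.8, 67)
  expect_true(wl[["lo"]] < 0.8 && 0.8 < wl[["hi"]])
  expect_false(isTRUE(all.equal(unname(ci), unname(wl))))
  # wilson never collapses to zero width at the boundary
  expect_gt(wilson_ci(1, 50)[["hi"]] - wilson_ci(1, 50)[["lo"]], 0)
  expect_error(wald_ci(0.5, 0), class = "spectriage_degenerate_error")
})

test_that("precision half-widths match the reported planning numbers", {
  expect_equal(round(half_width(54 / 67, 67), 1), 9.5)
  expect_equal(round(half_width(54 / 67, 600 * 67 / 385), 1), 7.6)
  # monotone decreasing in n, vanishing in the limit
  ns <- c(10, 100, 1000, 1e6)
  hw <- vapply(ns, function(n) half_width(0.5, n), numeric(1))
  expect_true(all(diff(hw) < 0))
  expect_lt(hw[4], 0.1)
})

test_that("required_n inverts half_width and matches a grid-search oracle", {
  # round trip
  for (p in c(0.8, 0.9375)) {
    for (n_pos in c(30, 67, 200)) {
      target <- half_width(p, n_pos)
      N <- required_n(p, target, prevalence = 0.2)
      expect_lte(abs(N * 0.2 - n_pos), 1)
      expect_lte(half_width(p, N * 0.2), target + 1e-9)
    }
  }
  # halving the target quadruples the required positives
  n1 <- required_n(0.9, 10, 0.05) * 0.05
  n2 <- required_n(0.9, 5, 0.05) * 0.05
  expect_equal(n2 / n1, 4, tolerance = 0.05)
  # brute-force scan oracle at the planning values
  p <- 0.9375; target <- 17; prev <- 0.03
  oracle <- Reduce(function(acc, N) {
    if (!is.na(acc)) acc
    else if (half_width(p, N * prev) <= target) N
    else NA_integer_
  }, seq_len(5000), accumulate = FALSE, init = NA_integer_)
  expect_equal(required_n(p, target, prev), oracle)
  expect_error(required_n(0.9, 0, 0.03), class = "spectriage_config_error")
})

test_that("prevalence transport matches the Bayes and linear formulas", {
  bayes <- adjust_predictive_values(54 / 67, 253 / 318, 0.03)
  expect_lt(abs(bayes$ppv - 0.109), 0.001)
  lin <- adjust_predictive_values(method = "linear", target_prevalence = 0.03,
                                  cohort_ppv = 54 / 119,
                                  cohort_prevalence = 67 / 385)
  expect_lt(abs(lin$ppv - 0.078), 0.001)
  expect_true(is.na(lin$npv))

  # identity: linear transport at the cohort prevalence returns the cohort PPV
  id <- adjust_predictive_values(method = "linear",
                                 target_prevalence = 67 / 385,
                                 cohort_ppv = 54 / 119,
                                 cohort_prevalence = 67 / 385)
  expect_equal(id$ppv, 54 / 119)
  # a perfect test transports to perfect predictive values at any prevalence
  perf <- adjust_predictive_values(1, 1, 0.37)
  expect_equal(c(perf$ppv, perf$npv), c(1, 1))
  expect_error(adjust_predictive_values(0.8, 0.8, 0),
               class = "spectriage_degenerate_error")
})

test_that("Bayes PPV rises with prevalence and tracks linear rescaling as pi -> 0", {
  pis <- seq(0.005, 0.5, by = 0.005)
  ppvs <- vapply(pis, function(pi)
    adjust_predictive_values(0.8, 0.8, pi)$ppv, numeric(1))
  expect_true(all(diff(ppvs) > 0))

  small <- c(1e-2, 1e-3, 1e-4, 1e-5)
  ratio <- vapply(small, function(pi) {
    b <- adjust_predictive_values(54 / 67, 253 / 318, pi)$ppv
    l <- adjust_predictive_values(method = "linear", target_prevalence = pi,
                                  cohort_ppv = 54 / 119,
                                  cohort_prevalence = 67 / 385)$ppv
    b / l
  }, numeric(1))
  expect_lt(abs(ratio[4] - ratio[3]), 1e-3)  # ratio converges to a constant
})

test_that("subgroup sensitivity restricts correctly", {
  n <- 40
  truth <- tibble::tibble(
    patient_id = sprintf("G%03d", 1:n),
    true_class = rep(c("cancer", "non-cancer"), c(33, 7)),
    subtype = c(rep("glioblastoma", 33), rep(NA, 7))
  )
  preds <- tibble::tibble(
    patient_id = truth$patient_id,
    predicted_class = c(rep("cancer", 30), rep("non-cancer", 10))
  )
  gb <- subgroup_sensitivity(preds, truth, "glioblastoma")
  expect_equal(gb$n, 33)
  expect_equal(gb$tp, 30)
  expect_equal(round(100 * gb$estimate), 91)

  # subgroup covering all cancers equals overall sensitivity
  overall <- tidy(diagnostic_report(confusion(preds, truth)))
  expect_equal(gb$estimate,
               overall$estimate[overall$metric == "sensitivity"])

  single <- subgroup_sensitivity(preds[1, ], truth[1, ], "glioblastoma")
  expect_equal(single$estimate, 1)
  expect_error(subgroup_sensitivity(preds, truth, "meningioma"),
               class = "spectriage_degenerate_error")
})
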