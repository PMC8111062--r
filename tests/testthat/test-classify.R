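test_that("grouped folds are patient-exclusive, stratified and seeded", {
  truth <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    true_class = rep(c("cancer", "non-cancer"), each = 5)
  )
  folds <- assign_grouped_folds(truth, 5, seed = 1)
  expect_equal(sort(folds$patient_id), sort(truth$patient_id))
  expect_false(anyDuplicated(folds$patient_id) > 0)
  per_fold <- folds |>
    dplyr::left_join(truth, by = "patient_id") |>
    dplyr::count(fold, true_class)
  expect_true(all(per_fold$n == 1))  # each fold: 1 cancer + 1 non-cancer
  expect_identical(folds, assign_grouped_folds(truth, 5, seed = 1))
  expect_false(identical(folds, assign_grouped_folds(truth, 5, seed = 2)))
  expect_error(assign_grouped_folds(truth, 6),
               class = "spectriage_config_error")
})

test_that("a fold map splitting a patient across folds is rejected", {
  coh <- quick_cohort(10, effect_size = 0, seed = 31, n_points = 30)
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  leaky <- tibble::tibble(
    patient_id = c(coh$truth$patient_id, coh$truth$patient_id[1]),
    fold = c(rep(1:2, length.out = nrow(coh$truth)), 2L)
  )
  expect_error(
    train_classifier(ft, coh$truth, training_config(n_folds = 2), folds = leaky),
    class = "spectriage_config_error"
  )
})

test_that("training rejects single-class cohorts", {
  coh <- simulate_cohort(sim_config(n_patients = 6, prevalence = 0,
                                    n_points = 30, seed = 32))
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  expect_error(train_classifier(ft, coh$truth, training_config()),
               class = "spectriage_degenerate_error")
})

test_that("a strong spectral effect yields near-perfect out-of-fold AUC", {
  coh <- quick_cohort(200, effect_size = 0.10, seed = 33)
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  m <- train_classifier(ft, coh$truth,
                        training_config(family = "linear", seed = 33))
  expect_gt(glance(m)$auc_oof, 0.95)
  # held-out probabilities separate the classes in the right direction
  oof <- m$oof
  expect_gt(mean(oof$p_cancer[oof$true_class == "cancer"]),
            mean(oof$p_cancer[oof$true_class == "non-cancer"]))
})

test_that("permuting patient labels destroys the signal", {
  coh <- quick_cohort(200, effect_size = 0.10, seed = 34)
  shuffled <- coh$truth
  shuffled$true_class <- withr::with_seed(7, sample(shuffled$true_class))
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  m <- train_classifier(ft, shuffled,
                        training_config(family = "linear", seed = 34))
  expect_gt(glance(m)$auc_oof, 0.40)
  expect_lt(glance(m)$auc_oof, 0.60)
})

test_that("out-of-fold AUC is monotone in effect size under shared seeds", {
  aucs <- vapply(c(0, 0.04, 0.10), function(es) {
    coh <- quick_cohort(150, effect_size = es, seed = 35, n_points = 100)
    ft <- preprocess_pipeline(coh$spectra, preprocess_config())
    m <- train_classifier(ft, coh$truth,
                          training_config(family = "linear", seed = 35))
    glance(m)$auc_oof
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.02))
  expect_gt(aucs[3], aucs[1])
})

test_that("prediction is deterministic, bounded and grid-checked", {
  coh <- quick_cohort(30, effect_size = 0.05, seed = 36, n_points = 60)
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  m <- train_classifier(ft, coh$truth,
                        training_config(family = "forest", n_folds = 3,
                                        hyperparameters = list(num_trees = 100),
                                        seed = 36))
  p1 <- predict(m, ft)
  p2 <- predict(m, ft)
  expect_identical(p1, p2)
  expect_true(all(p1$p_cancer >= 0 & p1$p_cancer <= 1))
  # duplicated feature rows get identical probabilities
  dup <- ft[c(1, 1, 2), ]
  pd <- predict(m, dup)
  expect_identical(pd$p_cancer[1], pd$p_cancer[2])

  narrower <- preprocess_pipeline(coh$spectra,
                                  preprocess_config(region_lo = 1000,
                                                    region_hi = 1700))
  expect_error(predict(m, narrower), class = "spectriage_grid_error")
})

test_that("forest family also recovers a separable cohort", {
  coh <- quick_cohort(60, effect_size = 0.10, seed = 37, n_points = 60)
  ft <- preprocess_pipeline(coh$spectra, preprocess_config())
  m <- train_classifier(ft, coh$truth,
                        training_config(family = "forest", n_folds = 3,
                                        hyperparameters = list(num_trees = 100),
                                        seed = 37))
  expect_gt(glance(m)$auc_oof, 0.9)
})

test_that("balanced threshold tuning matches a brute-force sweep", {
  withr::local_seed(41)
  ids <- sprintf("T%02d", 1:12)
  truth <- tibble::tibble(patient_id = ids,
                          true_class = rep(c("cancer", "non-cancer"), 6))
  probs <- tibble::tibble(
    patient_id = rep(ids, each = 9),
    well = rep(rep(1:3, each = 3), 12),
    scan = rep(rep(1:3, times = 3), 12),
    p_cancer = runif(108)
  )
  # nudge cancer patients upwards so the optimum is interior
  bump <- probs$patient_id %in% ids[truth$true_class == "cancer"]
  probs$p_cancer[bump] <- pmin(1, probs$p_cancer[bump] + 0.2)

  tuned <- tune_threshold(probs, truth, objective = "balanced")

  # oracle: exhaustive scan over midpoints of sorted unique probabilities
  cand <- sort(unique(probs$p_cancer))
  mids <- c(0, (head(cand, -1) + tail(cand, -1)) / 2, cand, 1)
  best <- max(vapply(mids, function(t) {
    preds <- predict_patients(probs, t)
    df <- dplyr::left_join(preds, truth, by = "patient_id")
    sens <- mean(df$predicted_class[df$true_class == "cancer"] == "cancer")
    spec <- mean(df$predicted_class[df$true_class == "non-cancer"] == "non-cancer")
    min(sens, spec)
  }, numeric(1)))
  expect_equal(min(tuned$sensitivity, tuned$specificity), best)

  # objective value is invariant under strictly monotone transforms
  cubed <- dplyr::mutate(probs, p_cancer = p_cancer^3)
  tuned3 <- tune_threshold(cubed, truth, objective = "balanced")
  expect_equal(min(tuned3$sensitivity, tuned3$specificity), best)
})

test_that("perfectly separated probabilities tune to a perfect threshold", {
  ids <- sprintf("S%02d", 1:8)
  truth <- tibble::tibble(patient_id = ids,
                          true_class = rep(c("cancer", "non-cancer"), each = 4))
  probs <- tibble::tibble(
    patient_id = rep(ids, each = 9), well = 1L, scan = rep(1:9, 8),
    p_cancer = rep(c(0.9, 0.1), each = 36)
  )
  tuned <- tune_threshold(probs, truth)
  expect_equal(tuned$sensitivity, 1)
  expect_equal(tuned$specificity, 1)
  expect_true(tuned$threshold > 0.1 && tuned$threshold <= 0.9)

  expect_error(
    tune_threshold(probs, dplyr::mutate(truth, true_class = "cancer")),
    class = "spectriage_degenerate_error"
  )
})

test_that("sensitivity-constrained tuning honours the specificity floor", {
  withr::local_seed(42)
  ids <- sprintf("U%02d", 1:20)
  truth <- tibble::tibble(patient_id = ids,
                          true_class = rep(c("cancer", "non-cancer"), 10))
  probs <- tibble::tibble(
    patient_id = rep(ids, each = 9), well = 1L, scan = rep(1:9, 20),
    p_cancer = runif(180)
  )
  bump <- probs$patient_id %in% ids[truth$true_class == "cancer"]
  probs$p_cancer[bump] <- pmin(1, probs$p_cancer[bump] + 0.15)
  tuned <- tune_threshold(probs, truth,
                          objective = "max_sensitivity_at_min_specificity",
                          min_specificity = 0.7)
  expect_gte(tuned$specificity, 0.7)
})
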