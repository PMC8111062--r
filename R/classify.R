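#' Classifier training configuration
#'
#' The published test's model (feature set, family, parameters) is
#' proprietary; this package provides two standard families behind one
#' contract so every downstream statistic can be exercised:
#' `"forest"` (a probability random forest, the default) and `"linear"`
#' (ridge-penalised logistic regression on the spectral features).
#'
#' Cross-validation is always grouped by patient and class-stratified:
#' replicate spectra of one patient are strongly correlated, so spectrum-level
#' splits would leak and inflate every performance estimate.
#'
#' @param family `"forest"` or `"linear"`.
#' @param hyperparameters Named list. Forest: `num_trees` (default 200),
#'   `min_node_size` (default 5). Linear: `lambda` (ridge penalty,
#'   default 0.01).
#' @param n_folds Number of grouped CV folds (>= 2).
#' @param tuning_objective `"balanced"` (maximise the smaller of patient-level
#'   sensitivity and specificity) or `"max_sensitivity_at_min_specificity"`.
#' @param min_specificity Constraint used by the second objective.
#' @param seed Integer seed controlling fold assignment and forest fitting.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(family = c("forest", "linear"),
                            hyperparameters = list(),
                            n_folds = 5L,
                            tuning_objective = c("balanced",
                                                 "max_sensitivity_at_min_specificity"),
                            min_specificity = 0.8,
                            seed = 1L) {
  family <- match.arg(family)
  tuning_objective <- match.arg(tuning_objective)
  if (!is.numeric(n_folds) || n_folds < 2 || n_folds != trunc(n_folds)) {
    abort("`n_folds` must be an integer >= 2.", class = "spectriage_config_error")
  }
  defaults <- switch(family,
    forest = list(num_trees = 200L, min_node_size = 5L),
    linear = list(lambda = 0.01)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(
    list(family = family, hyperparameters = hp, n_folds = as.integer(n_folds),
         tuning_objective = tuning_objective,
         min_specificity = min_specificity, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Patient-grouped, class-stratified fold assignment
#'
#' Every patient lands in exactly one fold (so all replicate spectra share the
#' fold) and folds are stratified by class to within one patient. Requires at
#' least `n_folds` patients in each class.
#'
#' @param truth Truth tibble with `patient_id` and `true_class`.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `patient_id`, `fold`.
#' @export
assign_grouped_folds <- function(truth, n_folds, seed = 1L) {
  counts <- table(truth$true_class)
  if (length(counts) < 2 || any(counts < n_folds)) {
    abort(sprintf(
      "Each class needs at least %d patients for %d grouped folds.",
      n_folds, n_folds), class = "spectriage_config_error")
  }
  withr::with_seed(seed, {
    truth |>
      dplyr::group_by(.data$true_class) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(fold = rep_len(seq_len(n_folds), dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "fold") |>
      dplyr::arrange(.data$patient_id)
  })
}

# reject fold maps that split a patient across folds (leakage guard)
.check_folds <- function(folds) {
  dup <- folds$patient_id[duplicated(folds$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("Patient(s) assigned to more than one fold: ",
                 paste(unique(head(dup, 5)), collapse = ", ")),
          class = "spectriage_config_error")
  }
  invisible(folds)
}

.fit_family <- function(X, y, config, seed) {
  hp <- config$hyperparameters
  if (config$family == "forest") {
    ranger::ranger(
      x = X, y = factor(y, levels = c("non-cancer", "cancer")),
      probability = TRUE, num.trees = hp$num_trees,
      min.node.size = hp$min_node_size, seed = seed, num.threads = 1
    )
  } else {
    # decreasing lambda path ending at the requested penalty; predictions are
    # taken at s = hp$lambda
    glmnet::glmnet(
      x = X, y = factor(y, levels = c("non-cancer", "cancer")),
      family = "binomial", alpha = 0,
      lambda = sort(unique(c(hp$lambda * c(100, 10, 1))), decreasing = TRUE)
    )
  }
}

.predict_family <- function(fit, X, config) {
  if (config$family == "forest") {
    p <- predict(fit, data = X, num.threads = 1)$predictions
    as.numeric(p[, "cancer"])
  } else {
    as.numeric(predict(fit, newx = X, s = config$hyperparameters$lambda,
                       type = "response"))
  }
}

#' Train a per-spectrum cancer classifier with grouped cross-validation
#'
#' Fits the configured model family on preprocessed spectral features, and in
#' the same call produces an out-of-fold probability for every training
#' spectrum via patient-grouped, class-stratified cross-validation. All
#' performance reporting downstream (threshold tuning, ROC curves, diagnostic
#' reports) uses these out-of-fold probabilities, never resubstitution
#' predictions.
#'
#' @param features An `"slb_features"` tibble from [preprocess_pipeline()].
#' @param truth Truth tibble with `patient_id`, `true_class` covering every
#'   patient in `features`.
#' @param config A [training_config()].
#' @param folds Optional pre-built fold map (`patient_id`, `fold`); a patient
#'   appearing in more than one fold is rejected.
#' @return An object of class `"slb_classifier"`: the final model fitted on
#'   all spectra, the expected wavenumber grid, fold assignments, and the
#'   out-of-fold probability table `oof` (`patient_id`, `well`, `scan`,
#'   `p_cancer`, `true_class`).
#' @export
train_classifier <- function(features, truth, config = training_config(),
                             folds = NULL) {
  stopifnot(inherits(config, "training_config"))
  X <- features_matrix(features)
  wn <- features_wavenumbers(features)
  key <- features[, c("patient_id", "well", "scan")]
  lab <- dplyr::left_join(key, dplyr::select(truth, "patient_id", "true_class"),
                          by = "patient_id")
  if (anyNA(lab$true_class)) {
    missing_ids <- unique(lab$patient_id[is.na(lab$true_class)])
    abort(paste0("No truth entry for patient(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "spectriage_format_error")
  }
  if (dplyr::n_distinct(lab$true_class) < 2) {
    abort("Training requires both classes to be present.",
          class = "spectriage_degenerate_error")
  }
  truth_used <- dplyr::filter(truth, .data$patient_id %in% key$patient_id)
  if (is.null(folds)) {
    folds <- assign_grouped_folds(truth_used, config$n_folds, config$seed)
  }
  .check_folds(folds)
  fold_of <- setNames(folds$fold, folds$patient_id)
  spec_fold <- unname(fold_of[lab$patient_id])

  oof <- rep(NA_real_, nrow(X))
  for (f in sort(unique(folds$fold))) {
    test_idx <- which(spec_fold == f)
    train_idx <- which(spec_fold != f)
    fit <- .fit_family(X[train_idx, , drop = FALSE], lab$true_class[train_idx],
                       config, seed = config$seed + f)
    oof[test_idx] <- .predict_family(fit, X[test_idx, , drop = FALSE], config)
  }
  final <- .fit_family(X, lab$true_class, config, seed = config$seed)

  structure(
    list(
      model = final, family = config$family, wavenumbers = wn,
      config = config, folds = folds,
      oof = dplyr::bind_cols(key, tibble::tibble(p_cancer = oof,
                                                 true_class = lab$true_class))
    ),
    class = "slb_classifier"
  )
}

#' @export
print.slb_classifier <- function(x, ...) {
  cat(sprintf("<slb_classifier> family=%s, %d wavenumber features, %d folds\n",
              x$family, length(x$wavenumbers), x$config$n_folds))
  invisible(x)
}

#' Per-spectrum cancer probabilities
#'
#' Applies a trained classifier to a feature table and returns one probability
#' per spectrum. The feature grid must match the grid the model was trained
#' on.
#'
#' @param object An `"slb_classifier"`.
#' @param features An `"slb_features"` tibble.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `well`, `scan`, `p_cancer`.
#' @export
predict.slb_classifier <- function(object, features, ...) {
  wn <- features_wavenumbers(features)
  if (length(wn) != length(object$wavenumbers) ||
      !isTRUE(all.equal(wn, object$wavenumbers))) {
    abort("Feature grid does not match the grid the classifier was trained on.",
          class = "spectriage_grid_error")
  }
  X <- features_matrix(features)
  p <- .predict_family(object$model, X, object$config)
  dplyr::bind_cols(features[, c("patient_id", "well", "scan")],
                   tibble::tibble(p_cancer = pmin(1, pmax(0, p))))
}

#' @exportS3Method generics::tidy
tidy.slb_classifier <- function(x, ...) {
  truth <- dplyr::distinct(x$oof, .data$patient_id, .data$true_class)
  x$oof |>
    dplyr::left_join(x$folds, by = "patient_id") |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(function(df, key) {
      tr <- dplyr::distinct(df, .data$patient_id, .data$true_class)
      roc <- roc_curve(df[, c("patient_id", "well", "scan", "p_cancer")],
                       tr, consensus_config())
      tibble::tibble(n_patients = nrow(tr), auc = attr(roc, "auc"))
    }) |>
    dplyr::ungroup()
}

#' @exportS3Method generics::glance
glance.slb_classifier <- function(x, ...) {
  truth <- dplyr::distinct(x$oof, .data$patient_id, .data$true_class)
  roc <- roc_curve(x$oof[, c("patient_id", "well", "scan", "p_cancer")],
                   truth, consensus_config())
  tibble::tibble(
    family = x$family,
    n_spectra = nrow(x$oof),
    n_patients = nrow(truth),
    n_folds = x$config$n_folds,
    auc_oof = attr(roc, "auc")
  )
}

#' Tune the consensus decision threshold on out-of-fold probabilities
#'
#' Sweeps candidate thresholds (0 and every observed probability), computes
#' the patient-level consensus prediction at each, and picks the threshold by
#' the configured objective:
#' \describe{
#'   \item{balanced}{maximise `min(sensitivity, specificity)`; ties broken by
#'     smaller `|sensitivity - specificity|`, then by the lower threshold.}
#'   \item{max_sensitivity_at_min_specificity}{maximise sensitivity subject to
#'     `specificity >= min_specificity`; ties broken by higher specificity,
#'     then lower threshold.}
#' }
#' Tuning happens at patient (post-consensus) level because the reported
#' performance of the test is per patient.
#'
#' @param probs Tibble of per-spectrum probabilities (`patient_id`, `well`,
#'   `scan`, `p_cancer`), normally out-of-fold.
#' @param truth Truth tibble (`patient_id`, `true_class`).
#' @param objective,min_specificity See [training_config()].
#' @param consensus A [consensus_config()].
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `objective`.
#' @export
tune_threshold <- function(probs, truth,
                           objective = c("balanced",
                                         "max_sensitivity_at_min_specificity"),
                           min_specificity = 0.8,
                           consensus = consensus_config()) {
  objective <- match.arg(objective)
  if (dplyr::n_distinct(truth$true_class) < 2) {
    abort("Threshold tuning requires both classes in the truth table.",
          class = "spectriage_degenerate_error")
  }
  sweep <- .threshold_sweep(probs, truth, consensus)
  cand <- sweep |>
    dplyr::mutate(score = pmin(.data$sensitivity, .data$specificity),
                  gap = abs(.data$sensitivity - .data$specificity))
  pick <- if (objective == "balanced") {
    cand |>
      dplyr::arrange(dplyr::desc(.data$score), .data$gap, .data$threshold) |>
      dplyr::slice(1)
  } else {
    ok <- dplyr::filter(cand, .data$specificity >= min_specificity)
    ok |>
      dplyr::arrange(dplyr::desc(.data$sensitivity),
                     dplyr::desc(.data$specificity), .data$threshold) |>
      dplyr::slice(1)
  }
  tibble::tibble(threshold = pick$threshold,
                 sensitivity = pick$sensitivity,
                 specificity = pick$specificity,
                 objective = objective)
}
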