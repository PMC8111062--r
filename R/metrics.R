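#' Patient-level confusion matrix
#'
#' `confusion_matrix()` builds the object from the four counts directly (the
#' form in which published results are usually available);
#' `confusion()` tallies it from patient predictions against a truth table,
#' with "cancer" as the positive class.
#'
#' @param tp,fp,fn,tn Non-negative integer patient counts (true positive,
#'   false positive, false negative, true negative).
#' @return An object of class `"slb_confusion"`.
#' @export
#' @examples
#' cm <- confusion_matrix(54, 65, 13, 253)
#' cm
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != trunc(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "spectriage_input_error")
  }
  if (sum(counts) == 0) {
    abort("Confusion matrix must contain at least one patient.",
          class = "spectriage_input_error")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "slb_confusion")
}

#' @rdname confusion_matrix
#' @param predictions Tibble with `patient_id`, `predicted_class` (from
#'   [consensus_predict()] / [predict_patients()]).
#' @param truth Truth tibble with `patient_id`, `true_class`.
#' @export
confusion <- function(predictions, truth) {
  if (anyDuplicated(predictions$patient_id)) {
    dup <- unique(predictions$patient_id[duplicated(predictions$patient_id)])
    abort(paste0("Duplicate prediction for patient(s): ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "spectriage_format_error")
  }
  if (anyDuplicated(truth$patient_id)) {
    dup <- unique(truth$patient_id[duplicated(truth$patient_id)])
    abort(paste0("Duplicate truth entry for patient(s): ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "spectriage_format_error")
  }
  missing_pred <- setdiff(truth$patient_id, predictions$patient_id)
  extra_pred <- setdiff(predictions$patient_id, truth$patient_id)
  if (length(missing_pred) > 0 || length(extra_pred) > 0) {
    abort(paste0("Predictions and truth must cover the same patients; ",
                 "unmatched id(s): ",
                 paste(head(c(missing_pred, extra_pred), 5), collapse = ", ")),
          class = "spectriage_format_error")
  }
  df <- dplyr::inner_join(
    dplyr::select(predictions, "patient_id", "predicted_class"),
    dplyr::select(truth, "patient_id", "true_class"),
    by = "patient_id"
  )
  confusion_matrix(
    tp = sum(df$predicted_class == "cancer" & df$true_class == "cancer"),
    fp = sum(df$predicted_class == "cancer" & df$true_class == "non-cancer"),
    fn = sum(df$predicted_class == "non-cancer" & df$true_class == "cancer"),
    tn = sum(df$predicted_class == "non-cancer" & df$true_class == "non-cancer")
  )
}

#' @export
print.slb_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$tp + x$fp,
                x$fn, x$tn, x$fn + x$tn,
                x$tp + x$fn, x$fp + x$tn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Test positive", "Test negative", "Total"),
                              c("Disease", "No disease", "Total")))
  cat("Patient-level confusion matrix (positive = cancer)\n")
  print(m)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slb_confusion <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}

# ---- binomial intervals -----------------------------------------------------

# z for a two-sided level; 1.959964 at 95%
.z_level <- function(level) qnorm(1 - (1 - level) / 2)

#' Binomial confidence intervals for a proportion
#'
#' `wald_ci()` is the normal-approximation interval
#' \eqn{p \pm z \sqrt{p(1-p)/n}}, clipped to \[0, 1\]; it is the default
#' throughout the package because it is the interval conventionally reported
#' with diagnostic-accuracy tables. `wilson_ci()` (score interval) is
#' provided as an alternative with better small-sample coverage.
#'
#' @param p Observed proportion in \[0, 1\].
#' @param n Number of trials (may be non-integral for planning calculations).
#' @param level Two-sided confidence level.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' wald_ci(54 / 67, 67)
wald_ci <- function(p, n, level = 0.95) {
  if (n <= 0) {
    abort("Confidence interval undefined for n = 0.",
          class = "spectriage_degenerate_error")
  }
  hw <- .z_level(level) * sqrt(p * (1 - p) / n)
  c(lo = max(0, p - hw), hi = min(1, p + hw))
}

#' @rdname wald_ci
#' @export
wilson_ci <- function(p, n, level = 0.95) {
  if (n <= 0) {
    abort("Confidence interval undefined for n = 0.",
          class = "spectriage_degenerate_error")
  }
  z <- .z_level(level)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lo = max(0, centre - hw), hi = min(1, centre + hw))
}

#' Precision of a proportion estimate, in percentage points
#'
#' The half-width of the Wald interval, \eqn{z \sqrt{p(1-p)/n}}, expressed in
#' percentage points: the "precision" quoted in diagnostic-accuracy study
#' designs (e.g. "sensitivity estimated to +/- 9.5%").
#'
#' @inheritParams wald_ci
#' @return Half-width in percentage points.
#' @export
#' @examples
#' half_width(54 / 67, 67)  # 9.47 -> reported as +/- 9.5
half_width <- function(p, n, level = 0.95) {
  if (n <= 0) {
    abort("Half-width undefined for n = 0.",
          class = "spectriage_degenerate_error")
  }
  100 * .z_level(level) * sqrt(p * (1 - p) / n)
}

#' Cohort size needed for a target precision
#'
#' Smallest total cohort size `N` such that estimating a proportion `p` from
#' the `N * prevalence` positive patients achieves a Wald half-width no larger
#' than `target_half_width` percentage points. Inverse of [half_width()]:
#' `required_n(p, half_width(p, n), prev)` returns the `N` with
#' `N * prev ~ n`.
#'
#' @param p Anticipated proportion (e.g. sensitivity).
#' @param target_half_width Target precision in percentage points (> 0).
#' @param prevalence Fraction of the cohort contributing to the denominator.
#' @param level Confidence level.
#' @return Smallest integer total cohort size.
#' @export
#' @examples
#' required_n(0.9375, 17, 0.03)
required_n <- function(p, target_half_width, prevalence, level = 0.95) {
  if (target_half_width <= 0) {
    abort("`target_half_width` must be positive.",
          class = "spectriage_config_error")
  }
  if (prevalence <= 0 || prevalence > 1) {
    abort("`prevalence` must lie in (0, 1].",
          class = "spectriage_config_error")
  }
  z <- .z_level(level)
  n_pos <- z^2 * p * (1 - p) / (target_half_width / 100)^2
  N <- ceiling(n_pos / prevalence)
  # guard against floating-point edge: step down while still within target
  while (N > 1 && half_width(p, (N - 1) * prevalence, level) <= target_half_width) {
    N <- N - 1
  }
  N
}

# ---- diagnostic report ------------------------------------------------------

.metric_defs <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  tibble::tibble(
    metric = c("sensitivity", "specificity", "prevalence", "ppv", "npv",
               "accuracy"),
    numerator = c(cm$tp, cm$tn, cm$tp + cm$fn, cm$tp, cm$tn, cm$tp + cm$tn),
    denominator = c(cm$tp + cm$fn, cm$tn + cm$fp, total, cm$tp + cm$fp,
                    cm$tn + cm$fn, total)
  )
}

#' Diagnostic performance report with confidence intervals
#'
#' Computes the six standard patient-level diagnostic-accuracy metrics from a
#' confusion matrix — sensitivity, specificity, prevalence, positive and
#' negative predictive value, accuracy — each with a binomial confidence
#' interval on its own denominator. Metrics with a zero denominator are
#' reported as `NA` with a warning rather than silently as 0.
#'
#' @param cm An `"slb_confusion"` object.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @return An `"slb_report"` tibble: `metric`, `estimate`, `conf.low`,
#'   `conf.high`, `numerator`, `denominator`. The print method displays
#'   whole-percent rounding in the conventional table layout.
#' @export
#' @examples
#' diagnostic_report(confusion_matrix(54, 65, 13, 253))
diagnostic_report <- function(cm, level = 0.95,
                              ci_method = c("wald", "wilson")) {
  stopifnot(inherits(cm, "slb_confusion"))
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, wald = wald_ci, wilson = wilson_ci)
  defs <- .metric_defs(cm)
  out <- defs |>
    dplyr::mutate(
      estimate = dplyr::if_else(.data$denominator > 0,
                                .data$numerator / .data$denominator, NA_real_)
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      conf.low = if (is.na(.data$estimate)) NA_real_ else
        ci_fun(.data$estimate, .data$denominator, level)[["lo"]],
      conf.high = if (is.na(.data$estimate)) NA_real_ else
        ci_fun(.data$estimate, .data$denominator, level)[["hi"]]
    ) |>
    dplyr::ungroup() |>
    dplyr::select("metric", "estimate", "conf.low", "conf.high",
                  "numerator", "denominator")
  if (anyNA(out$estimate)) {
    warn(paste0("Undefined metric(s) (zero denominator): ",
                paste(out$metric[is.na(out$estimate)], collapse = ", ")))
  }
  class(out) <- c("slb_report", class(out))
  attr(out, "level") <- level
  attr(out, "ci_method") <- ci_method
  out
}

#' @export
print.slb_report <- function(x, ...) {
  lv <- attr(x, "level") %||% 0.95
  cat(sprintf("Diagnostic performance (%s %g%% CI, whole-percent display)\n",
              attr(x, "ci_method") %||% "wald", 100 * lv))
  disp <- function(v) ifelse(is.na(v), "  NA", sprintf("%3.0f%%", 100 * v))
  lab <- c(sensitivity = "Sensitivity", specificity = "Specificity",
           prevalence = "Prevalence", ppv = "PPV", npv = "NPV",
           accuracy = "Accuracy")
  cat(sprintf("  %-12s %8s %8s %8s\n", "Metric", "Reported", "Lower", "Upper"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %8s %8s %8s\n", lab[[x$metric[i]]],
                disp(x$estimate[i]), disp(x$conf.low[i]), disp(x$conf.high[i])))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slb_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "slb_report")
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.slb_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$metric <- factor(df$metric, levels = rev(df$metric))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Prevalence-transported predictive values
#'
#' Recomputes PPV (and NPV) for a population whose disease prevalence differs
#' from the study cohort's, e.g. carrying enriched-cohort performance back to
#' the 1--3% prevalence of a symptomatic primary-care referral population.
#' Two methods are offered and always labelled in the output:
#' \describe{
#'   \item{bayes}{the textbook formulas
#'     \eqn{PPV = s\pi / (s\pi + (1-c)(1-\pi))},
#'     \eqn{NPV = c(1-\pi) / (c(1-\pi) + (1-s)\pi)} for sensitivity `s`,
#'     specificity `c`, prevalence \eqn{\pi}.}
#'   \item{linear}{the simple rescaling
#'     \eqn{PPV = PPV_{cohort} \times \pi / \pi_{cohort}}; NPV is undefined
#'     under this method and returned as `NA`.}
#' }
#'
#' @param sensitivity,specificity Test characteristics in (0, 1)
#'   (bayes method).
#' @param target_prevalence Prevalence of the target population, in (0, 1).
#' @param method `"bayes"` or `"linear"`.
#' @param cohort_ppv,cohort_prevalence Study-cohort PPV and prevalence
#'   (linear method).
#' @return One-row tibble: `method`, `prevalence`, `ppv`, `npv`.
#' @export
#' @examples
#' adjust_predictive_values(54 / 67, 253 / 318, 0.03)
#' adjust_predictive_values(method = "linear", target_prevalence = 0.03,
#'                          cohort_ppv = 54 / 119, cohort_prevalence = 67 / 385)
adjust_predictive_values <- function(sensitivity = NULL, specificity = NULL,
                                     target_prevalence,
                                     method = c("bayes", "linear"),
                                     cohort_ppv = NULL,
                                     cohort_prevalence = NULL) {
  method <- match.arg(method)
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("`target_prevalence` must lie strictly inside (0, 1).",
          class = "spectriage_degenerate_error")
  }
  if (method == "bayes") {
    stopifnot(!is.null(sensitivity), !is.null(specificity))
    if (sensitivity <= 0 || sensitivity >= 1 + 1e-12 ||
        specificity <= 0 || specificity >= 1 + 1e-12) {
      if (!(sensitivity == 1 || specificity == 1)) {
        abort("`sensitivity` and `specificity` must lie in (0, 1].",
              class = "spectriage_input_error")
      }
    }
    pi <- target_prevalence
    ppv <- sensitivity * pi / (sensitivity * pi + (1 - specificity) * (1 - pi))
    npv <- specificity * (1 - pi) /
      (specificity * (1 - pi) + (1 - sensitivity) * pi)
    tibble::tibble(method = "bayes", prevalence = pi, ppv = ppv, npv = npv)
  } else {
    stopifnot(!is.null(cohort_ppv), !is.null(cohort_prevalence))
    if (cohort_prevalence <= 0 || cohort_prevalence >= 1) {
      abort("`cohort_prevalence` must lie strictly inside (0, 1).",
            class = "spectriage_degenerate_error")
    }
    tibble::tibble(
      method = "linear", prevalence = target_prevalence,
      ppv = cohort_ppv * target_prevalence / cohort_prevalence,
      npv = NA_real_
    )
  }
}

#' Sensitivity within a tumour-subtype subgroup
#'
#' Restricts the sensitivity calculation to cancer patients of one subtype
#' (e.g. glioblastoma), with its own confidence interval.
#'
#' @param predictions Tibble with `patient_id`, `predicted_class`.
#' @param truth Truth tibble with `patient_id`, `true_class`, `subtype`.
#' @param subtype Subtype name to restrict to.
#' @param level Confidence level.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return One-row tibble: `subtype`, `n`, `tp`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
subgroup_sensitivity <- function(predictions, truth, subtype, level = 0.95,
                                 ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, wald = wald_ci, wilson = wilson_ci)
  sub <- truth |>
    dplyr::filter(.data$true_class == "cancer", .data$subtype == !!subtype)
  if (nrow(sub) == 0) {
    abort(paste0("No cancer patients with subtype '", subtype, "'."),
          class = "spectriage_degenerate_error")
  }
  df <- dplyr::inner_join(sub,
                          dplyr::select(predictions, "patient_id",
                                        "predicted_class"),
                          by = "patient_id")
  tp <- sum(df$predicted_class == "cancer")
  p <- tp / nrow(df)
  ci <- ci_fun(p, nrow(df), level)
  tibble::tibble(subtype = subtype, n = nrow(df), tp = tp, estimate = p,
                 conf.low = ci[["lo"]], conf.high = ci[["hi"]])
}
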