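#' Consensus-vote configuration
#'
#' A patient is called "cancer" when at least `votes_required` of the
#' `expected_spectra` per-spectrum predictions are "cancer" (defaults 5 of 9,
#' the published decision rule). For patients with fewer usable spectra the
#' default policy is a strict majority of the available votes with exact ties
#' resolved to "cancer": the test's clinical role is rule-out, so ambiguity
#' must not produce false reassurance. Set
#' `incomplete_policy = "error"` to refuse incomplete patients instead.
#'
#' @param votes_required Cancer votes needed for a cancer call (complete
#'   patients).
#' @param expected_spectra Spectra expected per patient.
#' @param incomplete_policy `"strict_majority_of_available"` or `"error"`.
#' @return A list of class `"consensus_config"`.
#' @export
consensus_config <- function(votes_required = 5L, expected_spectra = 9L,
                             incomplete_policy = c("strict_majority_of_available",
                                                   "error")) {
  incomplete_policy <- match.arg(incomplete_policy)
  if (votes_required < 1 || votes_required > expected_spectra) {
    abort("`votes_required` must lie in 1..expected_spectra.",
          class = "spectriage_config_error")
  }
  structure(
    list(votes_required = as.integer(votes_required),
         expected_spectra = as.integer(expected_spectra),
         incomplete_policy = incomplete_policy),
    class = "consensus_config"
  )
}

#' Binarise per-spectrum probabilities into votes
#'
#' A spectrum votes "cancer" when its probability is greater than or equal to
#' the threshold (inclusive comparison, so every ROC point is
#' bit-reproducible).
#'
#' @param probs Tibble with a `p_cancer` column.
#' @param threshold Probability threshold in \[0, 1\].
#' @return `probs` with an added logical `vote` column (`TRUE` = cancer).
#' @export
#' @examples
#' spectrum_votes(tibble::tibble(p_cancer = c(0.6, 0.4)), 0.5)$vote
spectrum_votes <- function(probs, threshold) {
  if (threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].", class = "spectriage_input_error")
  }
  dplyr::mutate(probs, vote = .data$p_cancer >= threshold)
}

#' Patient-level consensus prediction from per-spectrum votes
#'
#' Aggregates the votes of each patient's spectra into one diagnosis. With
#' the expected number of votes the rule is "cancer iff at least
#' `votes_required` cancer votes"; incomplete patients follow the configured
#' policy (see [consensus_config()]).
#'
#' @param votes Tibble with `patient_id` and logical `vote` columns.
#' @param config A [consensus_config()].
#' @param threshold Optional threshold to carry through to the output.
#' @return Tibble, one row per patient: `patient_id`, `n_spectra`,
#'   `n_cancer_votes`, `predicted_class`, `threshold`.
#' @export
consensus_predict <- function(votes, config = consensus_config(),
                              threshold = NA_real_) {
  if (nrow(votes) == 0) {
    abort("No votes supplied.", class = "spectriage_input_error")
  }
  tallies <- votes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_spectra = dplyr::n(),
                     n_cancer_votes = sum(.data$vote), .groups = "drop")
  incomplete <- tallies$n_spectra != config$expected_spectra
  if (any(incomplete) && config$incomplete_policy == "error") {
    abort(paste0("Patient(s) without exactly ", config$expected_spectra,
                 " votes: ",
                 paste(head(tallies$patient_id[incomplete], 5), collapse = ", ")),
          class = "spectriage_input_error")
  }
  # strict majority of available votes, exact tie -> cancer, is equivalent to
  # requiring ceiling(n/2) cancer votes
  required <- ifelse(incomplete, ceiling(tallies$n_spectra / 2),
                     config$votes_required)
  tallies |>
    dplyr::mutate(
      predicted_class = ifelse(.data$n_cancer_votes >= required,
                               "cancer", "non-cancer"),
      threshold = threshold
    )
}

#' Threshold, votes and consensus in one step
#'
#' @param probs Tibble of per-spectrum probabilities (`patient_id`, `well`,
#'   `scan`, `p_cancer`).
#' @param threshold Probability threshold.
#' @param config A [consensus_config()].
#' @return As [consensus_predict()].
#' @export
predict_patients <- function(probs, threshold, config = consensus_config()) {
  consensus_predict(spectrum_votes(probs, threshold), config,
                    threshold = threshold)
}

# per-patient decision score: the r-th largest probability, where r is the
# number of cancer votes required for that patient. The consensus calls
# "cancer" at threshold t exactly when score >= t, which turns the consensus
# threshold sweep into a standard ROC on these scores.
.patient_scores <- function(probs, config) {
  probs |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_spectra = dplyr::n(),
      score = {
        r <- if (dplyr::n() == config$expected_spectra) {
          config$votes_required
        } else {
          ceiling(dplyr::n() / 2)
        }
        sort(.data$p_cancer, decreasing = TRUE)[r]
      },
      .groups = "drop"
    )
}

.threshold_sweep <- function(probs, truth, config) {
  scores <- .patient_scores(probs, config) |>
    dplyr::left_join(dplyr::select(truth, "patient_id", "true_class"),
                     by = "patient_id")
  if (anyNA(scores$true_class)) {
    abort("Probabilities include patients missing from the truth table.",
          class = "spectriage_format_error")
  }
  s_pos <- scores$score[scores$true_class == "cancer"]
  s_neg <- scores$score[scores$true_class == "non-cancer"]
  thresholds <- sort(unique(c(0, probs$p_cancer, 1 + 1e-9)))
  tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(s_pos >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(s_neg < t), numeric(1))
  )
}

#' Patient-level ROC curve by consensus threshold sweeping
#'
#' Recomputes the patient-level consensus prediction at every candidate
#' threshold (0, each observed probability, and one point above the maximum)
#' and records sensitivity and specificity. As the threshold rises, spectra
#' can only lose cancer votes, so sensitivity is non-increasing and
#' specificity non-decreasing; the area under the curve is computed by the
#' trapezoid rule over (1 - specificity, sensitivity), which equals the
#' concordance of the per-patient decision scores on tie-free data.
#'
#' @param probs Tibble of per-spectrum probabilities (`patient_id`, `well`,
#'   `scan`, `p_cancer`).
#' @param truth Truth tibble (`patient_id`, `true_class`), both classes
#'   present.
#' @param config A [consensus_config()].
#' @return An `"slb_roc"` tibble (`threshold`, `sensitivity`, `specificity`)
#'   with the AUC in `attr(, "auc")`; see also [roc_auc()].
#' @export
roc_curve <- function(probs, truth, config = consensus_config()) {
  if (dplyr::n_distinct(truth$true_class) < 2) {
    abort("ROC requires both classes in the truth table.",
          class = "spectriage_degenerate_error")
  }
  sweep <- .threshold_sweep(probs, truth, config)
  fpr <- 1 - sweep$specificity
  ord <- order(fpr, sweep$sensitivity)
  xs <- fpr[ord]
  ys <- sweep$sensitivity[ord]
  keep <- !duplicated(data.frame(xs, ys))
  xs <- xs[keep]; ys <- ys[keep]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  out <- sweep
  class(out) <- c("slb_roc", class(out))
  attr(out, "auc") <- auc
  out
}

#' Area under an ROC curve
#'
#' @param roc An `"slb_roc"` object from [roc_curve()].
#' @return The trapezoidal AUC as a single number.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' @exportS3Method generics::glance
glance.slb_roc <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.slb_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = 1 - object$specificity,
                       tpr = object$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Closed-form consensus operating characteristics
#'
#' `consensus_accuracy()` is the binomial tail
#' \eqn{\sum_{j \ge v} \binom{n}{j} p^j (1-p)^{n-j}}: the probability that a
#' consensus of `n_spectra` independent votes, each "cancer" with probability
#' `p`, reaches at least `votes_required` cancer votes. With the default 5-of-9
#' rule the same expression gives the patient-level accuracy for either class
#' when `p` is the per-spectrum probability of a *correct* vote, because
#' 5-of-9 is a symmetric majority. `spectrum_accuracy_for()` inverts it:
#' the per-spectrum vote probability that yields a requested patient-level
#' rate.
#'
#' @param p Per-spectrum vote probability in \[0, 1\].
#' @param target Desired patient-level rate in (0, 1).
#' @param votes_required,n_spectra Consensus rule (defaults 5 of 9).
#' @return A probability.
#' @export
#' @examples
#' consensus_accuracy(0.7)           # > 0.7: majority voting helps
#' spectrum_accuracy_for(0.8)        # per-spectrum accuracy giving 80%
consensus_accuracy <- function(p, votes_required = 5L, n_spectra = 9L) {
  1 - pbinom(votes_required - 1, n_spectra, p)
}

#' @rdname consensus_accuracy
#' @export
spectrum_accuracy_for <- function(target, votes_required = 5L, n_spectra = 9L) {
  if (target <= 0 || target >= 1) {
    abort("`target` must lie strictly inside (0, 1).",
          class = "spectriage_input_error")
  }
  uniroot(function(q) consensus_accuracy(q, votes_required, n_spectra) - target,
          interval = c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}
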