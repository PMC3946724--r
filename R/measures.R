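#' Area under the ROC curve (c statistic)
#'
#' Probability that the predicted probability of a randomly selected
#' diseased subject exceeds that of a randomly selected non-diseased
#' subject, with tied pairs scoring 1/2:
#' \deqn{AUC = \frac{1}{N_1 N_0} \sum_{i: D_i = 1} \sum_{j: D_j = 0}
#'   s(p_i, p_j),}
#' where \eqn{s} is 1 if \eqn{p_i > p_j}, 1/2 if \eqn{p_i = p_j} and 0
#' otherwise. Computed via midranks in \eqn{O(N \log N)}; identical to the
#' pairwise definition, ties included.
#'
#' @param data a [labeled_predictions()] object.
#' @return AUC in \eqn{[0, 1]}.
#' @examples
#' auc(labeled_predictions(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)))
#' @export
auc <- function(data) {
  data <- as_labeled_predictions(data)
  check_both_classes(data, "AUC")
  n1 <- as.numeric(data$n_diseased)
  n0 <- as.numeric(data$n_nondiseased)
  # midranks give the tie score of 1/2 exactly (Wilcoxon-Mann-Whitney form)
  r <- rank(data$probabilities, ties.method = "average")
  (sum(r[data$outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Sum over all ordered pairs of |p_i - p_j|, including i = j, via the
# sorted identity sum_k (2k - N - 1) p_(k) doubled. Equals the naive
# double loop exactly up to floating-point accumulation order.
abs_pairwise_sum <- function(p) {
  n <- length(p)
  ps <- sort(p)
  2 * sum((2 * seq_len(n) - n - 1) * ps)
}

#' Standardized Gini index of a prediction model
#'
#' Mean absolute pairwise difference of the predicted probabilities,
#' standardized by its value under the error-free model (the model with
#' \eqn{p_i = D_i}):
#' \deqn{Gini = \frac{\sum_i \sum_j |p_i - p_j|}{2 N^2 \bar p (1 - \bar p)}.}
#' The double sum runs over all ordered pairs including \eqn{i = j}.
#' Quantifies the "separation" a model induces between subjects: 0 when
#' every subject gets the same probability, 1 for the error-free model.
#'
#' @inheritParams auc
#' @param naive if `TRUE`, accumulate the double sum with the literal
#'   \eqn{O(N^2)} loop instead of the sorted \eqn{O(N \log N)} identity
#'   (used for cross-checking; identical result).
#' @return Gini index (in \eqn{[0, 1]} for probabilities in \eqn{[0, 1]}).
#' @export
gini_index <- function(data, naive = FALSE) {
  data <- as_labeled_predictions(data)
  check_pbar(data, "the Gini index")
  p <- data$probabilities
  n <- data$n
  total <- if (naive) {
    s <- 0
    for (i in seq_len(n)) s <- s + sum(abs(p[i] - p))
    s
  } else {
    abs_pairwise_sum(p)
  }
  total / (2 * n^2 * data$pbar * (1 - data$pbar))
}

#' Standardized Pietra index of a prediction model
#'
#' Mean absolute deviation of the predicted probabilities from the
#' reference probability \eqn{\bar p}, standardized by the error-free
#' model's value:
#' \deqn{Pietra = \frac{\sum_i |p_i - \bar p|}{2 N \bar p (1 - \bar p)}.}
#' Quantifies the "gain" over the a priori probability: how far, on
#' average, the model moves a subject away from the prior. Geometrically
#' it is the maximum vertical deviation of the Lorenz curve from the
#' diagonal, divided by \eqn{1 - \bar p} (see [pietra_from_lorenz()]).
#'
#' @inheritParams auc
#' @return Pietra index (in \eqn{[0, 1]} for probabilities in \eqn{[0, 1]}).
#' @export
pietra_index <- function(data) {
  data <- as_labeled_predictions(data)
  check_pbar(data, "the Pietra index")
  sum(abs(data$probabilities - data$pbar)) /
    (2 * data$n * data$pbar * (1 - data$pbar))
}

#' Brier score
#'
#' Mean squared difference between outcome and predicted probability,
#' \eqn{N^{-1} \sum_i (D_i - p_i)^2}. Lower is better; depends on the
#' disease prevalence, which motivates the scaled version
#' [scaled_brier()].
#'
#' @inheritParams auc
#' @return Brier score in \eqn{[0, 1]}.
#' @export
brier_score <- function(data) {
  data <- as_labeled_predictions(data)
  mean((data$outcomes - data$probabilities)^2)
}

#' Scaled Brier score (sBrier)
#'
#' The Brier score standardized against the constant-reference predictor:
#' \deqn{sBrier = 1 - \frac{Brier}{\bar p (1 - \bar p)}.}
#' Equals 1 for the error-free model, 0 for the constant predictor
#' \eqn{p_i \equiv \bar p}, and is negative for a model predicting worse
#' than the prior (returned with a warning, not clamped, since a negative
#' value is diagnostic of miscalibration).
#'
#' @inheritParams auc
#' @return scaled Brier score (\eqn{\le 1}).
#' @export
scaled_brier <- function(data) {
  data <- as_labeled_predictions(data)
  check_pbar(data, "the scaled Brier score")
  out <- 1 - brier_score(data) / (data$pbar * (1 - data$pbar))
  if (out < 0) {
    warning("scaled Brier is negative (", format(out, digits = 4),
            "): the model predicts worse than the constant-reference ",
            "predictor, indicating miscalibration")
  }
  out
}

#' Squared-gain form of the scaled Brier score
#'
#' The probability-only ratio
#' \deqn{\frac{\sum_i (p_i - \bar p)^2}{N \bar p (1 - \bar p)},}
#' i.e. the variance of the predicted probabilities relative to its
#' error-free maximum. Always in \eqn{[0, 1]} for probabilities in
#' \eqn{[0, 1]}; coincides with [scaled_brier()] whenever the predictions
#' are perfectly calibrated in-sample.
#'
#' @inheritParams auc
#' @return squared-gain ratio in \eqn{[0, 1]}.
#' @export
scaled_brier_gain <- function(data) {
  data <- as_labeled_predictions(data)
  check_pbar(data, "the scaled Brier squared gain")
  sum((data$probabilities - data$pbar)^2) /
    (data$n * data$pbar * (1 - data$pbar))
}

#' Evaluate all absolute performance measures at once
#'
#' Runs [auc()], [gini_index()], [pietra_index()], [brier_score()],
#' [scaled_brier()] and [scaled_brier_gain()] on the same sample and
#' bundles the results with sample provenance.
#'
#' @inheritParams auc
#' @return A `"performance_report"` object: list with fields `auc`,
#'   `gini`, `pietra`, `brier`, `sbrier`, `sbrier_gain`, `n`,
#'   `n_diseased`, `reference_probability`.
#' @examples
#' lp <- labeled_predictions(c(1, 0, 1, 0), c(0.8, 0.4, 0.6, 0.2))
#' evaluate_performance(lp)
#' @export
evaluate_performance <- function(data) {
  data <- as_labeled_predictions(data)
  check_both_classes(data, "the performance report")
  check_pbar(data, "the standardized indices")
  structure(
    list(auc = auc(data),
         gini = gini_index(data),
         pietra = pietra_index(data),
         brier = brier_score(data),
         sbrier = scaled_brier(data),
         sbrier_gain = scaled_brier_gain(data),
         n = data$n,
         n_diseased = data$n_diseased,
         reference_probability = data$pbar),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, digits = 4, ...) {
  cat("Prediction performance (n = ", x$n, ", diseased = ", x$n_diseased,
      ", reference p = ", format(x$reference_probability, digits = digits),
      ")\n", sep = "")
  m <- c(AUC = x$auc, Gini = x$gini, Pietra = x$pietra,
         Brier = x$brier, sBrier = x$sbrier, `sBrier gain` = x$sbrier_gain)
  print(round(m, digits))
  invisible(x)
}

#' Write a performance report to JSON or TSV
#'
#' @param report a `"performance_report"`.
#' @param path output file path.
#' @param format `"json"` (full precision) or `"tsv"` (one header row,
#'   one value row).
#' @return `path`, invisibly.
#' @export
write_performance_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "performance_report"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(unclass(report))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
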