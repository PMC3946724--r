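#' Empirical ROC curve
#'
#' Sweeps the distinct predicted probabilities from high to low as
#' thresholds; each threshold contributes the point (false positive rate,
#' true positive rate) obtained when subjects at or above it are called
#' diseased. The endpoints (0,0) and (1,1) are included exactly once.
#'
#' @inheritParams auc
#' @return A `"roc_curve"` data frame with columns `fpr` and `tpr` and
#'   attribute `thresholds`.
#' @export
roc_points <- function(data) {
  data <- as_labeled_predictions(data)
  check_both_classes(data, "the ROC curve")
  p <- data$probabilities
  d <- data$outcomes
  thr <- sort(unique(p), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(p[d == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p[d == 0] >= t), numeric(1))
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  attr(out, "thresholds") <- c(Inf, thr)
  class(out) <- c("roc_curve", "data.frame")
  out
}

# Trapezoidal area under a polyline given as (x, y) in sweep order.
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Trapezoidal area under an ROC curve
#'
#' Equals the pairwise (tie-aware) [auc()] exactly, which is asserted in
#' the package tests; exposed so the geometric and pairwise routes can be
#' compared.
#'
#' @param curve a `"roc_curve"` from [roc_points()].
#' @return area in \eqn{[0, 1]}.
#' @export
roc_area <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  trapezoid_area(curve$fpr, curve$tpr)
}

#' Lorenz curve of predicted risk
#'
#' Sorts subjects by ascending predicted probability and plots the
#' cumulative fraction of total predicted risk against the cumulative
#' population fraction. Ties are grouped into a single segment. The curve
#' starts at (0,0), ends at (1,1) and is convex (on or below the
#' diagonal): the "poorest" share of the population carries less than its
#' proportional share of the total risk.
#'
#' The curve is built from the probabilities alone, so its reference
#' probability is the mean predicted probability regardless of the
#' `reference` choice stored in `data`.
#'
#' @inheritParams auc
#' @return A `"lorenz_curve"` data frame with columns `pop_frac` and
#'   `risk_frac` and attribute `pbar` (mean predicted probability).
#' @export
lorenz_points <- function(data) {
  data <- as_labeled_predictions(data)
  p <- sort(data$probabilities)
  total <- sum(p)
  if (total == 0) {
    stop("all predicted probabilities are zero: total risk is zero, ",
         "the Lorenz curve is undefined")
  }
  n <- length(p)
  # group tied values into single vertices
  grp <- cumsum(!duplicated(p))
  counts <- tabulate(grp)
  risk <- vapply(split(p, grp), sum, numeric(1))
  out <- data.frame(pop_frac = c(0, cumsum(counts) / n),
                    risk_frac = c(0, cumsum(risk) / total))
  attr(out, "pbar") <- total / n
  class(out) <- c("lorenz_curve", "data.frame")
  out
}

lorenz_pbar <- function(curve, pbar) {
  if (is.null(pbar)) pbar <- attr(curve, "pbar")
  if (is.null(pbar) || pbar <= 0 || pbar >= 1) {
    stop("reference probability must lie strictly in (0, 1); got ", pbar)
  }
  pbar
}

#' Gini index from Lorenz-curve geometry
#'
#' The classical Gini coefficient — twice the area between the diagonal
#' and the Lorenz curve — divided by \eqn{1 - \bar p}, which standardizes
#' it against the error-free model. Equal to the formula-based
#' [gini_index()] computed with the same reference probability.
#'
#' @param curve a `"lorenz_curve"` from [lorenz_points()].
#' @param pbar reference probability; defaults to the curve's mean
#'   predicted probability.
#' @return standardized Gini index.
#' @export
gini_from_lorenz <- function(curve, pbar = NULL) {
  stopifnot(inherits(curve, "lorenz_curve"))
  pbar <- lorenz_pbar(curve, pbar)
  classical <- abs(1 - 2 * trapezoid_area(curve$pop_frac, curve$risk_frac))
  classical / (1 - pbar)
}

#' Pietra index from Lorenz-curve geometry
#'
#' The maximum vertical deviation of the Lorenz curve from the diagonal,
#' divided by \eqn{1 - \bar p}. The maximum is attained at a vertex (the
#' deviation is piecewise linear in the population fraction), so it is
#' computed exactly over the vertices. Equal to the formula-based
#' [pietra_index()] with the same reference probability.
#'
#' @inheritParams gini_from_lorenz
#' @return standardized Pietra index.
#' @export
pietra_from_lorenz <- function(curve, pbar = NULL) {
  stopifnot(inherits(curve, "lorenz_curve"))
  pbar <- lorenz_pbar(curve, pbar)
  max(abs(curve$pop_frac - curve$risk_frac)) / (1 - pbar)
}

#' Write an ROC or Lorenz curve as two-column TSV
#'
#' @param curve a `"roc_curve"` or `"lorenz_curve"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, c("roc_curve", "lorenz_curve")))
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.lorenz_curve <- function(x, ...) {
  plot(x$pop_frac, x$risk_frac, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Cumulative population fraction",
       ylab = "Cumulative risk fraction", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
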