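#' Labeled predictions for one model on one sample
#'
#' Bundles a vector of binary disease outcomes with the predicted
#' probabilities assigned to the same subjects by one prediction model.
#' All absolute performance measures ([auc()], [gini_index()],
#' [pietra_index()], [brier_score()], [scaled_brier()]) take this object.
#'
#' The reference probability \eqn{\bar p} used to standardize the Gini,
#' Pietra and scaled-Brier indices is, by default, the observed disease
#' prevalence \eqn{N_1/N}. For a model that is perfectly calibrated on
#' the sample the two choices coincide; `reference = "mean_predicted"`
#' uses the mean predicted probability instead, which is the natural
#' reference when the curve is built from the probabilities alone.
#'
#' @param outcomes integer/numeric/logical vector of 0/1 disease indicators.
#' @param probabilities numeric vector of predicted probabilities in
#'   \eqn{[0, 1]}, same length and subject order as `outcomes`.
#' @param reference how the reference probability \eqn{\bar p} is formed:
#'   `"prevalence"` (default, \eqn{N_1/N}) or `"mean_predicted"`.
#' @return An object of class `"labeled_predictions"`: a list with elements
#'   `outcomes`, `probabilities`, `n`, `n_diseased`, `n_nondiseased`,
#'   `reference` and `pbar`.
#' @examples
#' lp <- labeled_predictions(c(1, 0, 1, 0), c(0.8, 0.4, 0.6, 0.2))
#' lp$pbar
#' @export
labeled_predictions <- function(outcomes, probabilities,
                                reference = c("prevalence", "mean_predicted")) {
  reference <- match.arg(reference)
  if (is.logical(outcomes)) outcomes <- as.integer(outcomes)
  outcomes <- as.numeric(outcomes)
  probabilities <- as.numeric(probabilities)
  if (length(outcomes) != length(probabilities)) {
    stop("`outcomes` and `probabilities` must have the same length (",
         length(outcomes), " vs ", length(probabilities), ")")
  }
  if (length(outcomes) < 2L) {
    stop("at least 2 subjects are required")
  }
  if (anyNA(outcomes) || anyNA(probabilities)) {
    stop("missing values are not allowed in outcomes or probabilities")
  }
  if (!all(outcomes %in% c(0, 1))) {
    stop("`outcomes` must be binary 0/1")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("`probabilities` must lie in [0, 1]")
  }
  n <- length(outcomes)
  n1 <- sum(outcomes)
  pbar <- if (reference == "prevalence") n1 / n else mean(probabilities)
  structure(
    list(outcomes = outcomes,
         probabilities = probabilities,
         n = n,
         n_diseased = as.integer(n1),
         n_nondiseased = as.integer(n - n1),
         reference = reference,
         pbar = pbar),
    class = "labeled_predictions"
  )
}

#' @export
print.labeled_predictions <- function(x, ...) {
  cat("Labeled predictions: ", x$n, " subjects (",
      x$n_diseased, " diseased, ", x$n_nondiseased, " non-diseased)\n",
      "reference probability (", x$reference, "): ",
      format(x$pbar, digits = 4), "\n", sep = "")
  invisible(x)
}

# Coerce plain vectors on the fly so measure functions accept either an
# object or (outcomes, probabilities) pairs funneled through this helper.
as_labeled_predictions <- function(data) {
  if (inherits(data, "labeled_predictions")) return(data)
  stop("`data` must be a labeled_predictions object; see labeled_predictions()")
}

check_both_classes <- function(data, what = "this measure") {
  if (data$n_diseased == 0L) {
    stop("degenerate sample: no diseased subjects (all outcomes 0); ",
         what, " is undefined")
  }
  if (data$n_nondiseased == 0L) {
    stop("degenerate sample: no non-diseased subjects (all outcomes 1); ",
         what, " is undefined")
  }
  invisible(TRUE)
}

check_pbar <- function(data, what = "this measure") {
  if (data$pbar <= 0 || data$pbar >= 1) {
    stop("reference probability is ", data$pbar, "; the error-free ",
         "normalizer of ", what, " is zero for a degenerate reference")
  }
  invisible(TRUE)
}

#' Read labeled predictions from a delimited text file
#'
#' Reads a header-ed CSV/TSV with one binary outcome column and one or more
#' predicted-probability columns. Rows containing missing values in the
#' used columns are rejected with their line numbers reported.
#'
#' @param path file path.
#' @param outcome_col name of the 0/1 outcome column.
#' @param probability_cols character vector of probability column names;
#'   default: every other numeric column.
#' @param delimiter field delimiter; `","` (default) or `"\t"` etc.
#' @param reference passed to [labeled_predictions()].
#' @return A named list of `labeled_predictions`, one per probability column.
#' @export
read_predictions <- function(path, outcome_col = "outcome",
                             probability_cols = NULL, delimiter = ",",
                             reference = c("prevalence", "mean_predicted")) {
  reference <- match.arg(reference)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!outcome_col %in% names(df)) {
    stop("outcome column '", outcome_col, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  }
  if (is.null(probability_cols)) {
    probability_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                                outcome_col)
  }
  missing_cols <- setdiff(probability_cols, names(df))
  if (length(missing_cols)) {
    stop("probability column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  used <- df[, c(outcome_col, probability_cols), drop = FALSE]
  bad <- which(!stats::complete.cases(used))
  if (length(bad)) {
    # +1 for the header line so the numbers match the raw file
    stop("missing values in rows (file line numbers): ",
         paste(bad + 1L, collapse = ", "))
  }
  out <- lapply(probability_cols, function(cn) {
    labeled_predictions(df[[outcome_col]], df[[cn]], reference = reference)
  })
  names(out) <- probability_cols
  out
}
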