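#' Paired predictions from two models on the same subjects
#'
#' Holds the outcomes together with the predicted probabilities of a
#' baseline ("old") and an extended ("new") model, in the same subject
#' order, for the relative comparison measures [nri()], [cnri()], [idi()]
#' and [compare_models()].
#'
#' @param outcomes 0/1 disease indicators.
#' @param old numeric vector of baseline-model probabilities in \eqn{[0,1]}.
#' @param new numeric vector of extended-model probabilities in \eqn{[0,1]}.
#' @param reference reference-probability rule, passed through to the
#'   per-model [labeled_predictions()].
#' @return A `"paired_predictions"` object.
#' @export
paired_predictions <- function(outcomes, old, new,
                               reference = c("prevalence", "mean_predicted")) {
  reference <- match.arg(reference)
  lp_old <- labeled_predictions(outcomes, old, reference = reference)
  lp_new <- labeled_predictions(outcomes, new, reference = reference)
  structure(
    list(outcomes = lp_old$outcomes,
         old = lp_old$probabilities,
         new = lp_new$probabilities,
         lp_old = lp_old,
         lp_new = lp_new,
         n = lp_old$n),
    class = "paired_predictions"
  )
}

#' Risk categories from interior cutpoints
#'
#' @param cutpoints strictly increasing cutpoints in (0, 1) partitioning
#'   \eqn{[0, 1]} into ordered risk classes.
#' @return A `"risk_categories"` object (the validated cutpoint vector).
#' @export
risk_categories <- function(cutpoints) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1L) stop("at least one cutpoint is required")
  if (any(cutpoints <= 0 | cutpoints >= 1)) {
    stop("cutpoints must lie strictly in (0, 1)")
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  structure(cutpoints, class = "risk_categories")
}

assign_category <- function(p, categories) {
  findInterval(p, unclass(categories)) + 1L
}

# Shared up/down contrast: move is +1/0/-1 per subject.
reclassification_contrast <- function(outcomes, move) {
  d <- outcomes == 1
  (mean(move[d] > 0) - mean(move[d] < 0)) -
    (mean(move[!d] > 0) - mean(move[!d] < 0))
}

#' Net reclassification improvement (NRI)
#'
#' Difference between the proportion of subjects moving to a higher risk
#' category and the proportion moving to a lower one under the new model,
#' computed among diseased subjects, minus the corresponding difference
#' among non-diseased subjects. Ranges over \eqn{[-2, 2]}.
#'
#' @param data a [paired_predictions()] object.
#' @param categories a [risk_categories()] object (or numeric cutpoints).
#' @param components if `TRUE`, also return the event / non-event parts.
#' @return NRI as a single number, or (with `components = TRUE`) a list
#'   with `nri`, `nri_events`, `nri_nonevents`.
#' @export
nri <- function(data, categories, components = FALSE) {
  stopifnot(inherits(data, "paired_predictions"))
  if (!inherits(categories, "risk_categories")) {
    categories <- risk_categories(categories)
  }
  check_both_classes(data$lp_old, "NRI")
  move <- assign_category(data$new, categories) -
    assign_category(data$old, categories)
  if (!components) return(reclassification_contrast(data$outcomes, move))
  d <- data$outcomes == 1
  ev <- mean(move[d] > 0) - mean(move[d] < 0)
  ne <- mean(move[!d] < 0) - mean(move[!d] > 0)
  list(nri = ev + ne, nri_events = ev, nri_nonevents = ne)
}

#' Continuous (category-free) NRI
#'
#' Same contrast as [nri()] but any increase in predicted probability is
#' a movement up and any decrease a movement down; exact ties count as no
#' movement. Ranges over \eqn{[-2, 2]}.
#'
#' @inheritParams nri
#' @return cNRI as a single number.
#' @export
cnri <- function(data) {
  stopifnot(inherits(data, "paired_predictions"))
  check_both_classes(data$lp_old, "cNRI")
  reclassification_contrast(data$outcomes, sign(data$new - data$old))
}

#' Integrated discrimination improvement (IDI)
#'
#' Change in the discrimination slope (mean predicted probability among
#' the diseased minus mean among the non-diseased) from the old model to
#' the new one; the actual amount of probability movement is counted
#' rather than just its direction. Ranges over \eqn{[-1, 1]}. For models
#' perfectly calibrated in-sample, IDI equals the change in the scaled
#' Brier score.
#'
#' @inheritParams nri
#' @return IDI as a single number.
#' @export
idi <- function(data) {
  stopifnot(inherits(data, "paired_predictions"))
  check_both_classes(data$lp_old, "IDI")
  d <- data$outcomes == 1
  slope_new <- mean(data$new[d]) - mean(data$new[!d])
  slope_old <- mean(data$old[d]) - mean(data$old[!d])
  slope_new - slope_old
}

#' Compare two prediction models on the same sample
#'
#' Computes both models' absolute measures, their absolute improvements
#' (new minus old), the relative improvements in percent of the old
#' value, and the relative measures cNRI, IDI and (when risk categories
#' are supplied) NRI.
#'
#' @inheritParams nri
#' @param categories optional [risk_categories()] (or numeric cutpoints);
#'   when omitted, NRI is not computed.
#' @return A `"comparison_report"` list with elements `old`, `new`
#'   (performance reports), `delta` and `relative_pct` (named vectors over
#'   auc/gini/pietra/sbrier), `nri`, `nri_components`, `cnri`, `idi`.
#'   A relative improvement is `NaN`-flagged when the old index is 0.
#' @export
compare_models <- function(data, categories = NULL) {
  stopifnot(inherits(data, "paired_predictions"))
  rep_old <- evaluate_performance(data$lp_old)
  rep_new <- evaluate_performance(data$lp_new)
  keys <- c("auc", "gini", "pietra", "sbrier")
  old_v <- unlist(rep_old[keys])
  new_v <- unlist(rep_new[keys])
  delta <- new_v - old_v
  relative <- ifelse(old_v == 0, NaN, 100 * delta / old_v)
  nri_val <- NULL
  nri_comp <- NULL
  if (!is.null(categories)) {
    nri_comp <- nri(data, categories, components = TRUE)
    nri_val <- nri_comp$nri
  }
  structure(
    list(old = rep_old, new = rep_new,
         delta = delta, relative_pct = relative,
         nri = nri_val, nri_components = nri_comp,
         cnri = cnri(data), idi = idi(data)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  keys <- c("auc", "gini", "pietra", "sbrier")
  tab <- rbind(old = unlist(x$old[keys]),
               new = unlist(x$new[keys]),
               delta = x$delta,
               `relative %` = x$relative_pct)
  colnames(tab) <- c("AUC", "Gini", "Pietra", "sBrier")
  cat("Model comparison (new vs old)\n")
  print(round(tab, digits))
  if (!is.null(x$nri)) cat("NRI:  ", format(x$nri, digits = digits), "\n")
  cat("cNRI: ", format(x$cnri, digits = digits), "\n")
  cat("IDI:  ", format(x$idi, digits = digits), "\n")
  invisible(x)
}

#' Write a comparison report as JSON or a summary-table TSV
#'
#' The TSV mirrors the usual presentation: one row per model with the
#' four absolute measures, then an improvement row formatted as
#' "absolute (+relative%)".
#'
#' @param report a `"comparison_report"`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "comparison_report"))
  if (format == "json") {
    payload <- list(
      old = unclass(report$old), new = unclass(report$new),
      delta = as.list(report$delta),
      relative_pct = as.list(report$relative_pct),
      nri = report$nri, nri_components = report$nri_components,
      cnri = report$cnri, idi = report$idi)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    keys <- c("auc", "gini", "pietra", "sbrier")
    fmt_cell <- function(d, r) {
      sprintf("%+.3f (%+.1f%%)", d, r)
    }
    lines <- c(
      paste(c("model", "AUC", "Gini", "Pietra", "sBrier"), collapse = "\t"),
      paste(c("old", sprintf("%.3f", unlist(report$old[keys]))), collapse = "\t"),
      paste(c("new", sprintf("%.3f", unlist(report$new[keys]))), collapse = "\t"),
      paste(c("improvement",
              mapply(fmt_cell, report$delta, report$relative_pct)),
            collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Audit pairwise NRI/cNRI orderings for non-transitivity
#'
#' For three or more models evaluated on the same subjects, computes the
#' pairwise NRI (and cNRI) between every ordered pair and reports every
#' triple (A, B, C) whose pairwise preferences form a cycle: A beats B
#' and B beats C, yet C beats A. Because the absolute measures (AUC,
#' Gini, Pietra, sBrier) attach a single real number to each model, the
#' orderings they induce can never cycle; the audit recomputes them on
#' the same triples to exhibit the contrast.
#'
#' A pair is scored by `nri(old = Y, new = X)`: X beats Y when the value
#' is positive.
#'
#' @param models list of \eqn{\ge 3} probability vectors (named or not),
#'   one per model, all on the same subjects.
#' @param outcomes 0/1 disease indicators for those subjects.
#' @param categories a [risk_categories()] object or numeric cutpoints
#'   used for the NRI preferences.
#' @return A list with `nri_cycles` and `cnri_cycles` (data frames of
#'   intransitive triples with the three pairwise values; zero rows when
#'   none), `absolute_transitive` (`TRUE`; real-valued indices cannot
#'   cycle) and the pairwise matrices `nri_matrix`, `cnri_matrix`.
#' @export
transitivity_audit <- function(models, outcomes, categories) {
  if (length(models) < 3L) stop("at least 3 models are required")
  if (!inherits(categories, "risk_categories")) {
    categories <- risk_categories(categories)
  }
  k <- length(models)
  if (is.null(names(models))) names(models) <- paste0("model", seq_len(k))
  nm <- names(models)
  nri_m <- matrix(0, k, k, dimnames = list(new = nm, old = nm))
  cnri_m <- nri_m
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      pp <- paired_predictions(outcomes, old = models[[j]], new = models[[i]])
      nri_m[i, j] <- nri(pp, categories)
      cnri_m[i, j] <- cnri(pp)
    }
  }
  find_cycles <- function(m) {
    rows <- list()
    for (tr in utils::combn(k, 3, simplify = FALSE)) {
      for (perm in list(tr, tr[c(1, 3, 2)])) {
        a <- perm[1]; b <- perm[2]; c <- perm[3]
        # cycle a > b > c > a
        if (m[a, b] > 0 && m[b, c] > 0 && m[c, a] > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            a = nm[a], b = nm[b], c = nm[c],
            a_vs_b = m[a, b], b_vs_c = m[b, c], c_vs_a = m[c, a])
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(a = character(), b = character(), c = character(),
                 a_vs_b = numeric(), b_vs_c = numeric(), c_vs_a = numeric())
  }
  list(nri_cycles = find_cycles(nri_m),
       cnri_cycles = find_cycles(cnri_m),
       absolute_transitive = TRUE,
       nri_matrix = nri_m,
       cnri_matrix = cnri_m)
}

#' Randomized search for an NRI preference cycle
#'
#' Repeatedly generates small synthetic cohorts with three candidate
#' probability vectors and audits them until a pairwise-NRI cycle is
#' found (or the iteration budget is exhausted). The three candidate
#' models are random perturbations of a common risk signal, so each is a
#' plausible model of the same outcome.
#'
#' @param n_subjects cohort size per attempt.
#' @param categories cutpoints for the NRI; default tertile-style cuts.
#' @param max_tries iteration budget.
#' @param seed RNG seed for reproducibility.
#' @return The first audit result containing at least one NRI cycle,
#'   with the generating `models`/`outcomes` attached, or `NULL` if none
#'   was found within the budget.
#' @export
find_nri_cycle <- function(n_subjects = 20, categories = c(1/3, 2/3),
                           max_tries = 2000, seed = 1L) {
  categories <- risk_categories(categories)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    risk <- stats::runif(n_subjects)
    outcomes <- stats::rbinom(n_subjects, 1, risk)
    if (sum(outcomes) == 0 || sum(outcomes) == n_subjects) next
    jitter_model <- function() {
      pmin(pmax(risk + stats::runif(n_subjects, -0.45, 0.45), 0), 1)
    }
    models <- list(A = jitter_model(), B = jitter_model(), C = jitter_model())
    audit <- transitivity_audit(models, outcomes, categories)
    if (nrow(audit$nri_cycles) > 0) {
      audit$models <- models
      audit$outcomes <- outcomes
      audit$tries <- try
      return(audit)
    }
  }
  NULL
}
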