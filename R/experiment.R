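#' Fit a logistic risk model on a training cohort
#'
#' Maximum-likelihood logistic regression of the outcome on the named
#' covariates, via iteratively reweighted least squares. The covariate
#' `"m2k"` denotes the kernel-modulated marker term \eqn{K(B) M_2}
#' (built from `kernel_width`); it lets the fitted model mirror the
#' gray-zone structure of the generating process, whereas plain `"m2"`
#' is the main-effects reading in which the analyst does not know the
#' kernel.
#'
#' Non-convergence or (quasi-)complete separation is signalled as a
#' condition of class `"riskgauge_skip"` rather than returning a silently
#' wrong fit, so replicate loops can count and skip such fits.
#'
#' @param train a `"cohort"` data frame (needs an outcome column `d`).
#' @param covariates character vector of covariate names among the
#'   cohort's columns, plus optionally `"m2k"`.
#' @param kernel_width kernel scale used to build the `m2k` term.
#' @return A `"risk_model"` object wrapping the glm fit; use
#'   [predict_risk()] to obtain probabilities.
#' @export
fit_risk_model <- function(train, covariates, kernel_width = 1) {
  train <- as.data.frame(train)
  if (!"d" %in% names(train)) stop("training cohort must have a `d` column")
  if (length(unique(train$d)) < 2L) {
    skip_replicate("training outcome has a single class")
  }
  train <- add_kernel_column(train, covariates, kernel_width)
  missing_cov <- setdiff(covariates, names(train))
  if (length(missing_cov)) {
    stop("covariate(s) not found in cohort: ",
         paste(missing_cov, collapse = ", "))
  }
  fml <- stats::as.formula(paste("d ~", paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = train,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        skip_replicate(conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || any(!is.finite(stats::coef(fit)))) {
    skip_replicate("logistic fit did not converge")
  }
  structure(list(fit = fit, covariates = covariates,
                 kernel_width = kernel_width),
            class = "risk_model")
}

#' Predicted probabilities from a fitted risk model
#'
#' @param model a `"risk_model"` from [fit_risk_model()].
#' @param newdata a cohort (or data frame) with the model's covariates.
#' @return probabilities strictly inside \eqn{(0, 1)}.
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "risk_model"))
  newdata <- add_kernel_column(as.data.frame(newdata), model$covariates,
                               model$kernel_width)
  p <- stats::predict(model$fit, newdata = newdata, type = "response")
  # guard the open-interval contract against numerical saturation
  eps <- .Machine$double.eps
  pmin(pmax(as.numeric(p), eps), 1 - eps)
}

add_kernel_column <- function(df, covariates, kernel_width) {
  if ("m2k" %in% covariates && !"m2k" %in% names(df)) {
    if (!all(c("b", "m2") %in% names(df))) {
      stop("the kernel-modulated term `m2k` needs columns `b` and `m2`")
    }
    df$m2k <- gaussian_kernel(df$b, kernel_width) * df$m2
  }
  df
}

skip_replicate <- function(reason) {
  stop(structure(class = c("riskgauge_skip", "error", "condition"),
                 list(message = reason, call = NULL)))
}

#' Evaluate fitted models on a validation cohort
#'
#' Applies each fitted model to the validation covariates and runs
#' [evaluate_performance()] on the resulting labeled predictions.
#'
#' @param models named list of `"risk_model"` objects.
#' @param validation a `"cohort"` with the outcome column `d`.
#' @param reference reference-probability rule for the standardized
#'   indices.
#' @return named list of `"performance_report"` objects.
#' @export
evaluate_models <- function(models, validation,
                            reference = c("prevalence", "mean_predicted")) {
  reference <- match.arg(reference)
  validation <- as.data.frame(validation)
  if (length(unique(validation$d)) < 2L) {
    skip_replicate("validation outcome has a single class")
  }
  lapply(models, function(m) {
    lp <- labeled_predictions(validation$d, predict_risk(m, validation),
                              reference = reference)
    evaluate_performance(lp)
  })
}

#' Configuration of a marker-addition experiment
#'
#' Describes the replicate experiment: per replicate, a training and a
#' validation cohort are simulated, the candidate models are fitted on
#' the training cohort and all absolute measures are computed on the
#' evaluation sample (validation by default; training available for
#' sensitivity checks).
#'
#' The default model set is the three-model comparison: the baseline
#' score alone (`B`), baseline plus the uniform-effect marker
#' (`B+M1`), and baseline plus the gray-zone marker (`B+M2`).
#' `m2_form` selects how the third model uses M2: `"kernel"` fits the
#' kernel-modulated term \eqn{K(B) M_2} (analyst knows the gray-zone
#' structure; the default), `"main"` fits M2 as a plain main effect.
#'
#' @param n_train,n_validation cohort sizes; default 500 each.
#' @param n_replicates number of replicates; default 10000.
#' @param base_seed integer; replicate `r` re-seeds the RNG at
#'   `base_seed + r`, so results are reproducible and replicates can be
#'   re-run in isolation.
#' @param params a [generating_params()] object.
#' @param m2_form `"kernel"` or `"main"` (see above).
#' @param evaluate_on `"validation"` (default) or `"training"`.
#' @return An `"experiment_config"` list, with a `models` element giving
#'   the covariate set of each fitted model.
#' @export
experiment_config <- function(n_train = 500, n_validation = 500,
                              n_replicates = 10000, base_seed = 20140307,
                              params = generating_params(),
                              m2_form = c("kernel", "main"),
                              evaluate_on = c("validation", "training")) {
  m2_form <- match.arg(m2_form)
  evaluate_on <- match.arg(evaluate_on)
  stopifnot(inherits(params, "generating_params"))
  if (n_train < 2 || n_validation < 2 || n_replicates < 1) {
    stop("cohort sizes must be >= 2 and n_replicates >= 1")
  }
  m2_cov <- if (m2_form == "kernel") "m2k" else "m2"
  structure(
    list(n_train = n_train, n_validation = n_validation,
         n_replicates = n_replicates, base_seed = base_seed,
         params = params, m2_form = m2_form, evaluate_on = evaluate_on,
         models = list(B = "b",
                       `B+M1` = c("b", "m1"),
                       `B+M2` = c("b", m2_cov))),
    class = "experiment_config"
  )
}

#' Run the replicate marker-addition experiment
#'
#' For each replicate: simulate training and validation cohorts, fit the
#' configured models on the training cohort, evaluate AUC, Gini, Pietra,
#' Brier and sBrier on the evaluation sample, and collect. Replicates in
#' which a cohort is single-class or a fit fails to converge are skipped
#' and counted, never imputed. Aggregation is the arithmetic mean over
#' the retained replicates; improvements are reported both as means of
#' per-replicate deltas and as deltas of the aggregate means (identical
#' up to floating point), with relative improvements in percent of the
#' baseline aggregate.
#'
#' @param config an [experiment_config()].
#' @param keep_predictions pool the evaluation-sample predicted
#'   probabilities across replicates (for [probability_histograms()])?
#'   Off by default: it stores n_replicates x n_validation x models
#'   numbers.
#' @param progress print a progress line every 500 replicates.
#' @return A `"table1_result"` list: `measures` (mean and Monte-Carlo SE
#'   per model x measure), `improvements` (absolute, relative %, SE, per
#'   contrast x measure), `n_replicates_used`, `n_skipped`,
#'   `skip_reasons`, `replicates` (per-replicate measure array) and
#'   optionally `pooled_predictions`.
#' @export
run_experiment <- function(config, keep_predictions = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  measures <- c("auc", "gini", "pietra", "brier", "sbrier")
  model_names <- names(config$models)
  res <- array(NA_real_,
               dim = c(config$n_replicates, length(model_names),
                       length(measures)),
               dimnames = list(NULL, model_names, measures))
  skip_reasons <- character(0)
  pooled <- if (keep_predictions) vector("list", config$n_replicates) else NULL
  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$base_seed + r
    one <- tryCatch({
      set.seed(seed_r)
      train <- simulate_cohort(config$n_train, config$params)
      validation <- simulate_cohort(config$n_validation, config$params)
      eval_sample <- if (config$evaluate_on == "validation") validation else train
      fits <- lapply(config$models, fit_risk_model, train = train,
                     kernel_width = config$params$kernel_width)
      reports <- evaluate_models(fits, eval_sample)
      preds <- if (keep_predictions) {
        lapply(fits, predict_risk, newdata = eval_sample)
      }
      list(reports = reports, preds = preds, d = eval_sample$d)
    }, riskgauge_skip = function(e) e)
    if (inherits(one, "riskgauge_skip")) {
      skip_reasons <- c(skip_reasons, conditionMessage(one))
      next
    }
    for (m in model_names) {
      res[r, m, ] <- unlist(one$reports[[m]][measures])
    }
    if (keep_predictions) {
      pooled[[r]] <- data.frame(
        replicate = r,
        d = rep(one$d, times = length(model_names)),
        model = rep(model_names, each = length(one$d)),
        p = unlist(one$preds, use.names = FALSE))
    }
    if (progress && r %% 500 == 0) {
      message("replicate ", r, "/", config$n_replicates)
    }
  }
  used <- which(!is.na(res[, 1, 1]))
  if (!length(used)) stop("all replicates were degenerate or non-convergent")
  res_used <- res[used, , , drop = FALSE]
  mean_tab <- apply(res_used, c(2, 3), mean)
  se_tab <- apply(res_used, c(2, 3), stats::sd) / sqrt(length(used))
  contrasts <- list(`B -> B+M1` = c("B", "B+M1"),
                    `B -> B+M2` = c("B", "B+M2"))
  contrasts <- Filter(function(ct) all(ct %in% model_names), contrasts)
  improvements <- lapply(contrasts, function(ct) {
    deltas <- res_used[, ct[2], ] - res_used[, ct[1], ]
    abs_imp <- colMeans(deltas)
    list(absolute = abs_imp,
         absolute_se = apply(deltas, 2, stats::sd) / sqrt(length(used)),
         delta_of_means = mean_tab[ct[2], ] - mean_tab[ct[1], ],
         relative_pct = 100 * abs_imp / mean_tab[ct[1], ])
  })
  structure(
    list(measures = list(mean = mean_tab, se = se_tab),
         improvements = improvements,
         n_replicates_used = length(used),
         n_skipped = config$n_replicates - length(used),
         skip_reasons = skip_reasons,
         replicates = res_used,
         pooled_predictions = if (keep_predictions) {
           do.call(rbind, pooled[used])
         },
         config = config),
    class = "table1_result"
  )
}

#' @export
print.table1_result <- function(x, digits = 3, ...) {
  keys <- c("auc", "gini", "pietra", "sbrier")
  cat("Marker-addition experiment: ", x$n_replicates_used,
      " replicates used (", x$n_skipped, " skipped)\n\n", sep = "")
  tab <- x$measures$mean[, keys, drop = FALSE]
  colnames(tab) <- c("AUC", "Gini", "Pietra", "sBrier")
  print(round(tab, digits))
  cat("\nAbsolute (relative) improvement\n")
  for (nm in names(x$improvements)) {
    imp <- x$improvements[[nm]]
    cells <- sprintf("%+.3f (%+.1f%%)",
                     imp$absolute[keys], imp$relative_pct[keys])
    cat(format(nm, width = 12), paste(format(cells, width = 16),
                                      collapse = " "), "\n")
  }
  invisible(x)
}

#' Write the experiment summary table
#'
#' @param result a `"table1_result"`.
#' @param path output file path.
#' @param format `"tsv"` (model rows, measure columns, improvement rows
#'   with "absolute (+relative%)" cells) or `"json"` (full precision).
#' @return `path`, invisibly.
#' @export
write_table1 <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "table1_result"))
  keys <- c("auc", "gini", "pietra", "sbrier")
  if (format == "json") {
    payload <- list(
      measures_mean = apply(result$measures$mean, 1, as.list),
      measures_se = apply(result$measures$se, 1, as.list),
      improvements = lapply(result$improvements, lapply, as.list),
      n_replicates_used = result$n_replicates_used,
      n_skipped = result$n_skipped)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    header <- paste(c("model", "AUC", "Gini", "Pietra", "sBrier"),
                    collapse = "\t")
    model_rows <- vapply(rownames(result$measures$mean), function(nm) {
      paste(c(nm, sprintf("%.3f", result$measures$mean[nm, keys])),
            collapse = "\t")
    }, character(1))
    imp_rows <- vapply(names(result$improvements), function(nm) {
      imp <- result$improvements[[nm]]
      cells <- sprintf("%+.3f (%+.1f%%)",
                       imp$absolute[keys], imp$relative_pct[keys])
      paste(c(nm, cells), collapse = "\t")
    }, character(1))
    writeLines(c(header, model_rows, imp_rows), path)
  }
  invisible(path)
}

#' Histograms of predicted probabilities by model and disease status
#'
#' Bins the pooled evaluation-sample predicted probabilities of each
#' model, separately for diseased and non-diseased subjects, and records
#' the grand mean and the class-specific means of the predictions — the
#' display in which a gray-zone resolving marker shows up as a depletion
#' of mass near the grand mean.
#'
#' @param pooled the `pooled_predictions` data frame of a
#'   [run_experiment()] call made with `keep_predictions = TRUE` (columns
#'   `model`, `d`, `p`).
#' @param breaks histogram break points on \eqn{[0, 1]}.
#' @return A list with `counts` (data frame: model, disease status, bin
#'   midpoint, count) and `means` (per model: grand, diseased and
#'   non-diseased mean predicted probability).
#' @export
probability_histograms <- function(pooled, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(is.data.frame(pooled),
            all(c("model", "d", "p") %in% names(pooled)))
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  counts <- do.call(rbind, lapply(split(pooled, pooled[c("model", "d")]),
    function(chunk) {
      if (!nrow(chunk)) return(NULL)
      h <- hist(chunk$p, breaks = breaks, plot = FALSE)
      data.frame(model = chunk$model[1], d = chunk$d[1],
                 mid = mids, count = h$counts)
    }))
  rownames(counts) <- NULL
  means <- do.call(rbind, lapply(split(pooled, pooled$model), function(chunk) {
    data.frame(model = chunk$model[1],
               grand_mean = mean(chunk$p),
               mean_diseased = mean(chunk$p[chunk$d == 1]),
               mean_nondiseased = mean(chunk$p[chunk$d == 0]))
  }))
  rownames(means) <- NULL
  list(counts = counts, means = means)
}
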