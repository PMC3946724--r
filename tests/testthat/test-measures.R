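test_that("worked toy examples reproduce exactly", {
  # AUC
  expect_equal(auc(labeled_predictions(c(1, 0), c(0.9, 0.1))), 1)
  expect_equal(auc(labeled_predictions(c(1, 0), c(0.5, 0.5))), 0.5)
  expect_equal(auc(labeled_predictions(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))),
               0.75)
  # Gini / Pietra / sBrier gain on the evenly spread probabilities
  lp <- labeled_predictions(c(1, 0, 1, 0), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(gini_index(lp), 0.5)
  expect_equal(pietra_index(lp), 0.4)
  expect_equal(scaled_brier_gain(lp), 0.2)
  # Brier / sBrier
  lp2 <- labeled_predictions(c(1, 0, 1, 0), c(0.8, 0.4, 0.6, 0.2))
  expect_equal(brier_score(lp2), 0.1)
  expect_equal(scaled_brier(lp2), 0.6)
})

test_that("error-free and constant-prior models sit at the index boundaries", {
  d <- c(1, 1, 0, 0)
  perfect <- labeled_predictions(d, d)
  expect_equal(auc(perfect), 1)
  expect_equal(gini_index(perfect), 1)
  expect_equal(pietra_index(perfect), 1)
  expect_equal(brier_score(perfect), 0)
  expect_equal(scaled_brier(perfect), 1)
  expect_equal(scaled_brier_gain(perfect), 1)

  constant <- labeled_predictions(d, rep(0.5, 4))
  expect_equal(auc(constant), 0.5)
  expect_equal(gini_index(constant), 0)
  expect_equal(pietra_index(constant), 0)
  expect_equal(brier_score(constant), 0.25)
  expect_equal(scaled_brier(constant), 0)
  expect_equal(scaled_brier_gain(constant), 0)
})

test_that("rank-based AUC equals the brute-force pairwise definition", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_sample(n = sample(5:60, 1), ties = (i %% 2 == 0))
    expect_equal(auc(labeled_predictions(s$d, s$p)), pairwise_auc(s$d, s$p),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    s <- random_sample(n = 80, ties = (i %% 2 == 0))
    oracle <- as.numeric(pROC::auc(pROC::roc(s$d, s$p, quiet = TRUE,
                                             direction = "<")))
    expect_equal(auc(labeled_predictions(s$d, s$p)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("sorted O(N log N) Gini accumulation matches the naive double loop", {
  set.seed(31)
  for (n in c(2, 3, 10, 57, 200)) {
    s <- random_sample(n = n, ties = (n > 50))
    lp <- labeled_predictions(s$d, s$p)
    expect_equal(gini_index(lp), gini_index(lp, naive = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("calibrated samples satisfy gini = 2 auc - 1 and sbrier = squared gain", {
  set.seed(41)
  for (i in 1:40) {
    s <- calibrated_sample(n_groups = sample(3:7, 1))
    lp <- labeled_predictions(s$d, s$p)
    expect_equal(gini_index(lp), 2 * auc(lp) - 1, tolerance = 1e-9)
    expect_equal(scaled_brier(lp), scaled_brier_gain(lp), tolerance = 1e-9)
  }
})

test_that("all indices are invariant to permutation of subjects", {
  set.seed(51)
  s <- random_sample(n = 40)
  lp <- labeled_predictions(s$d, s$p)
  idx <- sample(40)
  lp2 <- labeled_predictions(s$d[idx], s$p[idx])
  for (f in list(auc, gini_index, pietra_index, brier_score,
                 scaled_brier, scaled_brier_gain)) {
    # a random model may be anti-calibrated; the negative-sBrier warning
    # is expected and not under test here
    expect_equal(suppressWarnings(f(lp)), suppressWarnings(f(lp2)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs raise informative errors, not NaN", {
  expect_error(labeled_predictions(c(1, 0), c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(labeled_predictions(c(1, 2), c(0.2, 0.4)), "binary")
  expect_error(labeled_predictions(1, 0.5), "at least 2")
  expect_error(labeled_predictions(c(1, 0), c(0.5, NA)), "missing")
  all_one <- labeled_predictions(c(1, 1), c(0.4, 0.6))
  expect_error(auc(all_one), "non-diseased")
  expect_error(gini_index(all_one), "reference probability")
  all_zero <- labeled_predictions(c(0, 0), c(0.4, 0.6))
  expect_error(auc(all_zero), "no diseased")
  expect_error(scaled_brier(all_zero), "reference probability")
})

test_that("negative scaled Brier is returned with a warning, unclamped", {
  # anti-calibrated model: predicts the opposite of the truth
  lp <- labeled_predictions(c(1, 1, 0, 0), c(0.1, 0.2, 0.9, 0.8))
  expect_warning(v <- scaled_brier(lp), "negative")
  expect_lt(v, 0)
})

test_that("the mean-predicted reference option changes pbar as documented", {
  d <- c(1, 0, 0, 0)
  p <- c(0.9, 0.3, 0.3, 0.3)
  prev <- labeled_predictions(d, p)
  mp <- labeled_predictions(d, p, reference = "mean_predicted")
  expect_equal(prev$pbar, 0.25)
  expect_equal(mp$pbar, mean(p))
  expect_false(isTRUE(all.equal(pietra_index(prev), pietra_index(mp))))
})

test_that("evaluate_performance bundles the individual measures", {
  set.seed(61)
  s <- random_sample(n = 30)
  lp <- labeled_predictions(s$d, s$p)
  rep <- suppressWarnings(evaluate_performance(lp))
  expect_s3_class(rep, "performance_report")
  expect_equal(rep$auc, auc(lp))
  expect_equal(rep$gini, gini_index(lp))
  expect_equal(rep$pietra, pietra_index(lp))
  expect_equal(rep$brier, brier_score(lp))
  expect_equal(rep$sbrier, suppressWarnings(scaled_brier(lp)))
  expect_equal(rep$sbrier_gain, scaled_brier_gain(lp))
  expect_equal(rep$n, 30)
  expect_equal(rep$reference_probability, mean(s$d))
})

test_that("reports round-trip through JSON and TSV", {
  lp <- labeled_predictions(c(1, 0, 1, 0), c(0.8, 0.4, 0.6, 0.2))
  rep <- evaluate_performance(lp)
  j <- tempfile(fileext = ".json")
  t <- tempfile(fileext = ".tsv")
  write_performance_report(rep, j, "json")
  write_performance_report(rep, t, "tsv")
  back <- jsonlite::read_json(j)
  expect_equal(back$auc, rep$auc)
  expect_equal(back$sbrier, rep$sbrier)
  tab <- read.delim(t)
  expect_equal(tab$pietra, rep$pietra)
})

test_that("read_predictions parses delimited tables and flags bad rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("outcome,model_a,model_b",
               "1,0.8,0.7", "0,0.4,0.3", "1,0.6,0.9", "0,0.2,0.1"), f)
  lps <- read_predictions(f)
  expect_named(lps, c("model_a", "model_b"))
  expect_equal(auc(lps$model_a), 1)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("outcome,p", "1,0.8", "0,", "1,0.6"), f2)
  expect_error(read_predictions(f2), "line numbers.*3")
  expect_error(read_predictions(f, outcome_col = "disease"), "not found")
})
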