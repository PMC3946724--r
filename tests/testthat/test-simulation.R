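test_that("the Gaussian kernel has its closed form and symmetry", {
  expect_equal(gaussian_kernel(0), 1)
  expect_equal(gaussian_kernel(1, width = 1), exp(-0.5))
  b <- seq(-3, 3, by = 0.5)
  expect_equal(gaussian_kernel(-b), gaussian_kernel(b))
  expect_true(all(diff(gaussian_kernel(seq(0, 4, by = 0.1))) < 0))
  expect_error(gaussian_kernel(1, width = 0), "positive")
})

test_that("disease_probability follows the kernel-modulated logistic model", {
  pr <- generating_params()
  expect_equal(disease_probability(0, 0, 0, pr), plogis(pr$intercept))
  # conditional odds ratio of M2 peaks at b = 0 and vanishes in the tails
  or_m2 <- function(b) {
    p1 <- disease_probability(b, 0, 1, pr)
    p0 <- disease_probability(b, 0, 0, pr)
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }
  expect_equal(or_m2(0), exp(pr$log_or_m2_peak))
  expect_equal(or_m2(3), exp(pr$log_or_m2_peak *
                               gaussian_kernel(3, pr$kernel_width)))
  expect_lt(abs(or_m2(3) - 1), 0.01)
  expect_equal(or_m2(1.5), or_m2(-1.5))
  # M1's odds ratio does not depend on the baseline score
  or_m1 <- function(b) {
    p1 <- disease_probability(b, 1, 0, pr)
    p0 <- disease_probability(b, 0, 0, pr)
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }
  expect_equal(or_m1(-2), or_m1(0))
  expect_equal(or_m1(2), exp(pr$log_or_m1))
})

test_that("simulate_cohort is deterministic given a seed", {
  a <- simulate_cohort(100, seed = 5)
  b <- simulate_cohort(100, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(100, seed = 6)
  expect_false(identical(a, c))
  expect_error(simulate_cohort(1), "at least 2")
})

test_that("marker prevalences match the B-conditional 85%/75% rule", {
  co <- simulate_cohort(200000, seed = 17)
  expect_equal(mean(co$m1[co$b > 0]), 0.85, tolerance = 0.005 / 0.85)
  expect_equal(mean(co$m1[co$b <= 0]), 0.75, tolerance = 0.005 / 0.75)
  expect_equal(mean(co$m2[co$b > 0]), 0.85, tolerance = 0.005 / 0.85)
  # marginal prevalence by total probability: 0.5 * 0.85 + 0.5 * 0.75
  expect_equal(mean(co$m1), 0.80, tolerance = 0.005 / 0.80)
})

test_that("empirical prevalence converges to the mean true probability", {
  co <- simulate_cohort(100000, seed = 23)
  se <- sd(co$p_true * (1 - co$p_true))  # conservative scale
  se_prev <- sqrt(mean(co$p_true * (1 - co$p_true)) / nrow(co))
  expect_lt(abs(mean(co$d) - mean(co$p_true)), 3 * se_prev)
})

test_that("p_true is calibrated by construction (binned mean outcome)", {
  co <- simulate_cohort(200000, seed = 29)
  bins <- cut(co$p_true, breaks = quantile(co$p_true, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    se <- sqrt(mean(co$p_true[idx] * (1 - co$p_true[idx])) / sum(idx))
    expect_lt(abs(mean(co$d[idx]) - mean(co$p_true[idx])), 4 * se)
  }
})

test_that("a zero M2 effect makes M2 independent of disease given B", {
  pr <- generating_params(log_or_m2_peak = 0)
  set.seed(37)
  coefs <- replicate(30, {
    co <- simulate_cohort(2000, pr)
    fit <- suppressWarnings(glm(d ~ b + m2, binomial(), data = co))
    coef(fit)[["m2"]]
  })
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(length(coefs)))
})

test_that("solve_intercept hits a requested prevalence", {
  pr <- generating_params()
  a <- solve_intercept(0.3, pr, n = 100000, seed = 3)
  pr2 <- generating_params(intercept = a)
  co <- simulate_cohort(100000, pr2, seed = 4)
  expect_equal(mean(co$p_true), 0.3, tolerance = 0.02)
  expect_error(solve_intercept(1.2), "in \\(0, 1\\)")
})

test_that("continuous-marker cohorts honor the zero-effect and AUC-gain contracts", {
  pr <- generating_params()
  # zero marker effect: p_true identical to the baseline-only model
  co0 <- simulate_cohort_continuous(500, pr, log_or_cont = 0, seed = 41)
  expect_equal(co0$p_true, plogis(pr$intercept + pr$beta_baseline * co0$b))
  expect_identical(simulate_cohort_continuous(100, pr, seed = 43),
                   simulate_cohort_continuous(100, pr, seed = 43))
  # a uniform strong continuous effect raises validation AUC over baseline
  set.seed(47)
  wins <- replicate(200, {
    co <- simulate_cohort_continuous(400, pr, log_or_cont = 1)
    train <- co[1:200, ]; valid <- co[201:400, ]
    ok <- tryCatch({
      fb <- fit_risk_model(train, "b")
      fx <- fit_risk_model(train, c("b", "x"))
      rb <- evaluate_models(list(m = fb), valid)$m$auc
      rx <- evaluate_models(list(m = fx), valid)$m$auc
      rx > rb
    }, riskgauge_skip = function(e) NA)
    ok
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.95)
})

test_that("polygenic cohorts expose the genetic score as the marker sum", {
  pr <- generating_params()
  co1 <- simulate_cohort_polygenic(200, pr, n_markers = 1, seed = 53)
  expect_equal(co1$score, co1$g1)
  co <- simulate_cohort_polygenic(300, pr, n_markers = 18, seed = 59)
  gcols <- paste0("g", 1:18)
  expect_equal(co$score, unname(rowSums(co[, gcols])))
  expect_error(simulate_cohort_polygenic(100, pr, n_markers = 0), "at least 1")
})

test_that("a polygenic score out-predicts any single weak marker", {
  pr <- generating_params()
  set.seed(61)
  wins <- replicate(200, {
    co <- simulate_cohort_polygenic(1000, pr, n_markers = 18,
                                    per_marker_log_or = log(1.2))
    train <- co[1:500, ]; valid <- co[501:1000, ]
    tryCatch({
      fb <- fit_risk_model(train, "b")
      fs <- fit_risk_model(train, c("b", "score"))
      f1 <- fit_risk_model(train, c("b", "g1"))
      r <- evaluate_models(list(b = fb, s = fs, g = f1), valid)
      (r$s$auc - r$b$auc) > (r$g$auc - r$b$auc)
    }, riskgauge_skip = function(e) NA)
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.90)
})

test_that("generating params validate and round-trip through JSON", {
  expect_error(generating_params(kernel_width = -1), "positive")
  expect_error(generating_params(marker_prev_high = 1), "\\(0, 1\\)")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(intercept = -2, log_or_m1 = 1), f,
                       auto_unbox = TRUE)
  pr <- read_generating_params(f)
  expect_equal(pr$intercept, -2)
  expect_equal(pr$log_or_m1, 1)
  expect_equal(pr$beta_baseline, generating_params()$beta_baseline)
  jsonlite::write_json(list(nonsense = 1), f, auto_unbox = TRUE)
  expect_error(read_generating_params(f), "unknown")
})

test_that("cohorts write to CSV with the documented columns", {
  co <- simulate_cohort(50, seed = 67)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read.csv(f)
  expect_named(back, c("b", "m1", "m2", "p_true", "d"))
  expect_equal(back$p_true, co$p_true, tolerance = 1e-12)
})
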