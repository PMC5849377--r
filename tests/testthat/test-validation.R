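test_that("lag alignment pairs exposure day t with outcome day t+lag", {
  x <- 1:10
  y <- 101:110
  al0 <- lag_align(x, y, 0)
  expect_equal(al0$n_pairs, 10)
  expect_equal(al0$y, y)
  al3 <- lag_align(x, y, 3)
  expect_equal(al3$n_pairs, 7)
  expect_equal(al3$x, 1:7)
  expect_equal(al3$y, 104:110)
  # a missing outcome drops exactly its pair
  y2 <- y; y2[5] <- NA
  al1 <- lag_align(x, y2, 1)
  expect_equal(al1$n_pairs, 8)
  expect_equal(al1$n_dropped, 1)
  expect_false(4 %in% al1$x)
  expect_error(lag_align(x, y, 10), "series length")
  expect_error(lag_align(x, y, -1), "non-negative")
})

test_that("Pearson correlation and its t-based p-value behave as expected", {
  expect_equal(pearson_with_p(list(x = c(1, 2, 3), y = c(2, 4, 6)))$r, 1)
  expect_equal(pearson_with_p(list(x = c(1, 2, 3), y = c(3, 2, 1)))$r, -1)
  # t-transform arithmetic: r = 0.5, n = 12 -> t = 1.826, p from t(10)
  set.seed(31)
  x <- rnorm(12)
  y <- 0.5 * scale(x)[, 1] + sqrt(0.75) * scale(resid(lm(rnorm(12) ~ x)))[, 1]
  pr <- pearson_with_p(list(x = x, y = y))
  expect_equal(pr$r, 0.5, tolerance = 1e-6)
  t_stat <- pr$r * sqrt((12 - 2) / (1 - pr$r^2))
  expect_equal(t_stat, 1.8257, tolerance = 1e-3)
  expect_equal(pr$p_value, 2 * pt(-abs(t_stat), df = 10), tolerance = 1e-9)
  expect_equal(pr$n_pairs, 12)
  expect_error(pearson_with_p(list(x = rep(1, 5), y = 1:5)), "constant")
  expect_error(pearson_with_p(list(x = 1:2, y = 1:2)), "at least 3")
})

test_that("dichotomization reads 'up to the cutoff' as the negative class", {
  cls <- dichotomize(c(0, 1, 2, 3, 9), cutoff = 2)
  expect_equal(as.integer(cls), c(0, 0, 0, 1, 1))
  expect_equal(attr(cls, "n_pos"), 2L)
  expect_equal(attr(cls, "n_neg"), 3L)
  expect_equal(as.integer(dichotomize(c(0, 1, 2), cutoff = 0)), c(0, 1, 1))
  expect_equal(as.integer(dichotomize(c(1, 2, 3), cutoff = 2, strict = FALSE)),
               c(0, 1, 1))
  expect_warning(dichotomize(c(0, 0, 0), cutoff = 2), "one-class")
  expect_error(dichotomize(c(-1, 2), 2), "non-negative")
})

test_that("AUC equals brute-force pairwise counting with ties at one half", {
  expect_equal(roc_auc_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc_ci(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(41)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    predictor <- sample(seq_len(12), n, replace = TRUE) # force ties
    outcome <- rbinom(n, 1, 0.4)
    if (sum(outcome) == 0 || sum(outcome) == n) next
    rr <- roc_auc_ci(predictor, outcome)
    expect_equal(rr$auc, brute_force_auc(predictor, outcome),
                 tolerance = 1e-12)
    expect_true(rr$ci_low <= rr$auc && rr$auc <= rr$ci_high)
    expect_true(rr$ci_low >= 0 && rr$ci_high <= 1)
  }
  expect_error(roc_auc_ci(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with pROC and the DeLong interval is available", {
  skip_if_not_installed("pROC")
  set.seed(42)
  predictor <- rnorm(80)
  outcome <- rbinom(80, 1, plogis(predictor))
  rr <- roc_auc_ci(predictor, outcome, ci_method = "delong")
  ref <- pROC::roc(outcome, predictor, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
  expect_equal(rr$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_true(rr$ci_low < rr$auc && rr$auc < rr$ci_high)
})

test_that("the Hanley-McNeil interval narrows as roughly 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    set.seed(n)
    predictor <- rnorm(n)
    outcome <- rbinom(n, 1, plogis(1.5 * predictor))
    rr <- roc_auc_ci(predictor, outcome)
    rr$ci_high - rr$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # quadrupling n about halves the width
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.5)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.5)
})

test_that("Pearson r respects affine invariance and sign flips", {
  set.seed(43)
  x <- rnorm(50)
  y <- x + rnorm(50, sd = 0.5)
  r0 <- pearson_with_p(list(x = x, y = y))$r
  expect_equal(pearson_with_p(list(x = 3 * x + 7, y = y))$r, r0)
  expect_equal(pearson_with_p(list(x = x, y = -2 * y + 1))$r, -r0)
})

test_that("validate_series recovers known structure and reports cleanly", {
  fis <- respiratory_fis()
  # counts proportional to PM10: lag-0 correlation near 1, fading with lag
  # keep PM10 inside [0, 35], where the fuzzified response is not yet
  # saturated, so the model output tracks the planted signal
  set.seed(44)
  n <- 200
  s <- data.frame(
    date = seq(as.Date("2012-01-01"), by = "day", length.out = n),
    pm10 = runif(n, 0, 35), no2 = 60, temperature = 27, wind = 2.3
  )
  s$hospitalizations <- as.integer(round(s$pm10 / 5))
  rep1 <- validate_series(s, fis)
  expect_s3_class(rep1, "validation_report")
  expect_gt(rep1$pearson$r[rep1$pearson$lag == 0], 0.9)
  expect_gt(rep1$pearson$r[1], max(rep1$pearson$r[-1]))
  expect_equal(rep1$pearson$n_pairs, n - 0:3)
  expect_equal(nrow(rep1$roc), 12) # 3 predictors x 4 lags
  expect_gt(rep1$roc$auc[rep1$roc$predictor == "pm10" & rep1$roc$lag == 0],
            0.95)
  # shuffled outcomes: no association left
  s2 <- s
  set.seed(45)
  s2$hospitalizations <- sample(s2$hospitalizations)
  rep2 <- validate_series(s2, fis)
  expect_true(all(abs(rep2$pearson$r) < 0.2))
  expect_true(all(abs(rep2$roc$auc - 0.5) < 0.12))
})

test_that("validation reports round-trip through JSON", {
  fis <- respiratory_fis()
  s <- random_series(50, seed = 46)
  rep1 <- validate_series(s, fis)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, path)
  rep2 <- read_report_json(path)
  expect_equal(rep2$pearson, rep1$pearson, tolerance = 1e-12)
  expect_equal(rep2$roc$auc, rep1$roc$auc, tolerance = 1e-12)
  expect_equal(rep2$cutoff, rep1$cutoff)
  expect_equal(rep2$schema_version, rep1$schema_version)
})
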