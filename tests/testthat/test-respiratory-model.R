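test_that("the model has the canonical structure: 16 factorial rules, 5 output terms", {
  fis <- respiratory_fis()
  expect_length(fis$rules, 16)
  expect_length(fis$output$terms, 5)
  expect_named(fis$inputs, c("pm10", "no2", "temperature", "wind"))
  # every 2x2x2x2 antecedent combination appears exactly once
  ants <- vapply(fis$rules, function(r) {
    paste(r$antecedent[c("pm10", "no2", "temperature", "wind")],
          collapse = "|")
  }, character(1))
  expect_equal(anyDuplicated(ants), 0L)
  expect_length(unique(ants), 16)
  # consequent histogram across the rule base
  cons <- vapply(fis$rules, `[[`, character(1), "consequent")
  expect_equal(as.list(table(cons)[c("L", "ML", "M", "MH", "H")]),
               list(L = 4L, ML = 3L, M = 6L, MH = 2L, H = 1L))
  # all rules carry unit weight
  expect_true(all(vapply(fis$rules, `[[`, numeric(1), "weight") == 1))
})

test_that("key rules map the expected antecedents to their consequents", {
  rt <- respiratory_rule_table()
  expect_equal(nrow(rt), 16)
  # fully favourable day -> L; fully adverse day -> H
  expect_equal(rt$consequent[rt$pm10 == "acceptable" & rt$no2 == "acceptable"],
               rep("L", 4))
  r16 <- rt[rt$pm10 == "unacceptable" & rt$no2 == "unacceptable" &
              rt$temperature == "low" & rt$wind == "weak", ]
  expect_equal(r16$consequent, "H")
  expect_equal(r16$rule, 16L)
  # strong wind at high temperature offsets unacceptable NO2 (ML not M)
  r5 <- rt[rt$pm10 == "acceptable" & rt$no2 == "unacceptable" &
             rt$temperature == "high" & rt$wind == "strong", ]
  expect_equal(r5$consequent, "ML")
})

test_that("extreme days activate a single consequent whose centroid is recovered", {
  fis <- respiratory_fis()
  bps <- respiratory_breakpoints()$hospitalizations
  # adverse extremes: only the H rule fires, at degree 1
  adverse <- infer(fis, c(pm10 = 150, no2 = 130, temperature = 0, wind = 0.1))
  expect_equal(adverse, exact_clipped_centroid(bps$H, 1), tolerance = 1e-3)
  # favourable extremes: only L rules fire, at degree 1
  favourable <- infer(fis, c(pm10 = 0, no2 = 0, temperature = 40, wind = 4))
  expect_equal(favourable, exact_clipped_centroid(bps$L, 1), tolerance = 1e-3)
})

test_that("at the all-crossover point every rule fires at 0.5", {
  fis <- respiratory_fis()
  # each input's two terms cross at the midpoint of their shared flank
  x <- c(pm10 = 25, no2 = 60, temperature = 27, wind = 2.3)
  fz <- lapply(fis$inputs, function(v) fuzzify(v, x[[v$name]]))
  acts <- vapply(fis$rules, activate_rule, numeric(1), fuzzified = fz)
  expect_equal(acts, rep(0.5, 16))
  # output equals the centroid of the union of all five consequents at 0.5
  grid <- output_grid(fis)
  union_curve <- Reduce(pmax, lapply(fis$output$terms, function(mf) {
    pmin(0.5, evaluate_membership(mf, grid))
  }))
  expect_equal(infer(fis, x), defuzzify_centroid(union_curve, grid),
               tolerance = 1e-9)
})

test_that("predictions rise with each pollutant up to the known Mamdani dips", {
  # At three of the four crisp temperature/wind settings the active
  # consequents are ordered symmetrically in the two pollutants and the
  # response is exactly non-decreasing.  At (high temperature, weak wind)
  # the rule base is asymmetric (NO2-unacceptable concludes M while
  # PM10-unacceptable concludes ML), and min/max inference with centroid
  # defuzzification then admits small local dips; these stay below 0.03
  # admissions per sweep step and the end-to-end response still rises.
  fis <- respiratory_fis()
  settings <- expand.grid(temperature = c(18, 36), wind = c(1, 3.5))
  sweep <- seq(0, 150, length.out = 21)
  sweep_no2 <- seq(0, 130, length.out = 21)
  for (s in seq_len(nrow(settings))) {
    X <- expand.grid(pm10 = sweep, no2 = sweep_no2)
    X$temperature <- settings$temperature[s]
    X$wind <- settings$wind[s]
    pred <- matrix(predict_series(fis, X), nrow = 21)
    asymmetric <- settings$temperature[s] > 32 && settings$wind[s] < 1.8
    tol <- if (asymmetric) 0.03 else 1e-9
    expect_true(all(diff(pred) >= -tol),
                label = sprintf("PM10 direction at setting %d", s))
    expect_true(all(t(diff(t(pred))) >= -tol),
                label = sprintf("NO2 direction at setting %d", s))
    # the full shoulder-to-shoulder sweep always rises
    expect_gt(pred[21, 21], pred[1, 1])
    expect_true(all(pred[21, ] >= pred[1, ]))
    expect_true(all(pred[, 21] >= pred[, 1]))
  }
})

test_that("weak wind and low temperature never lower predictions on polluted days", {
  fis <- respiratory_fis()
  base <- c(pm10 = 150, no2 = 130)
  y_strong_high <- infer(fis, c(base, temperature = 40, wind = 4))
  y_weak_high <- infer(fis, c(base, temperature = 40, wind = 0.5))
  y_strong_low <- infer(fis, c(base, temperature = 10, wind = 4))
  y_weak_low <- infer(fis, c(base, temperature = 10, wind = 0.5))
  expect_true(y_weak_high >= y_strong_high)
  expect_true(y_strong_low >= y_strong_high)
  expect_true(y_weak_low >= max(y_weak_high, y_strong_low))
})

test_that("series prediction is stateless and handles missing exposures", {
  fis <- respiratory_fis()
  day <- data.frame(pm10 = 60, no2 = 70, temperature = 25, wind = 2)
  const <- day[rep(1, 10), ]
  pred <- predict_series(fis, const)
  expect_length(unique(pred), 1)
  # shuffling days permutes predictions identically
  s <- random_series(40, seed = 5)
  p <- predict_series(fis, s)
  perm <- sample(40)
  expect_equal(predict_series(fis, s[perm, ]), p[perm])
  # a missing exposure yields a missing prediction, others unaffected
  s2 <- s
  s2$pm10[7] <- NA
  expect_message(p2 <- predict_series(fis, s2), "1 day")
  expect_true(is.na(p2[7]))
  expect_equal(p2[-7], p[-7])
  expect_error(predict_series(fis, s[0, ]), "at least one row")
  expect_error(predict_series(fis, s[, -2]), "pm10")
})

test_that("breakpoint overrides apply and invalid ones are named in the error", {
  fis <- respiratory_fis(breakpoints = list(
    pm10 = list(acceptable = c(0, 0, 20, 40), unacceptable = c(20, 40, 150, 150))
  ))
  expect_equal(unname(fuzzify(fis$inputs$pm10, 30)), c(0.5, 0.5))
  expect_error(respiratory_fis(breakpoints = list(
    pm10 = list(acceptable = c(10, 5, 20, 40))
  )), "'acceptable'.*'pm10'|acceptable")
  expect_error(respiratory_fis(breakpoints = list(smoke = list(low = c(0, 1, 2)))),
               "unknown variable")
})
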