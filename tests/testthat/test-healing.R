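test_that("weekly contraction arithmetic and identities", {
  expect_equal(contraction_percentage(10, 10), 0)
  expect_equal(contraction_percentage(10, 7.5), 25.0)
  expect_equal(contraction_percentage(8, 10), -25.0)   # growth after debridement
  expect_equal(contraction_percentage(7, 0), 100)
  # strictly decreasing in Si
  si <- seq(0, 12, by = 0.5)
  expect_true(all(diff(contraction_percentage(10, si)) < 0))
  expect_planim_error(contraction_percentage(0, 1), "invalid_baseline")
})

test_that("healing series carries COi and normalized areas consistently", {
  s <- build_series(c(10, 9, 8))
  expect_equal(s$coi, c(0, 10, 20))
  expect_equal(s$normalized, c(1, 0.9, 0.8))

  expect_equal(build_series(c(5, 5, 5, 5))$coi, rep(0, 4))
  expect_equal(build_series(c(10, 12, 9))$coi, c(0, -20, 10))

  # algebraic identity for arbitrary series
  set.seed(21)
  for (i in 1:20) {
    a <- c(stats::runif(1, 5, 40), stats::runif(4, 0.5, 45))
    s <- build_series(a)
    expect_equal(s$normalized, 1 - s$coi / 100, tolerance = 1e-12)
    expect_equal(s$coi[1], 0)
    expect_equal(s$normalized[1], 1)
  }

  expect_planim_error(build_series(10), "insufficient_series")
  expect_planim_error(build_series(c(0, 5)), "invalid_baseline")
})

test_that("predictor rules classify boundary trajectories inclusively", {
  # exactly 25% at week 2 counts as predicted to heal
  s25 <- build_series(c(10, 8.7, 7.5))
  expect_equal(classify_healing(s25, "two_week_25")$verdict, "predicted_to_heal")

  # 35% at week 4 fails the >= 40% four-week rule
  s35 <- build_series(c(10, 9, 8, 7.2, 6.5))
  expect_equal(classify_healing(s35, "four_week_40")$verdict, "reassess")
  s40 <- build_series(c(10, 9, 8, 7, 6))
  expect_equal(classify_healing(s40, "four_week_40")$verdict, "predicted_to_heal")

  # a flat wound fails every rule
  flat <- build_series(rep(10, 5))
  for (r in c("weekly_10_15", "two_week_25", "two_to_four_week_20_40",
              "four_week_40"))
    expect_equal(classify_healing(flat, r)$verdict, "reassess")

  # mean weekly contraction exactly 10% meets the weekly rule
  s10 <- build_series(c(10, 9, 8.1))
  expect_equal(classify_healing(s10, "weekly_10_15")$verdict, "predicted_to_heal")

  # 20% reached inside weeks 2-4 meets the window rule
  s20 <- build_series(c(10, 9.5, 8.0))
  expect_equal(classify_healing(s20, "two_to_four_week_20_40")$verdict,
               "predicted_to_heal")
  # threshold not met and week 4 still unread -> indeterminate
  s_wait <- build_series(c(10, 9.5, 9.0))
  expect_equal(classify_healing(s_wait, "two_to_four_week_20_40")$verdict,
               "indeterminate")

  expect_planim_error(classify_healing(build_series(c(10, 9)), "four_week_40"),
                      "insufficient_series")
})

test_that("percent differences reproduce the published comparison rows", {
  expect_equal(round(percent_difference(37.5, 24.57), 2), 52.63)
  expect_equal(round(percent_difference(24.80, 24.57), 2), 0.94)
  expect_equal(round(percent_difference(32.67, 24.57), 2), 32.97)
  expect_equal(percent_difference(7.3, 7.3), 0)
  expect_planim_error(percent_difference(1, 0), "invalid_reference")
})

test_that("mean signed error reproduces the published summary row", {
  err <- method_errors_example()
  # agreement with the published summary row at its printed precision
  expect_equal(mean_error(err$planimetry_program), 1.01, tolerance = 0.006)
  expect_equal(mean_error(err$autosegmentation), -0.86, tolerance = 0.006)
  expect_equal(mean_error(err$caliper_kundin), -44.89, tolerance = 0.0002)
  expect_equal(mean_error(err$rigid_ruler_kundin), -44.70, tolerance = 0.0002)
  expect_equal(mean_error(c(5, -5)), 0)
  expect_planim_error(mean_error(numeric(0)), "empty_input")
})

test_that("pearson_r matches the closed-form moment formula", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  set.seed(31)
  x <- stats::rnorm(40, 20, 6); y <- 0.8 * x + stats::rnorm(40, 0, 3)
  closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), closed, tolerance = 1e-12)
  # invariance under positive affine rescaling
  expect_equal(pearson_r(3 * x + 7, y), pearson_r(x, y), tolerance = 1e-12)
  expect_planim_error(pearson_r(1:5, rep(2, 5)), "undefined_correlation")
  expect_planim_error(pearson_r(1:2, 1:2), "invalid_parameter")
})

test_that("method comparison reports per-wound differences, means, correlations", {
  set.seed(12)
  truth <- stats::runif(6, 5, 40)
  df <- rbind(
    data.frame(wound = LETTERS[1:6], method = "pixel", area_cm2 = truth),
    data.frame(wound = LETTERS[1:6], method = "kundin",
               area_cm2 = truth * stats::runif(6, 1.1, 1.5)),
    data.frame(wound = LETTERS[1:6], method = "manual",
               area_cm2 = truth * stats::runif(6, 0.98, 1.02)))
  rep <- compare_methods(df, "pixel")
  expect_equal(unname(rep$per_wound_errors[, "pixel"]), rep(0, 6))
  expect_equal(unname(rep$mean_errors["pixel"]), 0)
  # internal consistency with mean_error
  expect_equal(unname(rep$mean_errors["kundin"]),
               mean_error(rep$per_wound_errors[, "kundin"]))
  expect_true(all(rep$per_wound_errors[, "kundin"] > 0))
  expect_equal(dim(rep$correlations), c(3L, 3L))
  expect_gt(rep$correlations["pixel", "manual"], 0.99)

  # reference alone -> all zero
  solo <- df[df$method == "pixel", ]
  expect_true(all(compare_methods(solo, "pixel")$per_wound_errors == 0))

  # missing reference for one wound is diagnosed by wound id
  broken <- df[!(df$wound == "C" & df$method == "pixel"), ]
  err <- tryCatch(compare_methods(broken, "pixel"), error = identity)
  expect_s3_class(err, "planimetr_incomplete_data")
  expect_match(conditionMessage(err), "C")

  # CSV export round-trip
  p <- tempfile(fileext = ".csv")
  summ <- write_comparison(rep, p)
  expect_true(file.exists(p))
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", p)))
  expect_equal(summ$mean_error_pct[summ$method == "kundin"],
               unname(rep$mean_errors["kundin"]))
  unlink(c(p, sub("\\.csv$", "_summary.csv", p)))
})
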