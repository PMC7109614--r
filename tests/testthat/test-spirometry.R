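cfg <- test_config()

test_that("calibration window is inclusive at the boundary", {
  now <- "2024-03-01T12:00:00Z"
  expect_true(check_calibration("2024-03-01T10:00:00Z", now))
  expect_false(check_calibration("2024-02-29T11:00:00Z", now))
  expect_true(check_calibration("2024-02-29T12:00:00Z", now))  # exactly 24 h
  expect_error(check_calibration("2024-03-02T12:00:00Z", now),
               class = "copd_data_error")
})

test_that("attempt quality: short FET flags early termination, operator flags exclude", {
  att <- tibble::tibble(fvc = c(3.2, 3.1, 3.0), fev1 = c(2.1, 2.0, 1.9),
                        fet = c(4, 8, 9))
  flagged <- flag_attempt_quality(att, min_fet_s = 6)
  expect_equal(flagged$early_termination, c(TRUE, FALSE, FALSE))
  expect_equal(flagged$acceptable, c(FALSE, TRUE, TRUE))

  att2 <- tibble::tibble(fvc = 3.2, fev1 = 2.1, fet = 8, glottis_closure = TRUE)
  expect_false(flag_attempt_quality(att2)$acceptable)

  att3 <- tibble::tibble(fvc = 3.2, fev1 = 2.1, fet = 8)
  expect_true(all(flag_attempt_quality(att3)[, c(
    "slow_start", "early_termination", "glottis_closure",
    "variable_effort")] == FALSE))
})

test_that("implausible attempt values are rejected", {
  expect_error(flag_attempt_quality(tibble::tibble(fvc = 3, fev1 = 3.5)),
               class = "copd_data_error")
  expect_error(flag_attempt_quality(tibble::tibble(fvc = 11, fev1 = 2)),
               class = "copd_data_error")
})

test_that("reproducibility follows the 0.15 L two-best rule, inclusive", {
  ok <- check_reproducibility(good_attempts())
  expect_true(ok$reproducible)
  expect_equal(ok$delta_fvc, 0.10)
  expect_equal(ok$delta_fev1, 0.10)

  bad <- check_reproducibility(tibble::tibble(
    fvc = c(3.50, 3.30, 3.00), fev1 = c(2.20, 2.10, 2.05)))
  expect_false(bad$reproducible)
  expect_equal(bad$delta_fvc, 0.20)
  expect_equal(bad$reason, "delta_fvc")

  # exactly at the threshold on both parameters passes
  edge <- check_reproducibility(tibble::tibble(
    fvc = c(3.45, 3.30, 3.00), fev1 = c(2.25, 2.10, 2.00)))
  expect_true(edge$reproducible)

  few <- check_reproducibility(good_attempts()[1:2, ])
  expect_false(few$reproducible)
  expect_equal(few$reason, "insufficient_attempts")
})

test_that("reproducibility agrees with the brute-force pairwise oracle", {
  set.seed(42)
  for (i in 1:300) {
    fvc <- round(runif(3, 3.0, 3.4), 2)
    fev1 <- round(runif(3, 2.0, 2.3), 2)
    got <- check_reproducibility(tibble::tibble(fvc = fvc, fev1 = fev1))
    expect_identical(got$reproducible, oracle_reproducible(fvc, fev1),
                     info = paste(c(fvc, fev1), collapse = ","))
  }
  # four-attempt generalisation: the two best of all acceptable attempts
  four <- tibble::tibble(fvc = c(3.60, 3.50, 3.30, 3.00),
                         fev1 = c(2.30, 2.20, 2.10, 2.00))
  got4 <- check_reproducibility(four)
  expect_identical(got4$reproducible,
                   oracle_reproducible(four$fvc, four$fev1))
})

test_that("best values are per-parameter maxima, possibly from different attempts", {
  att <- tibble::tibble(fvc = c(3.1, 3.3), fev1 = c(2.2, 2.0))
  best <- select_best(att)
  expect_equal(best$best_fvc, 3.3)
  expect_equal(best$best_fev1, 2.2)
  one <- select_best(att[1, ])
  expect_equal(one$best_fvc, 3.1)
  expect_error(select_best(att[0, ]), class = "copd_no_acceptable_attempts")
  # dominance over every acceptable attempt
  expect_true(all(best$best_fvc >= att$fvc))
  expect_true(all(best$best_fev1 >= att$fev1))
})

test_that("obstruction classification is strict at both thresholds", {
  fx <- classify_obstruction(2.0, 3.0, mode = "fixed")
  expect_true(fx$obstructed)
  expect_equal(fx$ratio, 2 / 3)
  expect_false(classify_obstruction(7, 10, mode = "fixed")$obstructed)
  expect_false(classify_obstruction(0.67 * 3, 3, mode = "lln",
                                    lln = 0.65)$obstructed)
  expect_true(classify_obstruction(0.64 * 3, 3, mode = "lln",
                                   lln = 0.65)$obstructed)
  expect_error(classify_obstruction(2, 3, mode = "lln"),
               class = "copd_config_error")
})

test_that("LLN evaluation matches the frozen regression value and declines with age", {
  eq <- cfg$equations
  ref <- compute_lln(list(age = 60, sex = "male", height = 175), eq)
  expect_equal(ref$lln_ratio, 0.669525, tolerance = 1e-9)
  expect_gt(ref$lln_ratio, 0.55)
  expect_lt(ref$lln_ratio, 0.75)
  expect_lt(ref$lln_ratio, ref$pred_ratio)
  expect_gt(ref$pred_fev1, 0)

  older <- compute_lln(list(age = 80, sex = "male", height = 175), eq)
  expect_lt(older$lln_ratio, ref$lln_ratio)
})

test_that("LLN evaluation refuses extrapolation and unmapped groups", {
  eq <- cfg$equations
  hi <- eq$height_max[eq$sex == "male" & eq$group == "european"][1]
  expect_no_error(compute_lln(list(age = 60, sex = "male", height = hi), eq))
  expect_error(compute_lln(list(age = 60, sex = "male", height = hi + 1), eq),
               class = "copd_range_error")
  expect_error(compute_lln(list(age = 110, sex = "male", height = 175), eq),
               class = "copd_range_error")
  expect_error(compute_lln(list(age = 60, sex = "male", height = 175,
                                group = "unmapped"), eq),
               class = "copd_group_error")
})

test_that("full session assessment wires validity and the obstruction call together", {
  patient <- list(age = 60, sex = "male", height = 175)
  s <- assess_session(good_attempts(), patient,
                      last_calibration = "2024-03-01T07:00:00Z",
                      clock = "2024-03-01T09:00:00Z", config = cfg)
  expect_true(s$valid)
  expect_equal(s$best_fvc, 3.30)
  expect_equal(s$best_fev1, 2.20)
  # ratio 0.667 just below this patient's LLN 0.6695 -> obstructed in lln mode
  expect_true(s$obstructed)

  stale <- assess_session(good_attempts(), patient,
                          last_calibration = "2024-02-27T07:00:00Z",
                          clock = "2024-03-01T09:00:00Z", config = cfg)
  expect_false(stale$valid)
  expect_equal(stale$reason, "uncalibrated")
  expect_true(is.na(stale$obstructed))
})
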