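cfg <- test_config()

test_that("cohort generation is deterministic and extensible by patient stream", {
  s <- cohort_spec(n = 30, seed = 5)
  a <- generate_cohort(s, cfg)
  b <- generate_cohort(s, cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$screening, b$screening)
  # growing the cohort keeps earlier patients byte-identical
  big <- generate_cohort(cohort_spec(n = 40, seed = 5), cfg)
  expect_identical(big$patients[1:30, ], a$patients)
})

test_that("degenerate specs behave as stated", {
  none <- generate_cohort(cohort_spec(n = 40, seed = 2,
                                      obstruction_prevalence = 0), cfg)
  expect_equal(sum(none$labels$true_obstructed), 0L)
  expect_error(cohort_spec(n = 0), class = "copd_spec_error")
  expect_error(cohort_spec(no_show_prob = 1.2), class = "copd_spec_error")
  expect_error(cohort_spec(attempt_sigma_l = -1), class = "copd_spec_error")
})

test_that("true ratios sit on the correct side of each patient's own LLN", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 8), cfg)
  obs <- co$labels$true_obstructed
  expect_true(all(co$labels$true_ratio[obs] < co$labels$lln_ratio[obs]))
  expect_true(all(co$labels$true_ratio[!obs] > co$labels$lln_ratio[!obs]))
})

test_that("empirical prevalence approaches the spec value", {
  co <- generate_cohort(cohort_spec(n = 2000, seed = 13,
                                    obstruction_prevalence = 0.25), cfg)
  p_hat <- mean(co$labels$true_obstructed)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(p_hat - 0.25), 3 * se)
})

test_that("noise-free cohorts replay to perfect recovery", {
  co <- generate_cohort(cohort_spec(n = 120, seed = 4, attempt_sigma_l = 0,
                                    screening_sensitivity = 1,
                                    screening_specificity = 1,
                                    no_show_prob = 0), cfg)
  rep <- end_to_end_replay(co, cfg)
  expect_equal(rep$metrics$sensitivity, 1)
  expect_equal(rep$metrics$specificity, 1)
  expect_true(all(rep$results$terminal_state != "no_show"))
})

test_that("all no-shows end in the no_show terminal", {
  co <- generate_cohort(cohort_spec(n = 30, seed = 6, no_show_prob = 1), cfg)
  rep <- end_to_end_replay(co, cfg)
  expect_true(all(rep$results$terminal_state == "no_show"))
  expect_true(all(is.na(rep$results$engine_obstructed)))
})

test_that("session-invalid rate does not decrease with attempt noise", {
  lo <- generate_cohort(cohort_spec(n = 400, seed = 21,
                                    attempt_sigma_l = 0.05,
                                    no_show_prob = 0,
                                    attempt_flag_prob = 0), cfg)
  hi <- generate_cohort(cohort_spec(n = 400, seed = 21,
                                    attempt_sigma_l = 0.2,
                                    no_show_prob = 0,
                                    attempt_flag_prob = 0), cfg)
  invalid_rate <- function(co) {
    mean(vapply(split(co$sessions, co$sessions$patient_id), function(s) {
      !check_reproducibility(s)$reproducible
    }, logical(1)))
  }
  r_lo <- invalid_rate(lo)
  r_hi <- invalid_rate(hi)
  expect_gt(r_hi, r_lo)
})

test_that("replay confusion matrix accounts for every non-no-show patient", {
  co <- generate_cohort(cohort_spec(n = 150, seed = 17), cfg)
  rep <- end_to_end_replay(co, cfg)
  expect_equal(sum(rep$confusion),
               150L - sum(rep$results$terminal_state == "no_show"))
  expect_true(all(rep$results$terminal_state %in%
                    c("not_copd", "copd_diagnosed_primary_care",
                      "referred_to_specialist", "no_show")))
  # tidy/glance accessors
  expect_equal(nrow(tidy(rep)), 150L)
  expect_equal(nrow(glance(rep)), 1L)
  expect_s3_class(autoplot(rep), "ggplot")
})
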