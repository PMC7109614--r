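cfg <- test_config()

test_that("screening eligibility is strict at 40 and respects the 2-year window", {
  expect_true(is_eligible_for_screening(41, "2024-03-01T00:00:00Z",
                                        config = cfg)$eligible)
  at40 <- is_eligible_for_screening(40, "2024-03-01T00:00:00Z", config = cfg)
  expect_false(at40$eligible)
  expect_equal(at40$reason, "age")
  recent <- is_eligible_for_screening(
    55, "2024-03-01T00:00:00Z",
    last_screening = "2022-09-01T00:00:00Z", config = cfg)
  expect_false(recent$eligible)
  expect_equal(recent$reason, "recent_screening")
  old <- is_eligible_for_screening(
    55, "2024-03-01T00:00:00Z",
    last_screening = "2021-01-01T00:00:00Z", config = cfg)
  expect_true(old$eligible)
  missing <- is_eligible_for_screening(NA, "2024-03-01T00:00:00Z", config = cfg)
  expect_equal(missing$reason, "missing_age")
})

test_that("eligibility returns once the revalidation window expires", {
  last <- "2023-01-01T00:00:00Z"
  before <- is_eligible_for_screening(50, "2024-06-01T00:00:00Z", last,
                                      config = cfg)
  expect_equal(before$reason, "recent_screening")
  after <- is_eligible_for_screening(50, "2025-06-01T00:00:00Z", last,
                                     config = cfg)
  expect_true(after$eligible)
})

test_that("questionnaire scoring sums items with the >= cutoff convention", {
  instr <- cfg$instrument
  keys <- instr$items$key
  zeros <- setNames(rep(0, length(keys)), keys)
  expect_false(score_screening(zeros, instr)$positive)
  expect_equal(score_screening(zeros, instr)$total, 0)

  maxed <- setNames(instr$items$max, keys)
  top <- score_screening(maxed, instr)
  expect_equal(top$total, sum(instr$items$max))
  expect_true(top$positive)

  # exactly at the cutoff is positive
  at_cut <- zeros
  remaining <- instr$cutoff
  for (k in keys) {
    give <- min(remaining, instr$items$max[instr$items$key == k])
    at_cut[k] <- give
    remaining <- remaining - give
  }
  res <- score_screening(at_cut, instr)
  expect_equal(res$total, instr$cutoff)
  expect_true(res$positive)
})

test_that("scoring is answer-order independent and rejects bad answers", {
  instr <- cfg$instrument
  a <- c(age_band = 1, pack_years_band = 2, dyspnea_exertion = 0,
         chronic_cough_sputum = 2, breathing_episodes = 1)
  shuffled <- a[c(4, 1, 5, 2, 3)]
  expect_equal(score_screening(a, instr)$total,
               score_screening(shuffled, instr)$total)
  expect_error(score_screening(a[-1], instr), "missing answer.*age_band",
               class = "copd_scoring_error")
  bad <- a; bad["age_band"] <- 7
  expect_error(score_screening(bad, instr), "out of range.*age_band",
               class = "copd_scoring_error")
})

test_that("screening totals survive a serialization round trip", {
  instr <- cfg$instrument
  a <- c(age_band = 2, pack_years_band = 1, dyspnea_exertion = 2,
         chronic_cough_sputum = 0, breathing_episodes = 1)
  res <- score_screening(a, instr)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(a), path, auto_unbox = TRUE, digits = NA)
  back <- unlist(jsonlite::fromJSON(path))
  expect_equal(score_screening(back, instr)$total, res$total)
})

test_that("key-indicator suspicion needs age over the cut plus one indicator", {
  hit <- key_indicator_suspicion(list(age = 50, chronic_cough = TRUE))
  expect_true(hit$suspicion)
  expect_equal(hit$indicators, "chronic_cough")
  none <- key_indicator_suspicion(list(age = 50, dyspnea = FALSE,
                                       chronic_cough = FALSE))
  expect_false(none$suspicion)
  young <- key_indicator_suspicion(list(age = 30, dyspnea = TRUE))
  expect_false(young$suspicion)
  # the 35-year alternative cut is configurable
  expect_true(key_indicator_suspicion(list(age = 38, dyspnea = TRUE),
                                      age_cut = 35)$suspicion)
  # unknown flags are reported, not silently treated as data
  unk <- key_indicator_suspicion(list(age = 50, dyspnea = TRUE))
  expect_true("chronic_cough" %in% unk$unknown)
})
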