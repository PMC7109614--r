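cfg <- test_config()

test_that("BODE sums the published component points", {
  r <- bode_score(list(bmi = 20, fev1_pct = 65, mmrc = 2, six_mwd = 400),
                  cfg$bode_cutpoints)
  expect_equal(r$score, 2)
  expect_equal(unname(r$points), c(1, 0, 1, 0))

  best <- bode_score(list(bmi = 25, fev1_pct = 90, mmrc = 0, six_mwd = 500),
                     cfg$bode_cutpoints)
  expect_equal(best$score, 0)
  worst <- bode_score(list(bmi = 18, fev1_pct = 20, mmrc = 4, six_mwd = 100),
                      cfg$bode_cutpoints)
  expect_equal(worst$score, 10)

  expect_error(bode_score(list(bmi = 20, fev1_pct = 65, mmrc = 2,
                               six_mwd = NA), cfg$bode_cutpoints),
               class = "copd_bode_unavailable")
})

test_that("BODEx replaces exercise with exacerbations", {
  r <- bodex_score(list(bmi = 23, fev1_pct = 40, mmrc = 3, exacerbations = 2),
                   cfg$bodex_cutpoints)
  expect_equal(r$score, 5)
  expect_equal(unname(r$points), c(0, 2, 2, 1))

  expect_equal(bodex_score(list(bmi = 25, fev1_pct = 90, mmrc = 0,
                                exacerbations = 0), cfg$bodex_cutpoints)$score, 0)
  expect_equal(bodex_score(list(bmi = 18, fev1_pct = 20, mmrc = 4,
                                exacerbations = 5), cfg$bodex_cutpoints)$score, 9)
  expect_error(bodex_score(list(bmi = 23, fev1_pct = 40, mmrc = 3),
                           cfg$bodex_cutpoints),
               class = "copd_missing_field")
})

test_that("index points match the independent band oracles over the boundary lattice", {
  lat <- staging_lattice(walk = FALSE)
  staged <- stage_patients(lat, cfg)
  oracle <- oracle_bmi_points(lat$bmi) + oracle_fev1_points(lat$fev1_pct) +
    oracle_mmrc_points(lat$mmrc) + oracle_exac_points(lat$exacerbations)
  expect_equal(staged$bodex, oracle)

  latw <- staging_lattice(walk = TRUE)
  stagedw <- stage_patients(latw, cfg)
  oraclew <- oracle_bmi_points(latw$bmi) + oracle_fev1_points(latw$fev1_pct) +
    oracle_mmrc_points(latw$mmrc) + oracle_walk_points(latw$six_mwd)
  expect_equal(stagedw$bode, oraclew)
  # attained ranges are exactly 0..9 and 0..10
  expect_setequal(unique(staged$bodex), 0:9)
  expect_setequal(unique(stagedw$bode), 0:10)
})

test_that("worsening any single component never decreases a score", {
  lat <- staging_lattice(walk = TRUE)
  staged <- stage_patients(lat, cfg)
  worsen <- list(
    bmi = function(d) { d$bmi <- pmax(16, d$bmi - 5.01); d },
    fev1_pct = function(d) { d$fev1_pct <- pmax(10, d$fev1_pct - 15.01); d },
    mmrc = function(d) { d$mmrc <- pmin(4, d$mmrc + 1); d },
    exacerbations = function(d) { d$exacerbations <- d$exacerbations + 1; d },
    six_mwd = function(d) { d$six_mwd <- pmax(50, d$six_mwd - 100.01); d }
  )
  for (w in names(worsen)) {
    worse <- stage_patients(worsen[[w]](lat), cfg)
    expect_true(all(worse$bodex >= staged$bodex), info = paste("bodex", w))
    expect_true(all(worse$bode >= staged$bode), info = paste("bode", w))
    expect_true(all(worse$severity >= staged$severity), info = paste("sev", w))
  }
})

test_that("severity and impact levels follow the configured default bands", {
  expect_equal(as.character(severity_level(0, "bode", cfg$severity_bands)), "mild")
  expect_equal(as.character(severity_level(5, "bode", cfg$severity_bands)), "severe")
  expect_equal(as.character(severity_level(10, "bode", cfg$severity_bands)),
               "very_severe")
  expect_error(severity_level(11, "bode", cfg$severity_bands),
               class = "copd_staging_error")
  expect_false(is.unsorted(as.integer(severity_level(0:10, "bode",
                                                     cfg$severity_bands))))

  expect_equal(as.character(impact_level(0, cfg$impact_bands)), "low")
  expect_equal(as.character(impact_level(15, cfg$impact_bands)), "moderate")
  expect_equal(as.character(impact_level(40, cfg$impact_bands)), "very_high")
  expect_error(impact_level(41, cfg$impact_bands), class = "copd_staging_error")
})

test_that("the FEV1-based alternative severity driver is available", {
  alt <- engine_config(severity_driver = "fev1_pct")
  staged <- stage_patients(tibble::tibble(
    bmi = 24, fev1_pct = c(85, 60, 40, 25), mmrc = 1, exacerbations = 0), alt)
  expect_equal(as.character(staged$severity),
               c("mild", "moderate", "severe", "very_severe"))
  expect_equal(unique(staged$driving_index), "fev1_pct")
})

test_that("referral fires on severity or frequent exacerbations, with a complete report", {
  rep_ok <- list(scores = list(bodex = 5), spirometry_summary = "ratio 0.58",
                 exacerbation_history = "2/yr")
  sev <- referral_decision("severe", list(exacerbations = 0), cfg, rep_ok)
  expect_true(sev$refer)
  expect_equal(sev$reasons, "severity")

  freq <- referral_decision("mild", list(exacerbations = 3), cfg, rep_ok)
  expect_true(freq$refer)
  expect_equal(freq$reasons, "frequent_exacerbations")

  hosp <- referral_decision("mild", list(exacerbations = 0,
                                         hospitalizations = 1), cfg, rep_ok)
  expect_true(hosp$refer)

  none <- referral_decision("moderate", list(exacerbations = 1,
                                             hospitalizations = 0), cfg)
  expect_false(none$refer)
  expect_null(none$report)

  incomplete <- rep_ok[c("scores", "exacerbation_history")]
  expect_error(referral_decision("severe", list(exacerbations = 0), cfg,
                                 incomplete),
               "missing field 'spirometry_summary'",
               class = "copd_report_error")
})
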