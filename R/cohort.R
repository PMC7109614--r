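#' Specification of a synthetic cohort
#'
#' Defines the population the generator emulates: over-40 primary-care
#' attendees (the population targeted by opportunistic screening), with a
#' configurable obstruction prevalence, true FEV1/FVC ratios drawn relative to
#' each patient's own lower limit of normal (so the fixed-0.7 versus LLN
#' discordance is exercisable by construction), three-attempt spirometry
#' sessions with controllable within-session noise, screening answers sampled
#' to hit target sensitivity/specificity in expectation, and an appointment
#' stream with a configurable no-show probability (defaults in the
#' 10–15% absenteeism range reported for primary-care consultations).
#'
#' @param n Number of patients.
#' @param seed Integer master seed; each patient gets a derived stream so
#'   cohorts are extensible without reshuffling existing patients.
#' @param age_min,age_max,age_mean,age_sd Truncated-normal age distribution
#'   (years).
#' @param male_fraction Fraction of male patients.
#' @param smoking_prevalence Fraction of ever-smokers.
#' @param obstruction_prevalence Ground-truth obstructed fraction.
#' @param obstructed_offset Range (liters ratio units) the true ratio falls
#'   *below* the patient's LLN when obstructed.
#' @param clear_offset Range the true ratio lies *above* the LLN when clear.
#' @param attempt_sigma_l Within-session attempt noise SD (liters).
#' @param attempt_flag_prob Probability an attempt carries a quality failure
#'   (short forced expiratory time or an operator flag).
#' @param screening_sensitivity,screening_specificity Target operating point
#'   of the screening questionnaire against ground truth.
#' @param no_show_prob Appointment no-show probability.
#' @param uncalibrated_prob Probability the spirometer needs recalibration
#'   before the session.
#' @param missing_walk_prob Probability the 6-minute-walk test is not
#'   applicable (BODEx fallback path).
#' @param start_date First appointment-request date.
#' @return A validated `copd_cohort_spec` list.
#' @export
cohort_spec <- function(n = 100, seed = 1,
                        age_min = 41, age_max = 90, age_mean = 62, age_sd = 11,
                        male_fraction = 0.5,
                        smoking_prevalence = 0.45,
                        obstruction_prevalence = 0.25,
                        obstructed_offset = c(0.02, 0.12),
                        clear_offset = c(0.02, 0.15),
                        attempt_sigma_l = 0.05,
                        attempt_flag_prob = 0.03,
                        screening_sensitivity = 0.9,
                        screening_specificity = 0.85,
                        no_show_prob = 0.12,
                        uncalibrated_prob = 0.05,
                        missing_walk_prob = 0.3,
                        start_date = "2024-01-08") {
  spec <- list(
    n = n, seed = seed, age_min = age_min, age_max = age_max,
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    smoking_prevalence = smoking_prevalence,
    obstruction_prevalence = obstruction_prevalence,
    obstructed_offset = obstructed_offset, clear_offset = clear_offset,
    attempt_sigma_l = attempt_sigma_l, attempt_flag_prob = attempt_flag_prob,
    screening_sensitivity = screening_sensitivity,
    screening_specificity = screening_specificity,
    no_show_prob = no_show_prob, uncalibrated_prob = uncalibrated_prob,
    missing_walk_prob = missing_walk_prob, start_date = start_date
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (!is_scalar_number(spec$n) || spec$n < 1) {
    copd_abort("cohort spec: n must be >= 1", "copd_spec_error")
  }
  probs <- c("male_fraction", "smoking_prevalence", "obstruction_prevalence",
             "screening_sensitivity", "screening_specificity", "no_show_prob",
             "uncalibrated_prob", "attempt_flag_prob", "missing_walk_prob")
  for (p in probs) {
    v <- spec[[p]]
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      copd_abort(paste0("cohort spec: ", p, " must be a probability in [0, 1]"),
                 "copd_spec_error")
    }
  }
  if (!is_scalar_number(spec$attempt_sigma_l) || spec$attempt_sigma_l < 0) {
    copd_abort("cohort spec: attempt_sigma_l must be >= 0", "copd_spec_error")
  }
  if (spec$age_min > spec$age_max) {
    copd_abort("cohort spec: age_min must not exceed age_max", "copd_spec_error")
  }
  structure(spec, class = "copd_cohort_spec")
}

#' Read a cohort spec from YAML/JSON
#'
#' @param path Spec document; fields as in [cohort_spec()].
#' @return A validated `copd_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  doc <- read_config_document(path)
  # YAML 1.1 parses a bare `n:` key as boolean FALSE; recover the field name.
  names(doc)[names(doc) == "FALSE"] <- "n"
  do.call(cohort_spec, doc)
}

rtrunc_norm <- function(rng_n, mean, sd, lo, hi) {
  out <- numeric(rng_n)
  for (i in seq_len(rng_n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Allocate `total` points over k items with per-item max, randomly.
distribute_points <- function(total, fixed_first, k, max_per) {
  scores <- c(fixed_first, integer(k - 1L))
  remaining <- max(0L, total - fixed_first)
  while (remaining > 0L) {
    open <- which(scores < max_per)
    open <- setdiff(open, 1L)
    if (length(open) == 0L) break
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    scores[pick] <- scores[pick] + 1L
    remaining <- remaining - 1L
  }
  scores
}

# Generate one spirometry session (3 attempts) for a patient's true values.
generate_session_attempts <- function(true_fvc, true_fev1, sigma, flag_prob) {
  fvc <- clamp(true_fvc + rnorm(3, 0, sigma), 0.3, 9.5)
  fev1 <- true_fev1 + rnorm(3, 0, sigma)
  fev1 <- clamp(fev1, 0.1, fvc * 0.999)
  fet <- runif(3, 7, 12)
  glottis <- rep(FALSE, 3)
  effort <- rep(FALSE, 3)
  for (a in 1:3) {
    if (runif(1) < flag_prob) {
      which_fail <- sample(c("fet", "glottis", "effort"), 1)
      if (which_fail == "fet") fet[a] <- runif(1, 3, 5.5)
      if (which_fail == "glottis") glottis[a] <- TRUE
      if (which_fail == "effort") effort[a] <- TRUE
    }
  }
  list(fvc = fvc, fev1 = fev1, fet = fet,
       glottis_closure = glottis, variable_effort = effort)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec seed (one derived pseudo-random stream per
#' patient). Obstructed patients' true FEV1/FVC ratio is drawn strictly below
#' their own demographic LLN, clear patients' strictly above it; attempt
#' values are the true values plus Gaussian noise; screening answers are
#' constructed to hit the spec's sensitivity/specificity in expectation; the
#' severity stratum is derived from the resulting FEV1 percent predicted and
#' drives dyspnea, exacerbation, CAT and walk-distance draws.
#'
#' @param spec A `copd_cohort_spec`.
#' @param config Engine configuration (for the reference equations).
#' @return A `copd_cohort` list of tibbles: `patients`, `appointments`,
#'   `screening`, `sessions`, `assessments`, `labels`, plus the `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' cohort$labels$true_obstructed
#' @export
generate_cohort <- function(spec = cohort_spec(), config = engine_config()) {
  spec <- validate_cohort_spec(unclass(spec))
  eq <- as.data.frame(config$equations)
  eq_rows <- split(eq, paste(eq$sex, eq$group))
  start <- as_utc(paste0(spec$start_date, "T08:00:00Z"))
  n <- spec$n

  pid <- sprintf("p%05d", seq_len(n))
  num <- function() numeric(n)
  int <- function() integer(n)
  lgl <- function() logical(n)
  chr <- function() character(n)
  age <- int(); sex <- chr(); group <- chr(); height <- num(); bmi <- num()
  smoking_status <- chr(); pack_years <- num()
  dyspnea <- lgl(); chronic_cough <- lgl(); chronic_sputum <- lgl()
  recurrent_infections <- lgl(); risk_exposure <- lgl(); family_hx <- lgl()
  obstructed <- lgl(); lln_ratio <- num(); pred_fev1 <- num(); pred_fvc <- num()
  true_ratio <- num(); true_fvc <- num(); true_fev1 <- num(); fev1_pct_true <- num()
  stratum <- chr(); mmrc <- int(); exac <- int(); hosp <- int()
  cat_score <- int(); six_mwd <- num()
  intended_positive <- lgl(); answers <- matrix(0L, n, 5)
  request_time <- num(); appointment_time <- num()
  no_show <- lgl(); uncalibrated <- lgl()
  att_fvc <- matrix(0, n, 3); att_fev1 <- matrix(0, n, 3)
  att_fet <- matrix(0, n, 3)
  att_glottis <- matrix(FALSE, n, 3); att_effort <- matrix(FALSE, n, 3)

  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i))
    age[i] <- round(rtrunc_norm(1, spec$age_mean, spec$age_sd,
                                spec$age_min, spec$age_max))
    sex[i] <- if (runif(1) < spec$male_fraction) "male" else "female"
    group[i] <- if (runif(1) < 0.8) "european" else "other"
    height[i] <- round(if (sex[i] == "male") rtrunc_norm(1, 175, 7, 150, 200)
                       else rtrunc_norm(1, 162, 6, 140, 190))
    bmi[i] <- round(rtrunc_norm(1, 26, 4, 16, 40), 1)
    smoker <- runif(1) < spec$smoking_prevalence
    smoking_status[i] <- if (!smoker) "never" else sample(c("current", "ex"), 1)
    pack_years[i] <- if (smoker) round(runif(1, 5, 60)) else 0
    risk_exposure[i] <- smoker

    obstructed[i] <- runif(1) < spec$obstruction_prevalence
    row <- eq_rows[[paste(sex[i], group[i])]]
    pred_ratio_pct <- row$ratio_b0 + row$ratio_b_age * age[i]
    lln_ratio[i] <- (pred_ratio_pct - 1.645 * row$ratio_see) / 100
    pred_fev1[i] <- row$fev1_b0 + row$fev1_b_age * age[i] +
      row$fev1_b_height * height[i]
    pred_fvc[i] <- row$fvc_b0 + row$fvc_b_age * age[i] +
      row$fvc_b_height * height[i]
    true_ratio[i] <- if (obstructed[i]) {
      max(0.2, lln_ratio[i] - runif(1, spec$obstructed_offset[1],
                                    spec$obstructed_offset[2]))
    } else {
      min(0.92, lln_ratio[i] + runif(1, spec$clear_offset[1],
                                     spec$clear_offset[2]))
    }
    true_fvc[i] <- pred_fvc[i] * runif(1, 0.75, 1.05)
    true_fev1[i] <- true_ratio[i] * true_fvc[i]
    fev1_pct_true[i] <- 100 * true_fev1[i] / pred_fev1[i]

    stratum[i] <- if (!obstructed[i]) "none"
    else if (fev1_pct_true[i] >= 80) "mild"
    else if (fev1_pct_true[i] >= 50) "moderate"
    else if (fev1_pct_true[i] >= 30) "severe"
    else "very_severe"
    b <- match(stratum[i], c("mild", "moderate", "severe", "very_severe"))

    if (obstructed[i]) {
      mmrc[i] <- clamp(b - 1L + sample(-1:1, 1), 0, 4)
      exac[i] <- stats::rpois(1, c(0.2, 0.6, 1.8, 2.6)[b])
      hosp[i] <- stats::rbinom(1, 1, c(0.01, 0.05, 0.2, 0.4)[b])
      cat_score[i] <- round(clamp(rnorm(1, c(9, 14, 22, 30)[b], 4), 0, 40))
      six_mwd[i] <- round(clamp(rnorm(1, c(450, 380, 280, 180)[b], 40), 50, 750))
      dyspnea[i] <- mmrc[i] >= 1
      chronic_cough[i] <- runif(1) < 0.7
      chronic_sputum[i] <- runif(1) < 0.5
      recurrent_infections[i] <- runif(1) < 0.3
    } else {
      mmrc[i] <- sample(0:1, 1, prob = c(0.85, 0.15))
      cat_score[i] <- round(clamp(rnorm(1, 6, 3), 0, 40))
      six_mwd[i] <- round(clamp(rnorm(1, 480, 50), 50, 750))
      dyspnea[i] <- runif(1) < 0.1
      chronic_cough[i] <- runif(1) < 0.1
      chronic_sputum[i] <- runif(1) < 0.05
    }
    family_hx[i] <- runif(1) < 0.1
    if (runif(1) < spec$missing_walk_prob) six_mwd[i] <- NA_real_

    # Screening answers constructed to hit the intended call.
    intended_positive[i] <- if (obstructed[i]) {
      runif(1) < spec$screening_sensitivity
    } else {
      runif(1) > spec$screening_specificity
    }
    age_band <- if (age[i] <= 50) 0L else if (age[i] <= 65) 1L else 2L
    target <- if (intended_positive[i]) sample(5:9, 1) else sample(0:4, 1)
    answers[i, ] <- distribute_points(target, age_band, 5L, 2L)

    request_time[i] <- as.numeric(start) + round(runif(1, 0, 60)) * 86400 +
      round(runif(1, 0, 8 * 3600))
    appointment_time[i] <- request_time[i] + round(runif(1, 3, 14)) * 86400
    no_show[i] <- runif(1) < spec$no_show_prob
    uncalibrated[i] <- runif(1) < spec$uncalibrated_prob

    s <- generate_session_attempts(true_fvc[i], true_fev1[i],
                                   spec$attempt_sigma_l,
                                   spec$attempt_flag_prob)
    att_fvc[i, ] <- s$fvc
    att_fev1[i, ] <- s$fev1
    att_fet[i, ] <- s$fet
    att_glottis[i, ] <- s$glottis_closure
    att_effort[i, ] <- s$variable_effort
  }

  as_time <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  structure(
    list(
      patients = tibble(
        patient_id = pid, age = age, sex = sex, group = group,
        height = height, weight = round(bmi * (height / 100)^2, 1), bmi = bmi,
        smoking_status = smoking_status, pack_years = pack_years,
        dyspnea = dyspnea, chronic_cough = chronic_cough,
        chronic_sputum = chronic_sputum,
        recurrent_infections = recurrent_infections,
        risk_exposure = risk_exposure, family_history_copd = family_hx
      ),
      appointments = tibble(
        patient_id = pid, age = age, request_time = as_time(request_time),
        appointment_time = as_time(appointment_time), no_show = no_show,
        uncalibrated = uncalibrated
      ),
      screening = tibble(
        patient_id = pid, age_band = answers[, 1], pack_years_band = answers[, 2],
        dyspnea_exertion = answers[, 3], chronic_cough_sputum = answers[, 4],
        breathing_episodes = answers[, 5], intended_positive = intended_positive
      ),
      sessions = tibble(
        patient_id = rep(pid, each = 3), session_round = 1L,
        attempt = rep(1:3, n),
        fvc = as.vector(t(att_fvc)), fev1 = as.vector(t(att_fev1)),
        fet = as.vector(t(att_fet)),
        glottis_closure = as.vector(t(att_glottis)),
        variable_effort = as.vector(t(att_effort))
      ),
      assessments = tibble(
        patient_id = pid, bmi = bmi, mmrc = mmrc, exacerbations = exac,
        hospitalizations = hosp, cat_score = cat_score, six_mwd = six_mwd
      ),
      labels = tibble(
        patient_id = pid, true_obstructed = obstructed,
        true_severity = stratum, true_ratio = true_ratio,
        lln_ratio = lln_ratio, true_fev1 = true_fev1, true_fvc = true_fvc,
        pred_fev1 = pred_fev1, fev1_pct_true = fev1_pct_true
      ),
      spec = spec
    ),
    class = "copd_cohort"
  )
}

# Regenerate a repeat session for a patient deterministically.
regenerate_session <- function(cohort, patient_index, round) {
  set.seed(derive_seed(cohort$spec$seed, patient_index * 101L + round))
  lab <- cohort$labels[patient_index, ]
  s <- generate_session_attempts(lab$true_fvc, lab$true_fev1,
                                 cohort$spec$attempt_sigma_l,
                                 cohort$spec$attempt_flag_prob)
  tibble(patient_id = lab$patient_id, session_round = as.integer(round),
         attempt = 1:3, fvc = s$fvc, fev1 = s$fev1, fet = s$fet,
         glottis_closure = s$glottis_closure, variable_effort = s$variable_effort)
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat("<copd_cohort>", nrow(x$patients), "patients, seed", x$spec$seed, "\n")
  cat("  true obstructed:", sum(x$labels$true_obstructed), "| sessions:",
      nrow(x$sessions), "attempt rows\n")
  invisible(x)
}
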