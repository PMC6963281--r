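# Profile-conditioned vital-sign generation, synthetic patient profiles and
# cohort assembly (profiles + joined per-minute observation streams).

# altitude effect scale: fractional barometric-pressure drop maps to an SpO2
# decrease and heart-rate increase (high-altitude hypoxia response)
.spo2_altitude_gain <- -20   # % SpO2 per unit fractional pressure drop
.hr_altitude_gain <- 30      # bpm per unit fractional pressure drop

#' Generate vital-sign samples for a profile and activity category
#'
#' Each vital is drawn from a Gaussian centred on the midpoint of the
#' profile's safe band for the activity category, truncated at four standard
#' deviations. Heart rate is centred on [expected_resting_hr()] with the
#' reference spread for the profile's stage and age. When ambient conditions
#' are supplied, centres shift by the closed-form physiology deltas: cold or
#' hot ambient temperature raises HR/SBP/DBP, and altitude lowers SpO2 and
#' raises HR in proportion to the fractional barometric-pressure drop. A
#' configurable anomaly rate injects out-of-band episodes (the ground-truth
#' flag is returned in the `anomaly` column).
#'
#' @param profile A [patient_profile()].
#' @param category `"resting"` or an activity category; `"resting"` uses the
#'   sedentary bands with the resting heart-rate reference.
#' @param env Optional ambient conditions: named list with any of
#'   `outdoor_temperature` (degrees C) and `altitude` (m). `NULL` applies no
#'   ambient shift.
#' @param n Number of per-minute samples.
#' @param seed Optional integer seed.
#' @param anomaly_rate Probability that a sample is an injected abnormal
#'   episode (one random vital pushed out of band).
#' @return Data frame with one column per vital (see [vital_names()]) plus
#'   logical `anomaly`.
#' @export
generate_vitals <- function(profile, category = "resting", env = NULL,
                            n = 1, seed = NULL, anomaly_rate = 0) {
  stopifnot(inherits(profile, "copd_profile"), n >= 1)
  category <- match.arg(category, c("resting", .activity_categories))
  if (!is.null(seed)) set.seed(seed)
  band_cat <- if (category == "resting") "sedentary" else category
  centers <- numeric(0); sds <- numeric(0)
  for (v in .vital_names) {
    b <- activity_band(profile, v, band_cat)
    centers[v] <- (b$low + b$high) / 2
    sds[v] <- max((b$high - b$low) / 4, 0.01)
  }
  centers["heart_rate"] <- expected_resting_hr(profile, category)
  sds["heart_rate"] <- expected_hr_sd(profile, category)
  if (!is.null(env)) {
    if (!is.null(env$outdoor_temperature)) {
      d <- temperature_vital_deltas(env$outdoor_temperature)
      centers["heart_rate"] <- centers["heart_rate"] + d$d_hr
      centers["sbp"] <- centers["sbp"] + d$d_sbp
      centers["dbp"] <- centers["dbp"] + d$d_dbp
    }
    if (!is.null(env$altitude) && env$altitude > 0) {
      f <- 1 - barometric_pressure(env$altitude) / 760
      centers["spo2"] <- centers["spo2"] + .spo2_altitude_gain * f
      centers["heart_rate"] <- centers["heart_rate"] + .hr_altitude_gain * f
    }
  }
  out <- lapply(.vital_names, function(v) {
    z <- pmin(pmax(stats::rnorm(n), -4), 4)   # truncate at +/- 4 sd
    centers[[v]] + sds[[v]] * z
  })
  names(out) <- .vital_names
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$spo2 <- pmin(out$spo2, 100)
  anomaly <- stats::runif(n) < anomaly_rate
  if (any(anomaly)) {
    which_v <- sample(.vital_names, sum(anomaly), replace = TRUE)
    for (v in unique(which_v)) {
      rows <- which(anomaly)[which_v == v]
      b <- activity_band(profile, v, band_cat)
      half <- (b$high - b$low) / 2
      up <- stats::runif(length(rows)) < 0.5
      out[[v]][rows] <- ifelse(up, b$high + 1.5 * pmax(half, 4 * sds[[v]]),
                               b$low - 1.5 * pmax(half, 4 * sds[[v]]))
    }
    out$spo2 <- pmin(out$spo2, 100)
  }
  out$anomaly <- anomaly
  out
}

#' Generate a synthetic patient cohort's profiles
#'
#' Random demographically plausible COPD profiles spanning GOLD stages I-IV
#' and dependency levels, with stage-conditioned baselines (FEV1, PaO2,
#' SpO2, PaCO2 worsen with stage) and per-activity bands synthesized from
#' the baselines.
#'
#' @param n Number of profiles (>= 1).
#' @param seed Optional integer seed.
#' @return List of [patient_profile()] objects.
#' @export
generate_profiles <- function(n, seed = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stages <- c("I", "II", "III", "IV")
  stage_p <- c(0.3, 0.3, 0.25, 0.15)
  # stage-conditioned baseline means: pao2, spo2, paco2, rr, ph, hco3, fev1
  stage_base <- list(
    I   = c(pao2 = 80, spo2 = 96.5, paco2 = 38, rr = 14, ph = 7.40,
            hco3 = 24, fev1 = 2.8),
    II  = c(pao2 = 75, spo2 = 95.5, paco2 = 40, rr = 15, ph = 7.39,
            hco3 = 25, fev1 = 2.0),
    III = c(pao2 = 68, spo2 = 93.5, paco2 = 43, rr = 17, ph = 7.37,
            hco3 = 26, fev1 = 1.2),
    IV  = c(pao2 = 60, spo2 = 91.0, paco2 = 47, rr = 20, ph = 7.35,
            hco3 = 28, fev1 = 0.7)
  )
  lapply(seq_len(n), function(i) {
    stage <- sample(stages, 1L, prob = stage_p)
    sb <- stage_base[[stage]]
    gender <- sample(c("male", "female"), 1L)
    age <- round(stats::runif(1, 40, 90))
    height <- round(stats::rnorm(1, if (gender == "male") 174 else 161, 7))
    bmi <- stats::rnorm(1, 26, 4)
    bmi <- min(max(bmi, 17), 38)
    weight <- round(bmi * (height / 100)^2, 1)
    mmrc <- min(4L, max(0L, match(stage, stages) - 1L +
                          sample(c(0L, 1L), 1L)))
    coms <- .known_comorbidities[stats::runif(7) < 0.12]
    meds <- c("SABA", "LABA", "inhaler")[stats::runif(3) < c(0.5, 0.4, 0.5)]
    smoker <- stats::runif(1) < 0.3
    baselines <- c(
      temperature = stats::rnorm(1, 36.6, 0.2),
      dbp = stats::rnorm(1, 76, 5),
      sbp = stats::rnorm(1, 118, 8),
      heart_rate = 0,  # filled from the reference model below
      pao2 = stats::rnorm(1, sb[["pao2"]], 3),
      spo2 = min(stats::rnorm(1, sb[["spo2"]], 1), 99),
      paco2 = stats::rnorm(1, sb[["paco2"]], 2),
      vo2 = stats::rnorm(1, 2.5, 0.3),
      respiration_rate = stats::rnorm(1, sb[["rr"]], 1.5),
      ph = stats::rnorm(1, sb[["ph"]], 0.02),
      hco3 = stats::rnorm(1, sb[["hco3"]], 1.5),
      fev1 = max(stats::rnorm(1, sb[["fev1"]], 0.2), 0.4)
    )
    p <- patient_profile(
      id = sprintf("P%03d", i), age = age, gender = gender, height = height,
      weight = weight, smoker = smoker, gold_stage = stage, mmrc = mmrc,
      comorbidities = coms, medications = meds,
      baselines = replace(baselines, "heart_rate", 70))
    hr <- expected_resting_hr(p, "resting") + stats::rnorm(1, 0, 2)
    patient_profile(
      id = p$id, age = age, gender = gender, height = height,
      weight = weight, smoker = smoker, gold_stage = stage, mmrc = mmrc,
      comorbidities = coms, medications = meds,
      baselines = replace(baselines, "heart_rate", hr))
  })
}

#' Generate a full synthetic cohort with joined observation streams
#'
#' For each patient: a profile, a Markov activity sequence, an environmental
#' series and per-minute profile-conditioned vitals, joined into one record
#' per minute (timestamp, activity, location, indoor/outdoor environment,
#' vitals, altitude, ground-truth anomaly flag). A single patient followed
#' for 365 days yields exactly 525,600 records.
#'
#' @param n_patients Number of patients (>= 1).
#' @param days Days of follow-up per patient (>= 1).
#' @param seed Integer seed; each patient derives an independent sub-seed.
#' @param anomaly_rate Per-minute probability of an injected abnormal vital.
#' @param start Start timestamp of the follow-up.
#' @return List with `profiles` (list of profiles) and `streams` (named list
#'   of per-patient data frames).
#' @export
generate_cohort <- function(n_patients, days, seed = 1,
                            anomaly_rate = 5e-4,
                            start = as.POSIXct("2024-01-01 00:00:00",
                                               tz = "UTC")) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  if (!is.numeric(days) || days < 1) stop("days must be >= 1", call. = FALSE)
  n_patients <- as.integer(n_patients); days <- as.integer(days)
  profiles <- generate_profiles(n_patients, seed = seed)
  streams <- list()
  for (i in seq_len(n_patients)) {
    streams[[profiles[[i]]$id]] <-
      patient_stream(profiles[[i]], days, seed = seed + 1000L * i,
                     anomaly_rate = anomaly_rate, start = start)
  }
  list(profiles = profiles, streams = streams)
}

# one patient's joined per-minute stream
patient_stream <- function(profile, days, seed, anomaly_rate = 5e-4,
                           start = as.POSIXct("2024-01-01 00:00:00",
                                              tz = "UTC")) {
  env <- generate_environment(days, seed = seed, start = start)
  set.seed(seed + 1L)
  model <- transition_model(icf_capacity(profile))
  act <- do.call(rbind, lapply(seq_len(days), function(d)
    activity_minutes(generate_activity_day(model, profile))))
  stopifnot(nrow(act) == nrow(env))
  # vitals drawn per activity category, shifted by ambient physiology
  set.seed(seed + 2L)
  n <- nrow(env)
  outdoor <- act$location == "outdoor"
  vit <- as.data.frame(matrix(NA_real_, n, length(.vital_names),
                              dimnames = list(NULL, .vital_names)))
  anomaly <- logical(n)
  for (cat in .activity_categories) {
    idx <- which(act$activity_category == cat)
    if (!length(idx)) next
    block <- generate_vitals(profile, cat, n = length(idx),
                             anomaly_rate = anomaly_rate)
    vit[idx, ] <- block[, .vital_names]
    anomaly[idx] <- block$anomaly
  }
  # ambient temperature affects only minutes actually spent outdoors
  d <- temperature_vital_deltas(env$outdoor_temperature)
  vit$heart_rate[outdoor] <- vit$heart_rate[outdoor] + d$d_hr[outdoor]
  vit$sbp[outdoor] <- vit$sbp[outdoor] + d$d_sbp[outdoor]
  vit$dbp[outdoor] <- vit$dbp[outdoor] + d$d_dbp[outdoor]
  cbind(data.frame(timestamp = env$timestamp, patient_id = profile$id,
                   stringsAsFactors = FALSE),
        act, env[, setdiff(names(env), "timestamp")], vit,
        data.frame(altitude = 0, anomaly = anomaly))
}
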