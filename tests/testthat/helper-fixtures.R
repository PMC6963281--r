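# Shared fixtures: reference profiles built in code.

# The worked-example profile: 51-year-old male, GOLD I, GERD, baseline
# PaO2 78 mmHg, FEV1 1.73 L.
table7_profile <- function() {
  patient_profile(
    id = "t7", age = 51, gender = "male", height = 172, weight = 68,
    smoker = FALSE, gold_stage = "I", mmrc = 2, comorbidities = "GERD",
    medications = c("SABA", "LABA"),
    baselines = c(temperature = 36.95, dbp = 75, sbp = 115, heart_rate = 72,
                  pao2 = 78, spo2 = 96, paco2 = 39, vo2 = 2.53,
                  respiration_rate = 15, ph = 7.3, hco3 = 25, fev1 = 1.73))
}

# The example medical record with printed per-activity bands (heart rate
# baseline 60 with light band 60-97; SpO2 baseline 96.01 with vigorous band
# 91.30-92.6).
table6_profile <- function() {
  bands <- data.frame(
    vital = c("heart_rate", "heart_rate", "heart_rate",
              "spo2", "spo2", "spo2"),
    category = rep(c("light", "moderate", "vigorous"), 2),
    low = c(60, 98, 121, 95.21, 93.10, 91.30),
    high = c(97, 120, 130, 96.01, 95, 92.6),
    stringsAsFactors = FALSE)
  patient_profile(
    id = "t6", age = 77, gender = "male", height = 184, weight = 99,
    bmi = 29.33, smoker = TRUE, gold_stage = "II", mmrc = 2,
    comorbidities = "anemia", medications = "SABA",
    baselines = c(temperature = 36.39, dbp = 75.9, sbp = 120,
                  heart_rate = 60, pao2 = 78, spo2 = 96.01, paco2 = 39,
                  vo2 = 2.53, respiration_rate = 14, ph = 7.35, hco3 = 24,
                  fev1 = 1.01),
    activity_bands = bands)
}

# minimal clean profile with a chosen stage/age and no HR modifiers
stage_profile <- function(stage, age = 45, gender = "male",
                          comorbidities = character(), smoker = FALSE,
                          medications = character(), mmrc = 1) {
  base <- switch(stage,
    I   = c(pao2 = 80, spo2 = 96.5, paco2 = 38, rr = 14, ph = 7.40,
            hco3 = 24, fev1 = 2.8),
    II  = c(pao2 = 75, spo2 = 95.5, paco2 = 40, rr = 15, ph = 7.39,
            hco3 = 25, fev1 = 2.0),
    III = c(pao2 = 68, spo2 = 93.5, paco2 = 43, rr = 17, ph = 7.37,
            hco3 = 26, fev1 = 1.2),
    IV  = c(pao2 = 60, spo2 = 91.0, paco2 = 47, rr = 20, ph = 7.35,
            hco3 = 28, fev1 = 0.7))
  patient_profile(
    id = paste0("s", stage), age = age, gender = gender, height = 175,
    weight = 75, smoker = smoker, gold_stage = stage, mmrc = mmrc,
    comorbidities = comorbidities, medications = medications,
    baselines = c(temperature = 36.6, dbp = 76, sbp = 118, heart_rate = 75,
                  pao2 = base[["pao2"]], spo2 = base[["spo2"]],
                  paco2 = base[["paco2"]], vo2 = 2.5,
                  respiration_rate = base[["rr"]], ph = base[["ph"]],
                  hco3 = base[["hco3"]], fev1 = base[["fev1"]]))
}

# hand-built single-parameter observation stream for engine tests:
# indoor CO readings at 1-minute resolution, numeric timestamps
co_stream <- function(values, start_minute = 1) {
  n <- length(values)
  data.frame(timestamp = seq(start_minute, length.out = n),
             activity_category = "sedentary", location = "indoor",
             co = values, stringsAsFactors = FALSE)
}

# independent sliding-window recomputation of the firing minutes for one
# rule over one violation sequence (TRUE/FALSE/NA). Run lengths are
# recomputed by explicit backward window scans at every minute (O(n * W))
# rather than by a running accumulator, and the re-arm condition is
# recomputed by scanning for a refractory-length compliant block since the
# last fire.
oracle_fire_minutes <- function(violation, window, refractory = 5) {
  obs <- which(!is.na(violation))     # frozen minutes drop out entirely
  v <- violation[obs]
  fires <- integer()
  last_fire_pos <- 0L
  for (k in seq_along(v)) {
    if (!v[k]) next
    run <- 0L
    j <- k
    while (j >= 1 && v[j]) { run <- run + 1L; j <- j - 1L }
    if (run < window + 1) next
    armed <- if (last_fire_pos == 0L) TRUE else {
      span <- if (last_fire_pos + 1 <= k - 1) v[(last_fire_pos + 1):(k - 1)]
              else logical(0)
      clear_runs <- rle(!span)
      any(clear_runs$values & clear_runs$lengths >= refractory)
    }
    # only the first minute at which the run reaches the window can fire
    if (armed && run == window + 1) {
      fires <- c(fires, obs[k])
      last_fire_pos <- k
    } else if (armed && run > window + 1) {
      # armed with a longer run means the rule re-armed mid-violation,
      # which the engine forbids; it must not fire
    }
  }
  fires
}
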