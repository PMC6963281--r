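test_that("transition matrices are row-stochastic and capacity-aware", {
  for (cap in c("light", "moderate", "vigorous")) {
    m <- transition_model(cap)
    for (d in 1:6) {
      sums <- rowSums(m$matrices[[d]])
      expect_true(all(abs(sums - 1) < 1e-9), info = paste(cap, d))
    }
  }
  m_light <- transition_model("light")
  banned <- activity_labels()[activity_category_of(activity_labels()) %in%
                                c("moderate", "vigorous")]
  for (d in 1:6) {
    expect_true(all(m_light$matrices[[d]][, banned] == 0))
  }
})

test_that("a generated day tiles 1440 minutes with no gaps or overlaps", {
  p <- stage_profile("II")
  for (seed in c(1, 22, 333)) {
    day <- generate_activity_day(profile = p, seed = seed)
    expect_equal(day$start[1], 0)
    expect_equal(day$end[nrow(day)], 1440)
    expect_true(all(day$end > day$start))
    if (nrow(day) > 1) {
      expect_equal(day$start[-1], day$end[-nrow(day)])  # contiguous
    }
    expect_equal(sum(day$end - day$start), 1440)
    # same seed reproduces the day exactly
    expect_identical(day, generate_activity_day(profile = p, seed = seed))
  }
})

test_that("per-day activity frequencies respect the model bounds", {
  p <- stage_profile("I")
  m <- transition_model()
  set.seed(5150)
  for (i in 1:30) {
    day <- generate_activity_day(m, p)
    counts <- table(factor(day$activity, levels = m$activities))
    expect_true(all(counts <= m$fbounds$f_max[match(names(counts),
                                                    m$fbounds$activity)]))
    expect_gte(counts[["sleeping"]], 1)
  }
})

test_that("functional capacity excludes activities the profile cannot perform", {
  p_iv <- stage_profile("IV")
  expect_equal(icf_capacity(p_iv), "light")
  expect_equal(icf_capacity(stage_profile("III")), "moderate")
  expect_equal(icf_capacity(stage_profile("II", mmrc = 3)), "light")
  expect_equal(icf_capacity(stage_profile("I")), "vigorous")
  set.seed(77)
  m <- transition_model("light")
  for (i in 1:200) {
    day <- generate_activity_day(m, p_iv)
    expect_false(any(day$category %in% c("moderate", "vigorous")))
  }
  # capacity is tightened automatically if the model allows more
  day <- generate_activity_day(transition_model("vigorous"), p_iv, seed = 9)
  expect_false(any(day$category %in% c("moderate", "vigorous")))
})

test_that("empirical transition frequencies match the matrix rows", {
  m <- transition_model()
  counts0 <- stats::setNames(integer(18), m$activities)
  set.seed(2718)
  n <- 1e5
  from <- "eating"; daypart <- 3
  draws <- vapply(seq_len(n), function(i)
    copdwatch:::sample_next_activity(m, daypart, from, counts0),
    character(1))
  p <- m$matrices[[daypart]][from, ]
  obs <- table(factor(draws, levels = m$activities))
  for (a in m$activities[p > 1e-4]) {
    se <- sqrt(n * p[a] * (1 - p[a]))
    expect_lt(abs(obs[[a]] - n * p[a]), 3 * se + 1e-9,
              label = paste("count for", a))
  }
})

test_that("environmental series carry every schema field deterministically", {
  env <- generate_environment(1, seed = 31)
  need <- c("outdoor_humidity", "outdoor_temperature", "wind_speed",
            "wind_direction", "precipitation", "snowfall",
            "outdoor_pressure", "aqhi", "co_out", "h2s", "no", "no2", "nox",
            "o3", "pm10", "pm25", "so2", "trs", "indoor_temperature",
            "indoor_humidity", "indoor_pressure", "co2", "voc",
            "indoor_pm25", "indoor_pm10")
  expect_true(all(need %in% names(env)))
  expect_equal(nrow(env), 1440)
  concentrations <- c("co_out", "h2s", "no", "no2", "nox", "o3", "pm10",
                      "pm25", "so2", "trs", "co2", "voc", "indoor_pm25",
                      "indoor_pm10", "precipitation", "snowfall")
  for (f in concentrations) expect_true(all(env[[f]] >= 0), info = f)
  expect_identical(env, generate_environment(1, seed = 31))
  expect_false(identical(env, generate_environment(1, seed = 32)))
})

test_that("long-run means of the mean-reverting fields match the configuration", {
  env <- generate_environment(365, seed = 365)
  cfg <- copdwatch:::default_season_profile()
  # fields driven purely by the mean-reverting process (episodic boosts and
  # precipitation are excluded by design)
  ou_fields <- c("outdoor_temperature", "outdoor_humidity", "wind_speed",
                 "outdoor_pressure", "o3", "indoor_temperature",
                 "indoor_humidity", "indoor_pressure", "co2", "voc",
                 "indoor_pm25", "indoor_pm10")
  for (f in ou_fields) {
    expect_lt(abs(mean(env[[f]]) - cfg[[f]]$mean),
              0.02 * abs(cfg[[f]]$mean) + 1e-9, label = f)
  }
})

test_that("generated vitals centre on the profile bands and respect truncation", {
  p <- stage_profile("II")
  v <- generate_vitals(p, "light", n = 2000, seed = 8, anomaly_rate = 0)
  expect_equal(nrow(v), 2000)
  for (vt in vital_names()) {
    b <- activity_band(p, vt, "light")
    center <- if (vt == "heart_rate") expected_resting_hr(p, "light")
              else (b$low + b$high) / 2
    sd_v <- if (vt == "heart_rate") copdwatch:::expected_hr_sd(p, "light")
            else max((b$high - b$low) / 4, 0.01)
    # anomaly rate 0: every sample within 4 sd of its centre
    expect_true(all(abs(v[[vt]] - center) <= 4 * sd_v + 1e-9), info = vt)
  }
  expect_true(all(v$spo2 <= 100))
  expect_false(any(v$anomaly))
  # determinism
  expect_identical(v, generate_vitals(p, "light", n = 2000, seed = 8,
                                      anomaly_rate = 0))
})

test_that("cold ambient temperature raises mean heart rate by the closed-form delta", {
  p <- stage_profile("I")
  n <- 20000
  cold <- generate_vitals(p, "resting", env = list(outdoor_temperature = 12),
                          n = n, seed = 55)
  warm <- generate_vitals(p, "resting", env = list(outdoor_temperature = 22),
                          n = n, seed = 55)
  # identical noise stream, so the difference in means is exact
  expect_equal(mean(cold$heart_rate) - mean(warm$heart_rate), 0.63,
               tolerance = 1e-9)
})

test_that("altitude lowers SpO2 and raises heart rate", {
  p <- stage_profile("I")
  sea <- generate_vitals(p, "resting", env = list(altitude = 0),
                         n = 5000, seed = 77)
  high <- generate_vitals(p, "resting", env = list(altitude = 2500),
                          n = 5000, seed = 77)
  expect_lt(mean(high$spo2), mean(sea$spo2))
  expect_gt(mean(high$heart_rate), mean(sea$heart_rate))
})

test_that("anomaly injection produces out-of-band episodes at the requested rate", {
  p <- stage_profile("II")
  n <- 20000
  v <- generate_vitals(p, "sedentary", n = n, seed = 12, anomaly_rate = 0.01)
  rate <- mean(v$anomaly)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  # flagged rows have at least one vital out of its band
  bad <- which(v$anomaly)
  out_of_band <- vapply(bad, function(i) {
    any(vapply(vital_names(), function(vt) {
      b <- activity_band(p, vt, "sedentary")
      !in_band(b, v[[vt]][i])
    }, logical(1)))
  }, logical(1))
  expect_true(all(out_of_band))
})

test_that("cohort generation joins activities, environment and vitals per minute", {
  expect_error(generate_cohort(0, 10), "n_patients")
  expect_error(generate_cohort(2, 0), "days")
  ch <- generate_cohort(2, 2, seed = 99)
  expect_length(ch$profiles, 2)
  expect_named(ch$streams, vapply(ch$profiles, `[[`, character(1), "id"))
  s <- ch$streams[[1]]
  expect_equal(nrow(s), 2 * 1440)
  mandatory <- c("timestamp", "activity", "activity_category", "location",
                 "indoor_temperature", "outdoor_temperature", "co2",
                 "indoor_pm10", vital_names(), "altitude", "anomaly")
  expect_true(all(mandatory %in% names(s)))
  expect_false(any(is.na(s[, c("activity_category", vital_names())])))
  # activity labels consistent with their categories
  expect_equal(activity_category_of(s$activity), s$activity_category)
  # vigorous minutes draw vitals from vigorous bands (within 4 sd + ambient)
  p <- ch$profiles[[1]]
  vig <- s[s$activity_category == "vigorous", ]
  if (nrow(vig)) {
    b <- activity_band(p, "respiration_rate", "vigorous")
    sd_v <- (b$high - b$low) / 4
    center <- (b$low + b$high) / 2
    ok <- abs(vig$respiration_rate - center) <= 4 * sd_v + 1e-9
    expect_gt(mean(ok), 0.99)  # all but injected anomalies
  }
  # determinism across runs
  ch2 <- generate_cohort(2, 2, seed = 99)
  expect_identical(ch$streams[[2]], ch2$streams[[2]])
})
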