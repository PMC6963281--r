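test_that("dynamic threshold steps with accumulated exposure", {
  pm10 <- Filter(function(r) r$id == "pm10_dynamic",
                 load_rulepack("pollution")$rules)[[1]]
  expect_equal(dynamic_threshold(pm10, "low", 0)$value, 0.150)
  expect_equal(dynamic_threshold(pm10, "low", 479)$value, 0.150)
  expect_equal(dynamic_threshold(pm10, "low", 540)$value, 0.020)
  expect_equal(dynamic_threshold(pm10, "low", 1440)$value, 0.020)
  # schedule applies only to its severity group
  expect_equal(dynamic_threshold(pm10, "high", 540)$value, 0.150)
  # static rules return their printed limit unchanged
  co <- Filter(function(r) r$id == "co_1h",
               load_rulepack("pollution")$rules)[[1]]
  for (expo in c(0, 60, 600)) {
    expect_equal(dynamic_threshold(co, "low", expo)$value, 2)
  }
  # upper limit non-increasing in exposure
  lims <- vapply(seq(0, 1440, by = 10), function(e)
    dynamic_threshold(pm10, "low", e)$value, numeric(1))
  expect_true(all(diff(lims) <= 0))
})

test_that("immediate rules fire on the first violating minute", {
  p <- stage_profile("I")
  vit <- expand_rulepack(load_rulepack("vitals"), p)
  hr_band <- activity_band(p, "heart_rate", "light")
  rec <- list(timestamp = 1, activity_category = "light", location = "indoor",
              heart_rate = hr_band$high + 20)
  res <- evaluate_minute(p, rec, packs = vit)
  expect_equal(nrow(res$alarms), 1)
  expect_equal(res$alarms$category, "vital")
  expect_equal(res$alarms$rule_id, "hr_light")
  expect_true(nzchar(res$alarms$suggestion))
  # in-band value: no alarm
  rec$heart_rate <- (hr_band$low + hr_band$high) / 2
  res2 <- evaluate_minute(p, rec, packs = vit)
  expect_equal(nrow(res2$alarms), 0)
})

test_that("exposure-window rules fire when the violation exceeds the window", {
  p <- stage_profile("I")
  pol <- load_rulepack("pollution")
  # 61 consecutive minutes of CO at 2.5 ppm: alarm at minute 61, none before
  log <- evaluate_stream(p, co_stream(rep(2.5, 61)), pol)
  expect_equal(nrow(log), 1)
  expect_equal(log$timestamp, 61)
  expect_equal(log$rule_id, "co_1h")
  # 60 minutes only: no alarm
  log60 <- evaluate_stream(p, co_stream(rep(2.5, 60)), pol)
  expect_equal(nrow(log60), 0)
  # compliant values keep the log empty
  log0 <- evaluate_stream(p, co_stream(rep(1.2, 120)), pol)
  expect_equal(nrow(log0), 0)
})

test_that("missing sensor values freeze the accumulator", {
  p <- stage_profile("I")
  pol <- load_rulepack("pollution")
  vals <- c(rep(2.5, 30), rep(NA_real_, 5), rep(2.5, 31))
  log <- evaluate_stream(p, co_stream(vals), pol)
  expect_equal(nrow(log), 1)
  expect_equal(log$timestamp, 66)  # 61st violating minute, gaps skipped
  # a compliant minute resets the run entirely: 61 fresh minutes needed
  vals2 <- c(rep(2.5, 30), 1.0, rep(2.5, 61))
  log2 <- evaluate_stream(p, co_stream(vals2), pol)
  expect_equal(nrow(log2), 1)
  expect_equal(log2$timestamp, 92)
  # with one minute fewer the alarm is never reached
  log3 <- evaluate_stream(p, co_stream(vals2[-length(vals2)]), pol)
  expect_equal(nrow(log3), 0)
})

test_that("alarm de-duplication suppresses repeats until re-armed", {
  p <- stage_profile("I")
  vit <- expand_rulepack(load_rulepack("vitals"), p)
  hr_hi <- activity_band(p, "heart_rate", "light")$high + 20
  hr_ok <- mean(unlist(activity_band(p, "heart_rate", "light")))
  # 30 violating minutes: one alarm, not 30
  stream <- data.frame(timestamp = 1:30, activity_category = "light",
                       location = "indoor", heart_rate = hr_hi)
  expect_equal(nrow(evaluate_stream(p, stream, vit)), 1)
  # violation, long recovery, violation again: two alarms
  stream2 <- data.frame(timestamp = 1:30, activity_category = "light",
                        location = "indoor",
                        heart_rate = c(rep(hr_hi, 10), rep(hr_ok, 10),
                                       rep(hr_hi, 10)))
  expect_equal(nrow(evaluate_stream(p, stream2, vit)), 2)
  # recovery shorter than the refractory: still one alarm
  stream3 <- data.frame(timestamp = 1:30, activity_category = "light",
                        location = "indoor",
                        heart_rate = c(rep(hr_hi, 10), rep(hr_ok, 3),
                                       rep(hr_hi, 17)))
  expect_equal(nrow(evaluate_stream(p, stream3, vit)), 1)
})

test_that("engine agrees with the brute-force sliding-window oracle", {
  p <- stage_profile("I")
  set.seed(314)
  for (rep in 1:12) {
    W <- sample(c(0, 1, 5, 30, 60), 1)
    vals <- round(stats::rnorm(1440, mean = 2, sd = 0.6), 3)
    vals[stats::runif(1440) < 0.05] <- NA
    r <- rule("test_co", "pollution", "co",
              limit = list(direction = "above", value = 2),
              exposure_window = if (W > 0) W else NULL)
    pack <- rulepack("test", list(r))
    log <- evaluate_stream(p, co_stream(vals), pack)
    expected <- oracle_fire_minutes(vals > 2, W, refractory = 5)
    expect_equal(log$timestamp, expected, info = paste("rep", rep, "W", W))
    # every emitted alarm's value violates the recorded constraint
    if (nrow(log)) {
      expect_true(all(log$value < log$low | log$value > log$high))
    }
  }
})

test_that("evaluation is deterministic and enforces time ordering", {
  p <- stage_profile("I")
  pol <- load_rulepack("pollution")
  set.seed(4)
  vals <- stats::rnorm(500, 2, 0.5)
  a <- evaluate_stream(p, co_stream(vals), pol)
  b <- evaluate_stream(p, co_stream(vals), pol)
  expect_identical(a, b)
  st <- new_exposure_state(p, pol)
  res <- evaluate_minute(p, list(timestamp = 10, activity_category = "light",
                                 location = "indoor", co = 1), st)
  expect_error(
    evaluate_minute(p, list(timestamp = 9, activity_category = "light",
                            location = "indoor", co = 1), res$state),
    "out-of-order")
})

test_that("dynamic PM10 rule tightens after 8 h of indoor exposure", {
  p_low <- stage_profile("I")
  expect_equal(severity_group(p_low), "low")
  pol <- load_rulepack("pollution")
  # indoor PM10 at 100 ug/m3: below the 150 ug/m3 (0.150 mg/m3) base limit,
  # above the tightened 20 ug/m3 (0.020 mg/m3) limit after 8 h indoors
  n <- 700
  stream <- data.frame(timestamp = 1:n, activity_category = "sedentary",
                       location = "indoor", indoor_pm10 = 100)
  log <- evaluate_stream(p_low, stream, pol)
  dyn <- log[log$rule_id == "pm10_dynamic", ]
  expect_equal(nrow(dyn), 1)
  # limit flips at minute 480 of exposure; the violation then needs no window
  expect_equal(dyn$timestamp, 480)
  expect_equal(dyn$high, 20)   # converted to the sensor's ug/m3
  # without 8 h of accumulation no alarm is raised
  short <- data.frame(timestamp = 1:400, activity_category = "sedentary",
                      location = "indoor", indoor_pm10 = 100)
  log_s <- evaluate_stream(p_low, short, pol)
  expect_equal(nrow(log_s[log_s$rule_id == "pm10_dynamic", ]), 0)
})

test_that("altitude travel advisories follow the printed limits", {
  p <- table7_profile()
  # altitude above 1050 m alarms
  adv <- altitude_travel_check(p, 1200)
  expect_true(adv$alarm)
  # baseline FEV1 1.73 L >= 1.5: no prediction required
  expect_true(is.na(adv$predicted_pao2))
  # observed PaO2 below 50 mmHg: cannot travel
  adv2 <- altitude_travel_check(p, 900, observed_pao2 = 49)
  expect_true(adv2$cannot_travel)
  # SpO2 threshold drops to 84% under a walking test
  adv3 <- altitude_travel_check(p, 900, observed_spo2 = 88)
  expect_true(adv3$cannot_travel)
  adv4 <- altitude_travel_check(p, 900, observed_spo2 = 88, six_mwt = TRUE)
  expect_false(adv4$cannot_travel)
  # sea level at baseline: clear
  adv5 <- altitude_travel_check(p, 0)
  expect_false(adv5$alarm)
  # low-FEV1 profile gets the regression prediction
  p_iv <- stage_profile("IV")
  adv6 <- altitude_travel_check(p_iv, 1000)
  expect_equal(adv6$predicted_pao2,
               0.5196 * 60 + 11.856 * 0.7 - 1.76, tolerance = 1e-6)
  expect_true(adv6$cannot_travel)   # predicted PaO2 below 50
  # hypertension prevalence multiplier rides along
  expect_equal(adv$hypertension_multiplier, 1 + 0.02 * 12)
})

test_that("nutrient totals are checked against the activity pack", {
  expect_equal(nutrition_check(c(fructose = 30))$rule_id, "fructose_24h")
  expect_equal(nrow(nutrition_check(c(fiber = 20))), 0)
  expect_equal(nrow(nutrition_check(c(fructose = 20))), 0)
  expect_error(nutrition_check(c(fructose = -1)), "non-negative")
  # zero intake across the board: exactly the minimum-type rules fire
  pack <- load_rulepack("activity")
  nutrients <- c("sodium", "fructose", "glucose", "calcium", "vitamin_d",
                 "vitamin_c", "vitamin_a", "vitamin_e", "vitamin_b12",
                 "iron", "zinc", "magnesium", "carbohydrate", "protein",
                 "fat", "fiber")
  zero <- stats::setNames(rep(0, length(nutrients)), nutrients)
  fired <- nutrition_check(zero)$parameter
  # brute-force expectation from the pack itself
  expected <- vapply(pack$rules, function(r) {
    if (!r$parameter %in% nutrients) return(NA_character_)
    viol <- if (!is.null(r$band)) 0 < r$band[1] || 0 > r$band[2]
            else if (r$limit$direction == "below") 0 < r$limit$value
            else 0 > r$limit$value
    if (viol) r$parameter else NA_character_
  }, character(1))
  expect_setequal(fired, expected[!is.na(expected)])
  expect_true(all(c("calcium", "vitamin_d", "fiber") %in% fired))
})

test_that("risk-score totals map to the printed danger band", {
  expect_true(ottawa_risk(c(2, 2, 1))$dangerous)
  expect_equal(ottawa_risk(c(2, 2, 1))$total, 5)
  expect_false(ottawa_risk(numeric(0))$dangerous)
  expect_false(ottawa_risk(c(1, 1))$dangerous)
  expect_error(ottawa_risk(c(1, -1)), "non-negative")
  # boundary enumeration of totals 0..12
  for (total in 0:12) {
    r <- ottawa_risk(rep(1, total))
    expect_equal(r$dangerous, total >= 3 && total <= 9, info = total)
    expect_equal(r$band,
                 if (total > 9) "critical"
                 else if (total >= 3) "dangerous" else "low",
                 info = total)
  }
})
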