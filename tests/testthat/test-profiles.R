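test_that("profile construction validates fields and bands", {
  p <- table7_profile()
  expect_s3_class(p, "copd_profile")
  expect_equal(p$age, 51)
  expect_equal(p$gold_stage, "I")
  expect_equal(p$baselines[["pao2"]], 78)
  expect_equal(p$baselines[["fev1"]], 1.73)
  # BMI consistency within 0.5
  expect_error(
    patient_profile(id = "x", age = 50, gender = "male", height = 180,
                    weight = 80, bmi = 30, smoker = FALSE, gold_stage = "I",
                    baselines = table7_profile()$baselines),
    "inconsistent")
  # inverted band rejected
  expect_error(
    patient_profile(id = "x", age = 50, gender = "male", height = 180,
                    weight = 80, smoker = FALSE, gold_stage = "I",
                    baselines = table7_profile()$baselines,
                    activity_bands = data.frame(vital = "heart_rate",
                                                category = "light",
                                                low = 130, high = 110)),
    "inverted")
  # missing baseline vital rejected
  expect_error(
    patient_profile(id = "x", age = 50, gender = "male", height = 180,
                    weight = 80, smoker = FALSE, gold_stage = "I",
                    baselines = c(heart_rate = 70)),
    "missing baseline")
})

test_that("explicit per-activity bands are honoured, synthesized ones bracket baselines", {
  p <- table6_profile()
  b <- activity_band(p, "heart_rate", "light")
  expect_equal(c(b$low, b$high), c(60, 97))
  b <- activity_band(p, "spo2", "vigorous")
  expect_equal(c(b$low, b$high), c(91.30, 92.6))
  # sedentary band contains the baseline for every vital, every profile
  for (prof in list(p, table7_profile(), stage_profile("IV"))) {
    for (v in vital_names()) {
      sed <- activity_band(prof, v, "sedentary")
      expect_true(in_band(sed, prof$baselines[[v]]),
                  info = paste(prof$id, v))
    }
  }
  # all bands well-ordered
  for (key in names(p$activity_bands)) {
    b <- p$activity_bands[[key]]
    expect_lte(b$low, b$high)
  }
  expect_error(activity_band(p, "nonsense", "light"), "unknown vital")
})

test_that("severity grouping is deterministic and monotone", {
  expect_equal(severity_group(stage_profile("I")), "low")
  expect_equal(severity_group(stage_profile("I", comorbidities = "CHF")),
               "moderate")
  expect_equal(severity_group(stage_profile("I", age = 70)), "moderate")
  expect_equal(severity_group(stage_profile("III")), "high")
  expect_equal(severity_group(stage_profile("III", comorbidities = "HBP")),
               "very_high")
  expect_equal(severity_group(stage_profile("IV")), "very_high")
  expect_equal(severity_group(stage_profile("IV", comorbidities = "CHF")),
               "very_high")
  # same profile twice -> same level
  expect_identical(severity_group(table7_profile()),
                   severity_group(table7_profile()))
  # monotone over all stage x comorbidity-count combinations
  lv <- severity_levels()
  coms <- c("CHF", "HBP", "anemia", "IHD", "PH", "GERD", "asthma")
  for (age in c(50, 70)) {
    for (ncom in 0:3) {
      ranks <- vapply(c("I", "II", "III", "IV"), function(st)
        match(severity_group(stage_profile(st, age = age,
                                           comorbidities = head(coms, ncom))),
              lv), integer(1))
      expect_true(all(diff(ranks) >= 0), info = paste("age", age, "ncom", ncom))
    }
    for (st in c("I", "II", "III", "IV")) {
      ranks <- vapply(0:3, function(ncom)
        match(severity_group(stage_profile(st, age = age,
                                           comorbidities = head(coms, ncom))),
              lv), integer(1))
      expect_true(all(diff(ranks) >= 0), info = paste("age", age, "stage", st))
    }
  }
})

test_that("profile CSV and JSON round trips are lossless", {
  profs <- generate_profiles(50, seed = 421)
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_profiles(profs, path)
    back <- load_profiles(path)
    expect_length(back, 50)
    for (i in seq_along(profs)) {
      a <- profs[[i]]; b <- back[[i]]
      expect_equal(b$id, a$id)
      expect_equal(b$age, a$age)
      expect_equal(b$gender, a$gender)
      expect_equal(b$gold_stage, a$gold_stage)
      expect_equal(b$mmrc, a$mmrc)
      expect_equal(b$smoker, a$smoker)
      expect_equal(sort(b$comorbidities), sort(a$comorbidities))
      expect_equal(b$baselines, a$baselines, tolerance = 1e-8)
      for (key in names(a$activity_bands)) {
        expect_equal(b$activity_bands[[key]]$low, a$activity_bands[[key]]$low,
                     tolerance = 1e-8)
        expect_equal(b$activity_bands[[key]]$high,
                     a$activity_bands[[key]]$high, tolerance = 1e-8)
      }
    }
    unlink(path)
  }
})

test_that("profile loader reports schema and parse errors; header-only file loads empty", {
  profs <- generate_profiles(2, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_profiles(profs, path)
  df <- utils::read.csv(path, check.names = FALSE)
  # header-only file -> empty sequence
  utils::write.csv(df[0, ], path, row.names = FALSE)
  expect_length(load_profiles(path), 0)
  # missing mandatory column named in the error
  df2 <- df[, setdiff(names(df), "gold_stage")]
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(load_profiles(path), "gold_stage")
  # non-numeric vital names the row
  df3 <- df
  df3$baseline_heart_rate[1] <- "fast"
  utils::write.csv(df3, path, row.names = FALSE)
  expect_error(load_profiles(path), "P001")
  # unknown columns survive as extras
  df4 <- df
  df4$fef_25_75 <- c(0.4, 0.5)
  utils::write.csv(df4, path, row.names = FALSE)
  back <- load_profiles(path)
  expect_equal(back[[1]]$extras$fef_25_75, 0.4)
  unlink(path)
})
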