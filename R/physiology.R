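# Closed-form ambient-physiology equations: hypsometric pressure, gas partial
# pressures, the altitude arterial-oxygen regression, ambient-temperature
# effects on heart rate and blood pressure, cold-driven lung-function decline,
# and the reference resting-heart-rate model (stage x age grid + additive
# profile modifiers).

# Heart-rate reference grid (bpm): rows = GOLD stage, cols = age decade.
# Shipped as a versioned data file in inst/extdata/hr_reference.csv; the copy
# here is the compiled-in default (identical values).
.hr_age_breaks <- c(40, 50, 60, 70, 80, 90)
.hr_grid <- matrix(
  c(72.6, 69.2, 70.1, 68.70, 67.20,
    74.6, 72.3, 71.3, 70.3, 69.3,
    77.5, 75.2, 74.2, 73.6, 72.6,
    84.9, 82.2, 81.2, 80.2, 79.2),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("I", "II", "III", "IV"),
                  c("40-50", "50-60", "60-70", "70-80", "80-90"))
)
.hr_sd_grid <- matrix(
  c(12, 11, 8, 7, 9,
    13, 12, 11, 10, 12,
    13, 12, 11, 11, 10,
    14, 13, 12, 10, 11),
  nrow = 4, byrow = TRUE, dimnames = dimnames(.hr_grid)
)
# additive mean-change modifiers (bpm)
.hr_modifiers <- c(smoker = 6.6, obese = 9, inhaler = 7,
                   CHF = 9.6, anemia = 7, PH = 10, asthma = 8)
.hr_female_offset <- 3
# exercise-category reference means and spreads (bpm)
.hr_exercise_mean <- c(sedentary = 76.3, light = 85.5,
                       moderate = 125.6, vigorous = 145.3)
.hr_exercise_sd <- c(sedentary = 10, light = 15, moderate = 18, vigorous = 25)

#' Barometric pressure from altitude (hypsometric formula)
#'
#' P = 760 * (1 - altitude / constant)^5.255876, valid from sea level to
#' 11,000 m. The default constant 44330.76923 m reproduces textbook values
#' (about 670 mmHg at 1050 m) and gives exactly 760 mmHg at altitude 0.
#'
#' @param altitude Altitude in metres, within `[0, 11000]`.
#' @param constant Scale height constant in metres.
#' @return Pressure in mmHg.
#' @examples
#' barometric_pressure(0)     # 760
#' barometric_pressure(1050)  # ~670
#' @export
barometric_pressure <- function(altitude, constant = 44330.76923) {
  stopifnot(is.numeric(altitude))
  if (any(altitude < 0 | altitude > 11000)) {
    stop("altitude outside [0, 11000] m", call. = FALSE)
  }
  760 * (1 - altitude / constant)^5.255876
}

#' Partial pressures of atmospheric gases
#'
#' Ambient air is approximately 78% nitrogen, 21% oxygen and 0.038% carbon
#' dioxide; partial pressures scale linearly with total pressure. At the
#' standard 760 mmHg this gives 159.6 mmHg O2 and 592.8 mmHg N2 (160/593
#' when rounded).
#'
#' @param pressure Total barometric pressure in mmHg, positive.
#' @return Named list with `po2`, `pn2`, `pco2` (mmHg) and the input
#'   `pressure`.
#' @examples
#' partial_pressures(760)
#' @export
partial_pressures <- function(pressure) {
  stopifnot(is.numeric(pressure))
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  list(pressure = pressure,
       po2 = 0.21 * pressure,
       pn2 = 0.78 * pressure,
       pco2 = 0.00038 * pressure)
}

#' Atmosphere state at an altitude
#'
#' Convenience wrapper combining [barometric_pressure()] and
#' [partial_pressures()].
#'
#' @inheritParams barometric_pressure
#' @return Named list: `altitude`, `pressure`, `po2`, `pn2`, `pco2`.
#' @export
atmosphere_state <- function(altitude, constant = 44330.76923) {
  p <- barometric_pressure(altitude, constant)
  c(list(altitude = altitude), partial_pressures(p))
}

#' Predicted arterial oxygen pressure at altitude
#'
#' Regression estimate of PaO2 at high altitude for COPD patients from
#' sea-level PaO2 and FEV1:
#' `PaO2_alt = 0.5196 * PaO2_sea + 11.856 * FEV1 - 1.76`.
#' Intended for patients with baseline FEV1 below 1.5 L being assessed before
#' altitude travel.
#'
#' @param pao2_sea Sea-level arterial oxygen pressure, mmHg (positive).
#' @param fev1 Forced expiratory volume in one second, litres (non-negative).
#' @return Predicted PaO2 at altitude, mmHg.
#' @examples
#' pao2_at_altitude(78, 1.73)  # 59.28
#' @export
pao2_at_altitude <- function(pao2_sea, fev1) {
  stopifnot(is.numeric(pao2_sea), is.numeric(fev1))
  if (any(pao2_sea < 0) || any(fev1 < 0)) {
    stop("pao2_sea and fev1 must be non-negative", call. = FALSE)
  }
  0.5196 * pao2_sea + 11.856 * fev1 - 1.76
}

#' Ambient-temperature effects on heart rate and blood pressure
#'
#' Piecewise-linear increases in resting HR, SBP and DBP as the mean ambient
#' temperature departs from its comfort threshold (22 C for heart rate, 27 C
#' for blood pressure). Per degree below the threshold: +0.063 bpm HR,
#' +0.129 mmHg SBP, +0.065 mmHg DBP; per degree above: +0.133 bpm HR,
#' +0.605 mmHg SBP, +0.128 mmHg DBP. Deltas are always non-negative: both
#' cold and heat stress raise the vitals.
#'
#' @param mean_temp Mean ambient temperature in degrees C (finite, vectorised).
#' @return List of numeric vectors `d_hr` (bpm), `d_sbp`, `d_dbp` (mmHg).
#' @examples
#' temperature_vital_deltas(12)$d_hr   # 0.63
#' temperature_vital_deltas(28)$d_sbp  # 0.605
#' @export
temperature_vital_deltas <- function(mean_temp) {
  stopifnot(is.numeric(mean_temp), all(is.finite(mean_temp)))
  d_hr  <- ifelse(mean_temp < 22, 0.063 * (22 - mean_temp),
                  0.133 * (mean_temp - 22))
  d_sbp <- ifelse(mean_temp < 27, 0.129 * (27 - mean_temp),
                  0.605 * (mean_temp - 27))
  d_dbp <- ifelse(mean_temp < 27, 0.065 * (27 - mean_temp),
                  0.128 * (mean_temp - 27))
  list(d_hr = d_hr, d_sbp = d_sbp, d_dbp = d_dbp)
}

#' Cold-season decline in FEV1 (or FVC)
#'
#' Lung function falls linearly with outdoor temperature between warm and
#' cold periods, at 2.20 mL per degree C for FEV1 and 3.64 mL per degree C
#' for FVC.
#'
#' @param t_warm Warm-period mean temperature, degrees C.
#' @param t_cold Cold-period mean temperature, degrees C (`t_cold <= t_warm`).
#' @param measure `"fev1"` (slope 2.20 mL/C) or `"fvc"` (3.64 mL/C).
#' @return Decline in mL.
#' @examples
#' fev1_cold_decline(21.1, 0.78)  # 44.704
#' @export
fev1_cold_decline <- function(t_warm, t_cold, measure = c("fev1", "fvc")) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(t_warm), is.numeric(t_cold))
  if (any(t_warm < t_cold)) {
    stop("t_warm must be >= t_cold", call. = FALSE)
  }
  slope <- if (measure == "fev1") 2.20 else 3.64
  (t_warm - t_cold) * slope
}

# internal: reference resting HR components for a profile
hr_reference_cell <- function(gold_stage, age, gender) {
  age_c <- age
  warn <- NULL
  if (age_c < 40) { age_c <- 40; warn <- "below" }
  if (age_c > 90) { age_c <- 90; warn <- "above" }
  if (!is.null(warn)) {
    warning("age ", age, " outside reference range 40-90; clamped",
            call. = FALSE)
  }
  col <- findInterval(age_c, .hr_age_breaks, rightmost.closed = TRUE)
  col <- min(max(col, 1L), 5L)
  base <- .hr_grid[gold_stage, col]
  sd <- .hr_sd_grid[gold_stage, col]
  if (gender == "female") base <- base + .hr_female_offset
  list(base = base, sd = sd, col = col)
}

hr_profile_modifiers <- function(profile) {
  m <- 0
  if (profile$smoker) m <- m + .hr_modifiers[["smoker"]]
  if (profile$bmi >= 30) m <- m + .hr_modifiers[["obese"]]
  if (any(grepl("inhaler", profile$medications, ignore.case = TRUE))) {
    m <- m + .hr_modifiers[["inhaler"]]
  }
  for (cm in intersect(profile$comorbidities, c("CHF", "anemia", "PH", "asthma"))) {
    m <- m + .hr_modifiers[[cm]]
  }
  m
}

#' Expected resting (or per-activity) heart rate for a profile
#'
#' The reference model: a stage-by-age-decade grid of male resting heart
#' rates (stage I at 40-50 years is 72.6 bpm, rising to 84.9 bpm in stage
#' IV), an additive gender offset (+3 bpm for female profiles), and additive
#' modifiers for smoking (+6.6), obesity (BMI >= 30, +9), inhaler medication
#' (+7) and the heart-rate-associated comorbidities CHF (+9.6), anemia (+7),
#' PH (+10) and asthma (+8). For an exercise category the resting value is
#' replaced by the category's reference mean (sedentary 76.3, light 85.5,
#' moderate 125.6, vigorous 145.3 bpm) scaled by the ratio of the profile's
#' stage/age cell to the stage-I cell of the same age decade; modifiers stay
#' additive.
#'
#' @param profile A [patient_profile()].
#' @param category `"resting"` or one of [activity_categories()].
#' @return Expected heart rate in beats/min.
#' @export
expected_resting_hr <- function(profile, category = "resting") {
  stopifnot(inherits(profile, "copd_profile"))
  category <- match.arg(category, c("resting", .activity_categories))
  cell <- hr_reference_cell(profile$gold_stage, profile$age, profile$gender)
  mods <- hr_profile_modifiers(profile)
  if (category == "resting") return(cell$base + mods)
  stage1 <- .hr_grid["I", cell$col]
  if (profile$gender == "female") stage1 <- stage1 + .hr_female_offset
  .hr_exercise_mean[[category]] * (cell$base / stage1) + mods
}

# internal: spread (SD, bpm) to pair with expected_resting_hr
expected_hr_sd <- function(profile, category = "resting") {
  cell <- hr_reference_cell(profile$gold_stage, profile$age, profile$gender)
  if (category %in% c("resting", "sedentary")) return(cell$sd)
  .hr_exercise_sd[[category]]
}

#' Altitude-hypertension reporting multiplier
#'
#' Hypertension prevalence rises by 2% with every 100 m of altitude; the
#' multiplier `1 + 0.02 * altitude / 100` is attached to advisories (it does
#' not modify vitals).
#'
#' @param altitude Altitude in metres (non-negative).
#' @return Prevalence multiplier (1 at sea level).
#' @export
hypertension_altitude_multiplier <- function(altitude) {
  stopifnot(is.numeric(altitude))
  if (any(altitude < 0)) stop("altitude must be non-negative", call. = FALSE)
  1 + 0.02 * altitude / 100
}
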