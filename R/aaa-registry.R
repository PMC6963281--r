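# Canonical parameter registry: every parameter a rule may reference, with its
# fixed unit. Units are fixed per parameter and validated on load; there is no
# unit inference. Rules may declare a different unit for their limits (e.g. a
# particulate limit printed in mg/m3 against a ug/m3 sensor field); conversion
# factors between compatible units are listed in `.unit_conversions`.

.vital_names <- c(
  "temperature", "dbp", "sbp", "heart_rate", "pao2", "spo2", "paco2",
  "vo2", "respiration_rate", "ph", "hco3", "fev1"
)

.parameter_units <- c(
  # vitals
  temperature        = "degC",
  dbp                = "mmHg",
  sbp                = "mmHg",
  heart_rate         = "bpm",
  pao2               = "mmHg",
  spo2               = "%",
  paco2              = "mmHg",
  vo2                = "mL/kg/min",
  respiration_rate   = "breaths/min",
  ph                 = "pH",
  hco3               = "mmol/L",
  fev1               = "L",
  # indoor environment
  indoor_temperature = "degC",
  indoor_humidity    = "%",
  indoor_pressure    = "hPa",
  co2                = "ppm",
  voc                = "ppm",
  indoor_pm25        = "ug/m3",
  indoor_pm10        = "ug/m3",
  co                 = "ppm",
  hcho               = "ppm",
  tvoc               = "ppm",
  o3_indoor          = "ppm",
  bacteria           = "CFU/m3",
  fungi              = "CFU/m3",
  no2_indoor         = "ppm",
  so2_indoor         = "ppm",
  h2s_indoor         = "ppm",
  no_indoor          = "ppm",
  nox_indoor         = "ppm",
  trs_indoor         = "ppm",
  # outdoor environment
  outdoor_temperature = "degC",
  outdoor_humidity    = "%",
  wind_speed          = "mph",
  wind_direction      = "deg",
  precipitation       = "mm",
  snowfall            = "mm",
  outdoor_pressure    = "kPa",
  aqhi                = "index",
  co_out              = "ppm",
  h2s                 = "ppb",
  no                  = "ppb",
  no2                 = "ppb",
  nox                 = "ppb",
  o3                  = "ppb",
  pm10                = "ug/m3",
  pm25                = "ug/m3",
  so2                 = "ppb",
  trs                 = "ppb",
  # contextual / activity-level parameters
  altitude            = "m",
  activity_duration   = "min",
  # nutrient daily totals (24 h windows)
  sodium              = "mg",
  fructose            = "g",
  glucose             = "mg",
  calcium             = "mg",
  vitamin_d           = "IU",
  vitamin_c           = "mg",
  vitamin_a           = "mcg",
  vitamin_e           = "IU",
  vitamin_b12         = "mcg",
  iron                = "mg",
  zinc                = "mg",
  magnesium           = "mg",
  carbohydrate        = "g",
  protein             = "g",
  fat                 = "g",
  fiber               = "g"
)

# multiplicative factors: value[from -> to] (canonical unit on the right)
.unit_conversions <- list(
  "mg/m3->ug/m3" = 1000,
  "ug/m3->mg/m3" = 0.001,
  "cm->mm"       = 10,
  "hPa->kPa"     = 0.1,
  "kPa->hPa"     = 10
)

#' Canonical unit of a monitored parameter
#'
#' @param parameter Parameter name (snake_case, e.g. `"heart_rate"`,
#'   `"indoor_pm10"`).
#' @return The unit string registered for the parameter.
#' @examples
#' parameter_unit("heart_rate")
#' @export
parameter_unit <- function(parameter) {
  stopifnot(is.character(parameter), length(parameter) == 1L)
  if (!parameter %in% names(.parameter_units)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  unname(.parameter_units[[parameter]])
}

# Convert a numeric limit from `from` unit to `to` unit; identity if equal,
# error when no conversion is registered.
convert_unit <- function(x, from, to) {
  if (identical(from, to)) return(x)
  key <- paste0(from, "->", to)
  f <- .unit_conversions[[key]]
  if (is.null(f)) {
    stop("no unit conversion registered from '", from, "' to '", to, "'",
         call. = FALSE)
  }
  x * f
}

#' Names of the monitored vital signs
#'
#' The eleven continuously monitored vitals plus FEV1.
#'
#' @return Character vector of canonical vital names.
#' @export
vital_names <- function() .vital_names
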