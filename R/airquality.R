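# Indoor air quality indices.
#
# Two composite indices run in opposite directions: a 0-100 comfort index
# (higher = better, categorised good/normal/unhealthy/hazardous) and an
# EPA-AQI-style index (higher = worse, health-protection threshold 150 for
# respiratory patients). Neither source prints a sub-index formula, so both
# are EPA-style piecewise-linear interpolations anchored on the shipped
# per-pollutant alarm limits: the limit maps to comfort score 50 (the
# unhealthy boundary) / AQI 100, twice the limit to comfort 25 / AQI 200.
# The combination rule is stringent: worst sub-index wins on both scales.

.iaqi_categories <- c("good", "normal", "unhealthy", "hazardous")

# Default alarm limits per indoor pollutant (canonical units, see units.R).
# These anchor both index interpolations.
.iaqi_limits <- c(
  pm10 = 60, pm25 = 45, o3 = 0.03, co = 2, co2 = 600, hcho = 0.04,
  tvoc = 0.9, bacteria = 600, fungi = 500, no2 = 5, so2 = 0.06,
  h2s = 1, no = 25, nox = 10, trs = 10
)

#' Default indoor-pollutant breakpoint table
#'
#' One row per pollutant with the interpolation nodes used by
#' [saad_subindex()] and [iaqi()]: clean air (score 100), the alarm limit
#' (score 50, the unhealthy boundary), twice the limit (score 25, the
#' hazardous boundary) and three times the limit (score 0).
#'
#' @return Data frame with columns `pollutant`, `limit`, `hazardous_node`.
#' @export
iaqi_breakpoints <- function() {
  data.frame(pollutant = names(.iaqi_limits),
             limit = unname(.iaqi_limits),
             hazardous_node = 2 * unname(.iaqi_limits),
             stringsAsFactors = FALSE)
}

#' A pollutant reading
#'
#' @param name Pollutant name (lower case, e.g. `"pm10"`, `"co"`,
#'   `"bacteria"`). Must have a registered breakpoint.
#' @param concentration Non-negative concentration in the pollutant's
#'   canonical unit.
#' @return Object of class `pollutant_reading`.
#' @export
pollutant_reading <- function(name, concentration) {
  name <- tolower(name)
  if (!name %in% names(.iaqi_limits)) {
    stop("unknown pollutant: ", name, call. = FALSE)
  }
  stopifnot(is.numeric(concentration), length(concentration) == 1L)
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  structure(list(name = name, concentration = concentration),
            class = "pollutant_reading")
}

#' Comfort-scale sub-index (0-100, higher = better) for one pollutant
#'
#' Piecewise-linear interpolation through (0, 100), (limit, 50),
#' (2 x limit, 25), (3 x limit, 0), clamped to `[0, 100]`. Monotone
#' non-increasing in concentration; the alarm limit itself scores exactly 50.
#'
#' @param reading A [pollutant_reading()] (or pollutant name, with
#'   `concentration` supplied).
#' @param concentration Concentration when `reading` is a name.
#' @param breakpoints Breakpoint table as from [iaqi_breakpoints()].
#' @return Score in `[0, 100]`.
#' @examples
#' saad_subindex("pm10", 0)    # 100
#' saad_subindex("pm10", 60)   # 50
#' @export
saad_subindex <- function(reading, concentration = NULL,
                          breakpoints = iaqi_breakpoints()) {
  if (is.character(reading)) reading <- pollutant_reading(reading, concentration)
  stopifnot(inherits(reading, "pollutant_reading"))
  bp <- breakpoints[breakpoints$pollutant == reading$name, , drop = FALSE]
  if (nrow(bp) != 1L) {
    stop("no breakpoints for pollutant: ", reading$name, call. = FALSE)
  }
  L <- bp$limit
  H <- bp$hazardous_node
  x <- reading$concentration
  nodes_x <- c(0, L, H, H + (H - L))
  nodes_y <- c(100, 50, 25, 0)
  if (x >= nodes_x[4]) return(0)
  i <- findInterval(x, nodes_x)
  y <- nodes_y[i] + (nodes_y[i + 1] - nodes_y[i]) *
    (x - nodes_x[i]) / (nodes_x[i + 1] - nodes_x[i])
  min(max(y, 0), 100)
}

# EPA-style sub-index (higher = worse): limit -> 100, 2x limit -> 200,
# linear throughout (equivalent to 100 * concentration / limit).
aqi_subindex <- function(reading, breakpoints = iaqi_breakpoints()) {
  stopifnot(inherits(reading, "pollutant_reading"))
  bp <- breakpoints[breakpoints$pollutant == reading$name, , drop = FALSE]
  if (nrow(bp) != 1L) {
    stop("no breakpoints for pollutant: ", reading$name, call. = FALSE)
  }
  100 * reading$concentration / bp$limit
}

#' Categorise a comfort-scale index value
#'
#' Exact closed ranges: good 100-76, normal 75-51, unhealthy 50-26,
#' hazardous 25-0. A boundary value belongs to the better category's stated
#' range (76 is good, 51 normal, 26 unhealthy).
#'
#' @param saad_index Index in `[0, 100]`.
#' @return One of `"good"`, `"normal"`, `"unhealthy"`, `"hazardous"`.
#' @examples
#' categorize_iaqi(80)  # good
#' categorize_iaqi(51)  # normal
#' @export
categorize_iaqi <- function(saad_index) {
  stopifnot(is.numeric(saad_index), length(saad_index) == 1L)
  if (!is.finite(saad_index) || saad_index < 0 || saad_index > 100) {
    stop("index outside [0, 100]", call. = FALSE)
  }
  if (saad_index >= 76) "good"
  else if (saad_index >= 51) "normal"
  else if (saad_index >= 26) "unhealthy"
  else "hazardous"
}

#' Combined indoor air quality assessment
#'
#' Applies the stringent combination rule over a set of pollutant readings:
#' the comfort index is the minimum (worst) comfort sub-index, the AQI-style
#' index the maximum (worst) sub-index. The alarm is raised when the comfort
#' category is worse than `normal` or the AQI-style index exceeds the
#' 150-point health-protection threshold for respiratory patients.
#'
#' @param readings List of [pollutant_reading()]s, or a named numeric vector
#'   of concentrations.
#' @param breakpoints Breakpoint table as from [iaqi_breakpoints()].
#' @param aqi_threshold Health-protection threshold on the AQI scale.
#' @return Object of class `iaqi_result`: `saad_index`, `saad_category`,
#'   `aqi_index`, `alarm`, and the per-pollutant `subindices` data frame.
#' @examples
#' iaqi(c(pm10 = 10, co = 0.4))
#' @export
iaqi <- function(readings, breakpoints = iaqi_breakpoints(),
                 aqi_threshold = 150) {
  if (is.numeric(readings) && !is.null(names(readings))) {
    readings <- Map(pollutant_reading, names(readings), readings)
  }
  if (length(readings) == 0L) {
    stop("iaqi requires at least one pollutant reading", call. = FALSE)
  }
  stopifnot(all(vapply(readings, inherits, logical(1), "pollutant_reading")))
  sub <- data.frame(
    pollutant = vapply(readings, `[[`, character(1), "name"),
    concentration = vapply(readings, `[[`, numeric(1), "concentration"),
    saad = vapply(readings, saad_subindex, numeric(1),
                  breakpoints = breakpoints),
    aqi = vapply(readings, aqi_subindex, numeric(1),
                 breakpoints = breakpoints),
    stringsAsFactors = FALSE
  )
  saad_index <- min(sub$saad)
  aqi_index <- max(sub$aqi)
  cat_ <- categorize_iaqi(saad_index)
  alarm <- cat_ %in% c("unhealthy", "hazardous") || aqi_index > aqi_threshold
  structure(list(saad_index = saad_index, saad_category = cat_,
                 aqi_index = aqi_index, alarm = alarm, subindices = sub),
            class = "iaqi_result")
}

#' @export
print.iaqi_result <- function(x, ...) {
  cat(sprintf("indoor air quality: %.1f (%s); AQI-style %.1f; alarm: %s\n",
              x$saad_index, x$saad_category, x$aqi_index, x$alarm))
  worst <- x$subindices[which.min(x$subindices$saad), ]
  cat(sprintf("  limiting pollutant: %s at %g\n",
              worst$pollutant, worst$concentration))
  invisible(x)
}

#' Suggestion text for an air-quality category
#'
#' @param category One of the four index categories.
#' @return Advisory string for the patient.
#' @export
iaqi_suggestion <- function(category) {
  category <- match.arg(category, .iaqi_categories)
  switch(category,
    good = "Air quality is good; no action needed.",
    normal = "Air quality acceptable; sensitive patients should limit prolonged exertion indoors.",
    unhealthy = "Unhealthy indoor air: ventilate or filter the room and avoid exertion.",
    hazardous = "Hazardous indoor air: leave the room and alert the caregiver."
  )
}
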