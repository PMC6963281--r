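# Environmental time-series generator: per-minute indoor and outdoor
# conditions from seasonal mean-reverting (AR(1)/Ornstein-Uhlenbeck) noise
# processes around configurable seasonal means, plus episodic precipitation
# and pollution events. Field names and units follow the canonical parameter
# registry (units.R).

# default seasonal process configuration: mean, annual amplitude (peak in
# mid-July), diurnal amplitude (peak mid-afternoon), reversion rate theta,
# per-step noise sd, floor/ceiling
default_season_profile <- function() {
  ou <- function(mean, annual = 0, diurnal = 0, theta = 0.02, sigma = NULL,
                 lo = -Inf, hi = Inf) {
    if (is.null(sigma)) sigma <- 0.05 * abs(mean) * sqrt(2 * theta)
    list(mean = mean, annual = annual, diurnal = diurnal, theta = theta,
         sigma = sigma, lo = lo, hi = hi)
  }
  list(
    outdoor_temperature = ou(8, annual = 12, diurnal = 4, sigma = 0.15),
    outdoor_humidity    = ou(70, annual = -8, diurnal = -5, sigma = 0.5,
                             lo = 5, hi = 100),
    wind_speed          = ou(5, annual = 1, diurnal = 1.5, sigma = 0.3,
                             lo = 0),
    outdoor_pressure    = ou(101.6, annual = 0.3, theta = 0.01,
                             sigma = 0.02),
    aqhi                = ou(2.5, lo = 0.5),
    co_out              = ou(0.14, lo = 0),
    h2s                 = ou(0.2, lo = 0),
    no                  = ou(0.5, lo = 0),
    no2                 = ou(1.5, lo = 0),
    nox                 = ou(2.0, lo = 0),
    o3                  = ou(35, annual = 6, lo = 0),
    pm10                = ou(25, lo = 0),
    pm25                = ou(4, lo = 0),
    so2                 = ou(0.12, lo = 0),
    trs                 = ou(0.4, lo = 0),
    indoor_temperature  = ou(21, annual = 1, diurnal = 0.8, theta = 0.05,
                             sigma = 0.05),
    indoor_humidity     = ou(40, annual = 3, sigma = 0.3, lo = 5, hi = 95),
    indoor_pressure     = ou(1015.5, annual = 1, theta = 0.01, sigma = 0.02),
    co2                 = ou(680, diurnal = 40, lo = 350),
    voc                 = ou(0.062, lo = 0),
    indoor_pm25         = ou(8, lo = 0),
    indoor_pm10         = ou(9, lo = 0)
  )
}

# AR(1) with time-varying mean: x_t = (1-theta) x_{t-1} + theta mu_t + eps_t
ou_series <- function(n, cfg, minute_of_year) {
  doy <- minute_of_year / .minutes_per_day
  mod <- minute_of_year %% .minutes_per_day
  mu <- cfg$mean +
    cfg$annual * cos(2 * pi * (doy - 196) / 365.25) +
    cfg$diurnal * cos(2 * pi * (mod - 15 * 60) / .minutes_per_day)
  innov <- cfg$theta * mu + stats::rnorm(n, 0, cfg$sigma)
  x <- stats::filter(innov, 1 - cfg$theta, method = "recursive",
                     init = mu[1])
  pmin(pmax(as.numeric(x), cfg$lo), cfg$hi)
}

# two-state (dry/wet) episode indicator
episode_state <- function(n, p_start, p_stay) {
  u <- stats::runif(n)
  state <- logical(n)
  s <- FALSE
  for (i in seq_len(n)) {
    s <- if (s) u[i] < p_stay else u[i] < p_start
    state[i] <- s
  }
  state
}

#' Generate indoor and outdoor environmental series
#'
#' Per-minute environmental records over `days` days: outdoor weather
#' (temperature, humidity, wind speed/direction, precipitation, snowfall,
#' barometric pressure), outdoor air quality (AQHI, CO, H2S, NO, NO2, NOx,
#' O3, PM10, PM2.5, SO2, TRS) and indoor conditions (temperature, humidity,
#' pressure, CO2, VOC, PM2.5, PM10). Each continuous field follows a
#' mean-reverting noise process around a seasonal (annual + diurnal) mean;
#' precipitation is episodic, turning into snowfall below freezing, and
#' outdoor pollutants are scaled up during episodic pollution events. The
#' same seed reproduces the same series.
#'
#' @param days Number of days (>= 1).
#' @param season_profile Process configuration; see the package source for
#'   the default field set.
#' @param seed Optional integer seed.
#' @param start Start timestamp (POSIXct, minute 0 of day 1).
#' @return Data frame with `timestamp` and one column per field, one row
#'   per minute.
#' @export
generate_environment <- function(days,
                                 season_profile = default_season_profile(),
                                 seed = NULL,
                                 start = as.POSIXct("2024-01-01 00:00:00",
                                                    tz = "UTC")) {
  stopifnot(is.numeric(days), days >= 1)
  days <- as.integer(days)
  if (!is.null(seed)) set.seed(seed)
  n <- days * .minutes_per_day
  start_doy_min <- (as.integer(format(start, "%j")) - 1L) * .minutes_per_day +
    as.integer(format(start, "%H")) * 60L + as.integer(format(start, "%M"))
  moy <- start_doy_min + seq_len(n) - 1L
  out <- list(timestamp = start + 60 * (seq_len(n) - 1L))
  for (field in names(season_profile)) {
    out[[field]] <- ou_series(n, season_profile[[field]], moy)
  }
  # wind direction: slow random walk on the circle
  out$wind_direction <- (cumsum(stats::rnorm(n, 0, 2)) +
                           stats::runif(1, 0, 360)) %% 360
  # precipitation: episodic wet spells; snow when below freezing
  wet <- episode_state(n, p_start = 8e-4, p_stay = 0.995)
  rate <- stats::rexp(n, 1 / 0.05) * wet
  freezing <- out$outdoor_temperature < 0
  out$precipitation <- ifelse(freezing, 0, rate)
  out$snowfall <- ifelse(freezing, rate * 7, 0)
  # pollution episodes scale the outdoor pollutant block
  smog <- episode_state(n, p_start = 5e-5, p_stay = 0.998)
  boost <- 1 + smog * stats::runif(n, 4, 12)
  for (field in c("co_out", "no", "no2", "nox", "pm10", "pm25", "so2",
                  "h2s", "trs")) {
    out[[field]] <- out[[field]] * boost
  }
  out$aqhi <- pmin(out$aqhi * (1 + smog * 2), 10)
  as.data.frame(out, stringsAsFactors = FALSE)
}
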