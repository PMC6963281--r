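# Stateful forward evaluation of rulepacks over per-minute observation
# streams: band checks, temporal exposure windows, exposure-dependent
# dynamic thresholds, and alarm emission with de-duplication.
#
# Firing semantics: a rule with exposure window W fires when its continuous
# violation has lasted W + 1 minutes (i.e. the violation EXCEEDS the printed
# exposure limit; a "1 h" limit fires on the 61st consecutive violating
# minute). Rules without a window are W = 0 and fire on the first violating
# minute. After firing, a rule re-arms only once it has been compliant for
# `refractory` consecutive minutes (default 5), suppressing per-minute
# repeats. A missing sensor value freezes the rule: no alarm, accumulator
# unchanged.

.minutes_per_day <- 1440L

# minute index from a timestamp (POSIXct or plain numeric minutes)
minute_index <- function(timestamp) {
  if (inherits(timestamp, "POSIXt")) {
    as.numeric(timestamp) %/% 60
  } else {
    as.numeric(timestamp)
  }
}

season_of <- function(timestamp) {
  if (!inherits(timestamp, "POSIXt")) return(NA_character_)
  m <- as.integer(format(timestamp, "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

# six 4-hour dayparts starting 06:00 (1 = 06:00-10:00, ..., 6 = 02:00-06:00)
daypart_of <- function(timestamp) {
  hour <- if (inherits(timestamp, "POSIXt")) {
    as.integer(format(timestamp, "%H"))
  } else {
    (as.numeric(timestamp) %/% 60) %% 24
  }
  ((hour - 6) %% 24) %/% 4 + 1
}

# ---------------------------------------------------------------------------
# rule preparation: flatten packs into a uniform structure with canonical
# units, once per stream

prepare_rules <- function(packs, profile) {
  if (inherits(packs, "copd_rulepack")) packs <- list(packs)
  sev <- severity_group(profile)
  out <- list()
  for (pack in packs) {
    stopifnot(inherits(pack, "copd_rulepack"))
    for (r in pack$rules) {
      if (!identical(r$severity, "all") && !sev %in% r$severity) next
      canon <- parameter_unit(r$parameter)
      pr <- list(
        id = r$id, category = r$category, parameter = r$parameter,
        suggestion = r$suggestion,
        window = if (is.null(r$exposure_window)) 0 else r$exposure_window,
        ctx_activity = r$context$activity, ctx_location = r$context$location,
        ctx_season = r$context$season, ctx_daypart = r$context$daypart,
        ctx_when = r$context$when,
        dynamic = r$dynamic, unit = r$unit, canon_unit = canon
      )
      if (!is.null(r$band)) {
        pr$low <- convert_unit(r$band[1], r$unit, canon)
        pr$high <- convert_unit(r$band[2], r$unit, canon)
        pr$direction <- "band"
      } else {
        pr$direction <- r$limit$direction
        pr$limit_value <- convert_unit(r$limit$value, r$unit, canon)
        if (pr$direction == "above") {
          pr$low <- -Inf; pr$high <- pr$limit_value
        } else {
          pr$low <- pr$limit_value; pr$high <- Inf
        }
      }
      out[[length(out) + 1L]] <- pr
    }
  }
  out
}

#' Fresh exposure state for a monitoring session
#'
#' Holds, per rule, the continuous-violation accumulator, the re-arm
#' (de-duplication) counter, and the rolling context-exposure history used by
#' dynamic thresholds.
#'
#' @param profile A [patient_profile()].
#' @param packs A `copd_rulepack` or list of packs.
#' @param refractory Compliant minutes required before a fired rule re-arms.
#' @return An environment of class `exposure_state`.
#' @export
new_exposure_state <- function(profile, packs, refractory = 5) {
  rules <- prepare_rules(packs, profile)
  n <- length(rules)
  st <- new.env(parent = emptyenv())
  st$rules <- rules
  st$profile_id <- profile$id
  st$refractory <- refractory
  st$n <- n
  st$viol <- numeric(n)
  st$clear <- rep(refractory, n)   # start armed
  st$armed <- rep(TRUE, n)
  st$ctx_hist <- vector("list", n) # minute indices of context match (dynamic)
  st$last <- -Inf
  class(st) <- c("exposure_state", "environment")
  st
}

# context predicate for one rule against one record (list of fields)
rule_context_matches <- function(pr, rec, season, daypart) {
  if (!is.null(pr$ctx_activity) &&
      !identical(rec$activity_category, pr$ctx_activity)) return(FALSE)
  if (!is.null(pr$ctx_location)) {
    loc <- rec$location
    if (is.null(loc) || is.na(loc)) return(FALSE)
    ok <- if (pr$ctx_location == "indoor") {
      loc %in% c("indoor", "bedroom", "living_room")
    } else {
      identical(loc, pr$ctx_location)
    }
    if (!ok) return(FALSE)
  }
  if (!is.null(pr$ctx_season) &&
      (is.na(season) || !identical(season, pr$ctx_season))) return(FALSE)
  if (!is.null(pr$ctx_daypart) && daypart != pr$ctx_daypart) return(FALSE)
  if (!is.null(pr$ctx_when)) {
    for (cond in pr$ctx_when) {
      v <- rec[[cond$parameter]]
      if (is.null(v) || is.na(v)) return(FALSE)
      lo <- if (is.null(cond$min)) -Inf else cond$min
      hi <- if (is.null(cond$max)) Inf else cond$max
      if (v < lo || v > hi) return(FALSE)
    }
  }
  TRUE
}

#' Exposure-dependent effective limit of a rule
#'
#' For a rule carrying a dynamic schedule, returns the limit of the step
#' whose exposure node is the largest not exceeding `exposure_minutes`
#' (provided the severity group is one the schedule applies to); static rules
#' return their printed band/limit unchanged. For an upper ("above") limit
#' the effective limit is non-increasing in exposure.
#'
#' @param rule A [rule()].
#' @param severity A severity level (see [severity_levels()]).
#' @param exposure_minutes Accumulated context exposure in minutes.
#' @return For limit rules, `list(direction, value, unit)`; for band rules,
#'   `list(low, high, unit)`. Values are in the rule's declared unit.
#' @examples
#' pm10 <- Filter(function(r) r$id == "pm10_dynamic",
#'                load_rulepack("pollution")$rules)[[1]]
#' dynamic_threshold(pm10, "low", 540)$value  # 0.020
#' @export
dynamic_threshold <- function(rule, severity, exposure_minutes) {
  stopifnot(inherits(rule, "copd_rule"))
  severity <- match.arg(severity, .severity_levels)
  applicable <- identical(rule$severity, "all") || severity %in% rule$severity
  if (is.null(rule$band)) {
    value <- rule$limit$value
    if (!is.null(rule$dynamic) && applicable) {
      exposures <- vapply(rule$dynamic, `[[`, numeric(1), "exposure")
      i <- findInterval(exposure_minutes, exposures)
      if (i >= 1L) value <- rule$dynamic[[i]]$limit
    }
    list(direction = rule$limit$direction, value = value, unit = rule$unit)
  } else {
    list(low = rule$band[1], high = rule$band[2], unit = rule$unit)
  }
}

empty_alarms <- function() {
  data.frame(timestamp = numeric(), category = character(),
             parameter = character(), value = numeric(), low = numeric(),
             high = numeric(), rule_id = character(),
             suggestion = character(), stringsAsFactors = FALSE)
}

# single-minute engine step over prepared rules; mutates state, returns a
# list of alarm rows (possibly empty)
engine_step <- function(st, rec, t, season, daypart) {
  alarms <- list()
  for (k in seq_len(st$n)) {
    pr <- st$rules[[k]]
    value <- rec[[pr$parameter]]
    matches <- rule_context_matches(pr, rec, season, daypart)
    # rolling context exposure for dynamic rules (trailing 24 h, incl. now)
    low <- pr$low; high <- pr$high
    if (!is.null(pr$dynamic)) {
      hist <- st$ctx_hist[[k]]
      if (matches) hist <- c(hist, t)
      hist <- hist[hist > t - .minutes_per_day]
      st$ctx_hist[[k]] <- hist
      exposures <- vapply(pr$dynamic, `[[`, numeric(1), "exposure")
      i <- findInterval(length(hist), exposures)
      if (i >= 1L) {
        lim <- convert_unit(pr$dynamic[[i]]$limit, pr$unit, pr$canon_unit)
        if (pr$direction == "above") high <- lim else low <- lim
      }
    }
    if (!matches) {
      # not applicable: counts as a compliant minute
      st$viol[k] <- 0
      st$clear[k] <- st$clear[k] + 1
      if (st$clear[k] >= st$refractory) st$armed[k] <- TRUE
      next
    }
    if (is.null(value) || is.na(value)) next  # frozen
    violated <- value < low || value > high
    if (violated) {
      st$viol[k] <- st$viol[k] + 1
      st$clear[k] <- 0
      if (st$armed[k] && st$viol[k] >= pr$window + 1) {
        st$armed[k] <- FALSE
        alarms[[length(alarms) + 1L]] <- data.frame(
          timestamp = t, category = pr$category, parameter = pr$parameter,
          value = value, low = low, high = high, rule_id = pr$id,
          suggestion = pr$suggestion, stringsAsFactors = FALSE)
      }
    } else {
      st$viol[k] <- 0
      st$clear[k] <- st$clear[k] + 1
      if (st$clear[k] >= st$refractory) st$armed[k] <- TRUE
    }
  }
  alarms
}

as_record_list <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  record
}

#' Evaluate one observation minute against the rulepacks
#'
#' Advances the exposure state by one per-minute record and returns any
#' alarms fired at that minute. Records must arrive in strictly increasing
#' time order.
#'
#' @param profile A [patient_profile()].
#' @param record One joined observation: a one-row data frame or named list
#'   with `timestamp`, `activity_category`, `location`, and parameter fields
#'   (vitals and environment, canonical units).
#' @param state An `exposure_state` from [new_exposure_state()], or `NULL`
#'   to start a session.
#' @param packs A `copd_rulepack` or list of packs (used when `state` is
#'   `NULL`).
#' @param refractory Compliant minutes before a fired rule re-arms.
#' @return List with `alarms` (data frame, possibly empty) and `state`.
#' @export
evaluate_minute <- function(profile, record, state = NULL, packs = NULL,
                            refractory = 5) {
  if (is.null(state)) {
    if (is.null(packs)) stop("either state or packs must be given",
                             call. = FALSE)
    state <- new_exposure_state(profile, packs, refractory)
  }
  stopifnot(inherits(state, "exposure_state"))
  rec <- as_record_list(record)
  t <- minute_index(rec$timestamp)
  if (t <= state$last) {
    stop(sprintf("out-of-order timestamp: minute %g after %g", t, state$last),
         call. = FALSE)
  }
  season <- season_of(rec$timestamp)
  daypart <- daypart_of(rec$timestamp)
  rows <- engine_step(state, rec, t, season, daypart)
  state$last <- t
  alarms <- if (length(rows)) do.call(rbind, rows) else empty_alarms()
  list(alarms = alarms, state = state)
}

#' Evaluate a per-minute observation stream
#'
#' Streams a data frame of joined per-minute records through the engine and
#' collects the alarm log. Identical stream and state give an identical log.
#'
#' @param profile A [patient_profile()].
#' @param records Data frame, one row per minute, strictly increasing
#'   `timestamp`.
#' @param packs A `copd_rulepack` or list of packs.
#' @param refractory Compliant minutes before a fired rule re-arms.
#' @param state Optional `exposure_state` to continue a session.
#' @return Alarm log: data frame with `timestamp`, `category`, `parameter`,
#'   `value`, `low`, `high`, `rule_id`, `suggestion`.
#' @export
evaluate_stream <- function(profile, records, packs, refractory = 5,
                            state = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(state)) state <- new_exposure_state(profile, packs, refractory)
  ts <- minute_index(records$timestamp)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing",
                               call. = FALSE)
  seasons <- season_of(records$timestamp)
  if (length(seasons) == 1L) seasons <- rep(seasons, nrow(records))
  dayparts <- daypart_of(records$timestamp)
  cols <- as.list(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- lapply(cols, `[[`, i)
    rows <- engine_step(state, rec, ts[i], seasons[i], dayparts[i])
    if (length(rows)) out <- c(out, rows)
  }
  state$last <- ts[length(ts)]
  if (length(out)) do.call(rbind, out) else empty_alarms()
}

#' Altitude travel advisory
#'
#' Pre-travel assessment combining the altitude rule (alarm above 1050 m)
#' with hypoxia checks: predicted PaO2 at altitude (computed from the
#' baseline PaO2 and FEV1 when baseline FEV1 is below 1.5 L), an observed or
#' predicted PaO2 under 50 mmHg, or an SpO2 under 92% (84% under a
#' six-minute-walk test) all advise against travel without supplemental
#' oxygen. The advisory also reports the altitude hypertension-prevalence
#' multiplier.
#'
#' @param profile A [patient_profile()] with PaO2, SpO2 and FEV1 baselines.
#' @param altitude Target altitude in metres.
#' @param observed_pao2,observed_spo2 Optional current measurements
#'   overriding the baselines.
#' @param six_mwt Was the SpO2 measured under a six-minute-walk test?
#' @return Object of class `copd_advisory`: `alarm`, `cannot_travel`,
#'   `predicted_pao2`, `hypertension_multiplier`, `messages`.
#' @export
altitude_travel_check <- function(profile, altitude, observed_pao2 = NULL,
                                  observed_spo2 = NULL, six_mwt = FALSE) {
  stopifnot(inherits(profile, "copd_profile"), is.numeric(altitude))
  fev1 <- profile$baselines[["fev1"]]
  pao2 <- if (!is.null(observed_pao2)) observed_pao2
          else profile$baselines[["pao2"]]
  spo2 <- if (!is.null(observed_spo2)) observed_spo2
          else profile$baselines[["spo2"]]
  predicted <- if (fev1 < 1.5) pao2_at_altitude(profile$baselines[["pao2"]],
                                                fev1) else NA_real_
  spo2_limit <- if (six_mwt) 84 else 92
  msgs <- character()
  eff_pao2 <- if (!is.na(predicted)) min(pao2, predicted) else pao2
  cannot_travel <- FALSE
  if (eff_pao2 < 50) {
    cannot_travel <- TRUE
    msgs <- c(msgs, sprintf(
      "PaO2 %.1f mmHg below 50: cannot travel without supplemental oxygen.",
      eff_pao2))
  }
  if (spo2 < spo2_limit) {
    cannot_travel <- TRUE
    msgs <- c(msgs, sprintf(
      "SpO2 %.1f%% below %g%%: cannot travel without supplemental oxygen.",
      spo2, spo2_limit))
  }
  alarm <- altitude > 1050 || cannot_travel
  if (altitude > 1050) {
    msgs <- c(msgs, sprintf("Altitude %g m exceeds the 1050 m safe limit.",
                            altitude))
  }
  if (!is.na(predicted)) {
    msgs <- c(msgs, sprintf("Predicted PaO2 at altitude: %.2f mmHg.",
                            predicted))
  }
  structure(list(altitude = altitude, alarm = alarm,
                 cannot_travel = cannot_travel, predicted_pao2 = predicted,
                 hypertension_multiplier =
                   hypertension_altitude_multiplier(max(altitude, 0)),
                 messages = msgs),
            class = "copd_advisory")
}

#' @export
print.copd_advisory <- function(x, ...) {
  cat(sprintf("<travel advisory> altitude %g m: %s\n", x$altitude,
              if (x$cannot_travel) "CANNOT TRAVEL"
              else if (x$alarm) "ALARM" else "clear"))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Check 24-hour nutrient totals against the activity rulepack
#'
#' One alarm per violated nutrient rule: upper limits alarm above the limit,
#' minimum rules below it, and band rules (fiber, vitamin D) outside the
#' band. Only nutrients present in `daily_totals` are evaluated.
#'
#' @param daily_totals Named numeric vector of nutrient amounts over 24 h
#'   (canonical units per nutrient; all non-negative).
#' @param pack Rulepack holding the nutrient rules (the shipped `activity`
#'   pack by default).
#' @return Alarm data frame as in [evaluate_stream()] (timestamp `NA`).
#' @examples
#' nutrition_check(c(fructose = 30, fiber = 20))
#' @export
nutrition_check <- function(daily_totals, pack = load_rulepack("activity")) {
  stopifnot(is.numeric(daily_totals), !is.null(names(daily_totals)))
  if (any(daily_totals < 0)) {
    stop("nutrient amounts must be non-negative", call. = FALSE)
  }
  rows <- list()
  for (r in pack$rules) {
    if (!r$parameter %in% names(daily_totals)) next
    v <- daily_totals[[r$parameter]]
    if (!is.null(r$band)) {
      low <- r$band[1]; high <- r$band[2]
    } else if (r$limit$direction == "above") {
      low <- -Inf; high <- r$limit$value
    } else {
      low <- r$limit$value; high <- Inf
    }
    if (v < low || v > high) {
      rows[[length(rows) + 1L]] <- data.frame(
        timestamp = NA_real_, category = r$category, parameter = r$parameter,
        value = v, low = low, high = high, rule_id = r$id,
        suggestion = r$suggestion, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_alarms()
}

#' Exacerbation risk from a symptom-score checklist
#'
#' Sums the item scores of a clinical risk checklist; a total between 3 and
#' 9 reflects a dangerous situation, totals above 9 map to the highest band.
#'
#' @param item_scores Non-negative integer item scores.
#' @return List: `total`, `dangerous` (total in 3..9), `band` (`"low"`,
#'   `"dangerous"` or `"critical"`).
#' @examples
#' ottawa_risk(c(2, 2, 1))  # total 5, dangerous
#' @export
ottawa_risk <- function(item_scores) {
  stopifnot(is.numeric(item_scores))
  if (any(item_scores < 0)) {
    stop("item scores must be non-negative", call. = FALSE)
  }
  total <- sum(item_scores)
  band <- if (total > 9) "critical" else if (total >= 3) "dangerous" else "low"
  list(total = total, dangerous = total >= 3 && total <= 9, band = band)
}
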