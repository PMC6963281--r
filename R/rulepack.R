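# Declarative rulepacks: safe bands / relational limits with context
# predicates, temporal exposure windows, severity applicability and optional
# exposure-dependent dynamic schedules. Four default packs ship with the
# package (vitals, pollution, weather, activity) encoding the printed alarm
# tables; packs are YAML key-value trees and round-trip losslessly.

.rule_categories <- c("vital", "pollution", "weather", "activity")
.locations <- c("bedroom", "living_room", "indoor", "outdoor")
.seasons <- c("winter", "spring", "summer", "autumn")

#' Construct a monitoring rule
#'
#' A rule alarms when its parameter leaves its safe band (`value < low` or
#' `value > high`) or crosses its relational limit (`above`: alarm when value
#' exceeds the limit; `below`: alarm when value falls under it). Exactly one
#' of `band` / `limit` must be given. A rule with an exposure window `W`
#' fires only once the violation has persisted for more than `W` minutes;
#' rules without a window fire immediately.
#'
#' @param id Unique rule identifier.
#' @param category One of `"vital"`, `"pollution"`, `"weather"`,
#'   `"activity"`.
#' @param parameter Registered parameter name (see [parameter_unit()]).
#' @param band Numeric `c(low, high)` safe band, or `NULL`.
#' @param limit List `list(direction = "above"|"below", value = <number>)`,
#'   or `NULL`.
#' @param context Optional context predicate: a list with any of `activity`
#'   (an activity category), `location` (bedroom / living_room / indoor /
#'   outdoor; `indoor` matches the two rooms as well), `season`, `daypart`
#'   (1-6), and `when` (a list of numeric side-conditions
#'   `list(parameter=, min=, max=)` on other observed fields).
#' @param exposure_window Minutes of continuous violation required before the
#'   rule fires; `NULL` for immediate rules.
#' @param severity Severity levels the rule applies to: `"all"` (default) or
#'   a subset of [severity_levels()].
#' @param dynamic Optional dynamic-threshold schedule: a list of steps
#'   `list(exposure = <minutes>, limit = <number>)` in increasing exposure
#'   order. The step with the largest exposure node not exceeding the
#'   accumulated context exposure supplies the effective limit.
#' @param unit Unit the rule's numbers are expressed in; defaults to the
#'   parameter's canonical unit. The engine converts when they differ.
#' @param suggestion Advisory text carried on emitted alarms.
#' @return Object of class `copd_rule`.
#' @export
rule <- function(id, category, parameter, band = NULL, limit = NULL,
                 context = NULL, exposure_window = NULL, severity = "all",
                 dynamic = NULL, unit = NULL, suggestion = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  category <- match.arg(category, .rule_categories)
  if (!parameter %in% names(.parameter_units)) {
    stop("rule '", id, "': unknown parameter '", parameter, "'",
         call. = FALSE)
  }
  if (is.null(band) == is.null(limit)) {
    stop("rule '", id, "': exactly one of band/limit must be given",
         call. = FALSE)
  }
  if (!is.null(band)) {
    band <- as.numeric(band)
    if (length(band) != 2L || any(!is.finite(band))) {
      stop("rule '", id, "': band must be c(low, high)", call. = FALSE)
    }
    if (band[1] > band[2]) {
      stop("rule '", id, "': invalid band, low > high", call. = FALSE)
    }
  }
  if (!is.null(limit)) {
    if (!is.list(limit) || !all(c("direction", "value") %in% names(limit))) {
      stop("rule '", id, "': limit must be list(direction, value)",
           call. = FALSE)
    }
    limit$direction <- match.arg(limit$direction, c("above", "below"))
    limit$value <- as.numeric(limit$value)
  }
  if (!is.null(exposure_window)) {
    exposure_window <- as.numeric(exposure_window)
    if (!is.finite(exposure_window) || exposure_window <= 0) {
      stop("rule '", id, "': exposure_window must be > 0", call. = FALSE)
    }
  }
  if (!identical(severity, "all")) {
    severity <- as.character(severity)
    bad <- setdiff(severity, .severity_levels)
    if (length(bad)) {
      stop("rule '", id, "': unknown severity level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(dynamic)) {
    exposures <- vapply(dynamic, function(s) as.numeric(s$exposure), numeric(1))
    if (is.unsorted(exposures, strictly = TRUE)) {
      stop("rule '", id, "': dynamic steps must have strictly increasing exposure",
           call. = FALSE)
    }
    dynamic <- lapply(dynamic, function(s)
      list(exposure = as.numeric(s$exposure), limit = as.numeric(s$limit)))
  }
  if (is.null(unit)) unit <- parameter_unit(parameter)
  if (!is.null(context)) {
    allowed <- c("activity", "location", "season", "daypart", "when")
    bad <- setdiff(names(context), allowed)
    if (length(bad)) {
      stop("rule '", id, "': unknown context field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(context$location) && !context$location %in% .locations) {
      stop("rule '", id, "': unknown location '", context$location, "'",
           call. = FALSE)
    }
  }
  structure(list(id = id, category = category, parameter = parameter,
                 band = band, limit = limit, context = context,
                 exposure_window = exposure_window, severity = severity,
                 dynamic = dynamic, unit = unit, suggestion = suggestion),
            class = "copd_rule")
}

#' @export
print.copd_rule <- function(x, ...) {
  constraint <- if (!is.null(x$band)) {
    sprintf("alarm when %s outside [%g, %g] %s", x$parameter, x$band[1],
            x$band[2], x$unit)
  } else {
    sprintf("alarm when %s %s %g %s", x$parameter,
            if (x$limit$direction == "above") ">" else "<",
            x$limit$value, x$unit)
  }
  win <- if (is.null(x$exposure_window)) "immediate"
         else sprintf("after %g min", x$exposure_window)
  cat(sprintf("<rule %s> [%s] %s (%s)\n", x$id, x$category, constraint, win))
  invisible(x)
}

#' Construct a rulepack
#'
#' @param name Pack name.
#' @param rules List of [rule()] objects with unique ids.
#' @param version Version string.
#' @return Object of class `copd_rulepack`.
#' @export
rulepack <- function(name, rules = list(), version = "1.0") {
  stopifnot(is.character(name), length(name) == 1L)
  pack <- structure(list(name = name, version = version, rules = rules),
                    class = "copd_rulepack")
  validate_rulepack(pack)
  pack
}

#' Validate a rulepack
#'
#' Checks rule ids are unique, every band has `low <= high`, and every
#' referenced parameter has a registered unit. Errors list the offending
#' rule ids.
#'
#' @param pack A `copd_rulepack`.
#' @return `pack`, invisibly, on success.
#' @export
validate_rulepack <- function(pack) {
  stopifnot(inherits(pack, "copd_rulepack"))
  ids <- vapply(pack$rules, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("rulepack '", pack$name, "': duplicate rule id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_band <- ids[vapply(pack$rules, function(r)
    !is.null(r$band) && r$band[1] > r$band[2], logical(1))]
  if (length(bad_band)) {
    stop("rulepack '", pack$name, "': inverted band in rule(s): ",
         paste(bad_band, collapse = ", "), call. = FALSE)
  }
  bad_par <- ids[vapply(pack$rules, function(r)
    !r$parameter %in% names(.parameter_units), logical(1))]
  if (length(bad_par)) {
    stop("rulepack '", pack$name, "': unregistered parameter in rule(s): ",
         paste(bad_par, collapse = ", "), call. = FALSE)
  }
  invisible(pack)
}

#' @export
print.copd_rulepack <- function(x, ...) {
  cat(sprintf("<rulepack %s v%s> %d rule(s)\n", x$name, x$version,
              length(x$rules)))
  invisible(x)
}

rule_to_list <- function(r) {
  out <- list(id = r$id, category = r$category, parameter = r$parameter)
  if (!is.null(r$band)) out$band <- r$band
  if (!is.null(r$limit)) out$limit <- r$limit
  if (!is.null(r$context)) out$context <- r$context
  if (!is.null(r$exposure_window)) out$exposure_window <- r$exposure_window
  if (!identical(r$severity, "all")) out$severity <- r$severity
  if (!is.null(r$dynamic)) out$dynamic <- r$dynamic
  if (!identical(r$unit, parameter_unit(r$parameter))) out$unit <- r$unit
  if (nzchar(r$suggestion)) out$suggestion <- r$suggestion
  out
}

rule_from_list <- function(l) {
  rule(id = l$id, category = l$category, parameter = l$parameter,
       band = l$band, limit = l$limit, context = l$context,
       exposure_window = l$exposure_window,
       severity = if (is.null(l$severity)) "all" else l$severity,
       dynamic = l$dynamic, unit = l$unit,
       suggestion = if (is.null(l$suggestion)) "" else l$suggestion)
}

#' Load a rulepack from a YAML file or by shipped name
#'
#' The default packs `"vitals"`, `"pollution"`, `"weather"` and
#' `"activity"` are loadable with zero configuration by name.
#'
#' @param path Path to a YAML rulepack file, or one of the shipped pack
#'   names.
#' @return A validated `copd_rulepack`.
#' @examples
#' vp <- load_rulepack("vitals")
#' length(vp$rules)
#' @export
load_rulepack <- function(path) {
  if (path %in% c("vitals", "pollution", "weather", "activity")) {
    path <- system.file("rules", paste0(path, ".yaml"), package = "copdwatch",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("rulepack file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$name)) stop("rulepack file missing 'name'", call. = FALSE)
  rules <- lapply(doc$rules, rule_from_list)
  rulepack(name = doc$name, rules = rules,
           version = if (is.null(doc$version)) "1.0" else as.character(doc$version))
}

#' Write a rulepack to a YAML file
#'
#' @param pack A `copd_rulepack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rulepack <- function(pack, path) {
  stopifnot(inherits(pack, "copd_rulepack"))
  doc <- list(name = pack$name, version = pack$version,
              rules = lapply(pack$rules, rule_to_list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load the four default rulepacks
#'
#' @return Named list of the shipped `vitals`, `pollution`, `weather` and
#'   `activity` packs.
#' @export
default_rulepacks <- function() {
  nms <- c("vitals", "pollution", "weather", "activity")
  stats::setNames(lapply(nms, load_rulepack), nms)
}

#' Specialise a rulepack to a patient profile
#'
#' Personalisation step: vital-sign rules take their band from the profile's
#' own per-activity safe ranges (falling back to the pack default when the
#' rule's parameter or context names no profile band), and rules whose
#' severity applicability excludes the profile's severity group are dropped.
#' Idempotent: expanding an already-expanded pack with the same profile is a
#' no-op.
#'
#' @param pack A `copd_rulepack`.
#' @param profile A [patient_profile()].
#' @return A `copd_rulepack` specialised to the profile.
#' @export
expand_rulepack <- function(pack, profile) {
  stopifnot(inherits(pack, "copd_rulepack"), inherits(profile, "copd_profile"))
  sev <- severity_group(profile)
  keep <- vapply(pack$rules, function(r)
    identical(r$severity, "all") || sev %in% r$severity, logical(1))
  rules <- pack$rules[keep]
  rules <- lapply(rules, function(r) {
    if (r$category == "vital" && r$parameter %in% .vital_names &&
        !is.null(r$context$activity) &&
        r$context$activity %in% .activity_categories) {
      b <- activity_band(profile, r$parameter, r$context$activity)
      r$band <- c(b$low, b$high)
      r$limit <- NULL
    }
    r
  })
  out <- structure(list(name = pack$name, version = pack$version,
                        rules = rules), class = "copd_rulepack")
  attr(out, "expanded_for") <- profile$id
  out
}
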