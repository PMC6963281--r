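# Patient medical records: typed representation, I/O and severity grouping.
#
# A profile mirrors a COPD medical record: demographics, GOLD stage,
# comorbidities, medications, baseline values for the 11 monitored vitals plus
# FEV1, and per-activity-band safe ranges. Bands missing from the record are
# synthesized from the baselines using fixed per-vital offsets anchored on a
# reference record, so every profile is runnable by the engine.

.activity_categories <- c("sedentary", "light", "moderate", "vigorous")
.known_comorbidities <- c("CHF", "HBP", "anemia", "IHD", "PH", "GERD", "asthma")
.severity_levels <- c("low", "moderate", "high", "very_high")

# Additive band offsets (low, high) relative to the baseline, per vital and
# activity category. Anchored on the printed reference record (heart rate
# baseline 60 with light 60-97, moderate 98-120, vigorous 121-130; SpO2
# baseline 96.01 with vigorous 91.30-92.6; etc.). Sedentary bands always
# bracket the baseline.
.band_offsets <- list(
  heart_rate       = list(sedentary = c(-8, 10),    light = c(0, 37),
                          moderate  = c(38, 60),    vigorous = c(61, 70)),
  temperature      = list(sedentary = c(-0.5, 0.5), light = c(0.26, 0.86),
                          moderate  = c(0.57, 1.17), vigorous = c(1.1, 1.7)),
  spo2             = list(sedentary = c(-1, 1),     light = c(-0.8, 0),
                          moderate  = c(-2.91, -1.01), vigorous = c(-4.71, -3.41)),
  pao2             = list(sedentary = c(-4, 4),     light = c(-3, 4),
                          moderate  = c(5, 10),     vigorous = c(11, 17)),
  paco2            = list(sedentary = c(-2, 2),     light = c(-1, 2),
                          moderate  = c(-5, 0),     vigorous = c(-7, 0)),
  dbp              = list(sedentary = c(-5, 5),     light = c(-1, 2.1),
                          moderate  = c(3, 6.1),    vigorous = c(7, 14.1)),
  sbp              = list(sedentary = c(-10, 10),   light = c(1, 20),
                          moderate  = c(21, 25),    vigorous = c(26, 35)),
  respiration_rate = list(sedentary = c(-2, 2),     light = c(0, 5),
                          moderate  = c(6, 16),     vigorous = c(17, 36)),
  vo2              = list(sedentary = c(-0.5, 0.5), light = c(-0.03, 3.81),
                          moderate  = c(3.87, 6.83), vigorous = c(6.97, 9.26)),
  ph               = list(sedentary = c(-0.05, 0.05), light = c(-0.12, 0.04),
                          moderate  = c(-0.25, -0.06), vigorous = c(-0.37, -0.18)),
  hco3             = list(sedentary = c(-3, 3),     light = c(-5, 5),
                          moderate  = c(-9, 1),     vigorous = c(-10, -1)),
  fev1             = list(sedentary = c(-0.2, 0.2), light = c(-0.3, 0.1),
                          moderate  = c(-0.4, 0.1), vigorous = c(-0.5, 0.1))
)

#' Safe band for a monitored parameter
#'
#' @param low,high Numeric band edges, `low <= high`, in the units of the
#'   parameter the band belongs to.
#' @return An object of class `copd_band`.
#' @examples
#' band(77, 113)
#' @export
band <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high),
            length(low) == 1L, length(high) == 1L)
  if (!is.finite(low) || !is.finite(high)) {
    stop("band edges must be finite", call. = FALSE)
  }
  if (low > high) {
    stop("invalid band: low (", low, ") > high (", high, ")", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "copd_band")
}

#' @export
print.copd_band <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x$low, x$high))
  invisible(x)
}

#' Does a value lie inside a band?
#'
#' @param b A [band()].
#' @param x Numeric vector of values.
#' @return Logical vector, `TRUE` where `x` is within `[low, high]`.
#' @export
in_band <- function(b, x) {
  stopifnot(inherits(b, "copd_band"))
  x >= b$low & x <= b$high
}

#' Construct a COPD patient profile
#'
#' Builds and validates a typed medical record. Baselines must be supplied for
#' every monitored vital (see [vital_names()]); activity bands not supplied are
#' synthesized from the baselines with fixed per-vital offsets.
#'
#' @param id Patient identifier.
#' @param age Age in years.
#' @param gender `"male"` or `"female"`.
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param bmi Body mass index in kg/m^2; must agree with `weight/(height/100)^2`
#'   within 0.5. Computed when `NULL`.
#' @param smoker Logical.
#' @param gold_stage COPD airflow-limitation stage, one of `"I".."IV"`.
#' @param mmrc Modified MRC dyspnea grade, 0..4.
#' @param comorbidities Character vector drawn from
#'   CHF, HBP, anemia, IHD, PH, GERD, asthma.
#' @param medications Character vector (free-form, e.g. `"SABA"`, `"inhaler"`).
#' @param baselines Named numeric vector or list of baseline vital values; names
#'   must cover [vital_names()].
#' @param activity_bands Optional data frame with columns `vital`, `category`,
#'   `low`, `high` giving explicit per-activity safe bands.
#' @param extras Optional named list of additional record fields (e.g.
#'   spirometry extras such as FEF25-75, PEF) carried through untouched.
#' @return An object of class `copd_profile`.
#' @examples
#' p <- patient_profile(
#'   id = "t7", age = 51, gender = "male", height = 172, weight = 68,
#'   smoker = FALSE, gold_stage = "I", mmrc = 2, comorbidities = "GERD",
#'   medications = c("SABA", "LABA"),
#'   baselines = c(temperature = 36.95, dbp = 75, sbp = 115, heart_rate = 72,
#'                 pao2 = 78, spo2 = 96, paco2 = 39, vo2 = 2.53,
#'                 respiration_rate = 15, ph = 7.3, hco3 = 25, fev1 = 1.73))
#' severity_group(p)
#' @export
patient_profile <- function(id, age, gender, height, weight, bmi = NULL,
                            smoker = FALSE, gold_stage, mmrc = 0,
                            comorbidities = character(),
                            medications = character(),
                            baselines, activity_bands = NULL,
                            extras = list()) {
  stopifnot(length(id) == 1L, length(age) == 1L, is.numeric(age))
  gender <- match.arg(gender, c("male", "female"))
  gold_stage <- match.arg(as.character(gold_stage), c("I", "II", "III", "IV"))
  stopifnot(is.numeric(height), is.numeric(weight), height > 0, weight > 0)
  mmrc <- as.integer(mmrc)
  if (is.na(mmrc) || mmrc < 0L || mmrc > 4L) {
    stop("mmrc must be an integer in 0..4", call. = FALSE)
  }
  bmi_calc <- weight / (height / 100)^2
  if (is.null(bmi)) bmi <- round(bmi_calc, 2)
  if (abs(bmi - bmi_calc) > 0.5) {
    stop(sprintf("bmi %.2f inconsistent with weight/height (%.2f)",
                 bmi, bmi_calc), call. = FALSE)
  }
  comorbidities <- as.character(comorbidities)
  unknown <- setdiff(comorbidities, .known_comorbidities)
  if (length(unknown)) {
    stop("unknown comorbidities: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  baselines <- unlist(baselines)
  missing_v <- setdiff(.vital_names, names(baselines))
  if (length(missing_v)) {
    stop("missing baseline vitals: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  baselines <- baselines[.vital_names]
  if (any(!is.finite(baselines))) {
    stop("non-finite baseline vital: ",
         paste(names(baselines)[!is.finite(baselines)], collapse = ", "),
         call. = FALSE)
  }
  validate_baseline_units(baselines)

  bands <- synthesize_bands(baselines)
  if (!is.null(activity_bands)) {
    stopifnot(is.data.frame(activity_bands),
              all(c("vital", "category", "low", "high") %in%
                    names(activity_bands)))
    for (i in seq_len(nrow(activity_bands))) {
      row <- activity_bands[i, ]
      if (!row$vital %in% .vital_names) {
        stop("unknown vital in activity_bands: ", row$vital, call. = FALSE)
      }
      if (!row$category %in% .activity_categories) {
        stop("unknown activity category: ", row$category, call. = FALSE)
      }
      if (row$low > row$high) {
        stop(sprintf("inverted band for %s/%s: %g > %g", row$vital,
                     row$category, row$low, row$high), call. = FALSE)
      }
      key <- paste(row$vital, row$category, sep = ".")
      bands[[key]] <- band(row$low, row$high)
    }
  }
  # sedentary band must bracket the baseline
  for (v in .vital_names) {
    b <- bands[[paste(v, "sedentary", sep = ".")]]
    if (baselines[[v]] < b$low || baselines[[v]] > b$high) {
      bands[[paste(v, "sedentary", sep = ".")]] <-
        band(min(b$low, baselines[[v]]), max(b$high, baselines[[v]]))
    }
  }

  structure(
    list(id = as.character(id), age = as.numeric(age), gender = gender,
         height = height, weight = weight, bmi = bmi, smoker = isTRUE(smoker),
         gold_stage = gold_stage, mmrc = mmrc,
         comorbidities = comorbidities, medications = as.character(medications),
         baselines = baselines, activity_bands = bands, extras = extras),
    class = "copd_profile"
  )
}

# plausibility screens per vital: hard unit sanity, not clinical judgement
.vital_plausible <- list(
  temperature = c(30, 43), dbp = c(30, 140), sbp = c(60, 260),
  heart_rate = c(25, 230), pao2 = c(20, 150), spo2 = c(50, 100),
  paco2 = c(10, 120), vo2 = c(0.3, 90), respiration_rate = c(4, 80),
  ph = c(6.5, 8), hco3 = c(5, 60), fev1 = c(0.2, 7)
)

validate_baseline_units <- function(baselines) {
  for (v in names(.vital_plausible)) {
    r <- .vital_plausible[[v]]
    x <- baselines[[v]]
    if (x < r[1] || x > r[2]) {
      stop(sprintf("baseline %s = %g outside plausible range [%g, %g] %s",
                   v, x, r[1], r[2], parameter_unit(v)), call. = FALSE)
    }
  }
  invisible(TRUE)
}

synthesize_bands <- function(baselines) {
  bands <- list()
  for (v in .vital_names) {
    for (cat in .activity_categories) {
      off <- .band_offsets[[v]][[cat]]
      bands[[paste(v, cat, sep = ".")]] <-
        band(baselines[[v]] + off[1], baselines[[v]] + off[2])
    }
  }
  bands
}

#' @export
print.copd_profile <- function(x, ...) {
  cat(sprintf("<copd_profile %s> %s, %g y, GOLD %s, mMRC %d, BMI %.1f\n",
              x$id, x$gender, x$age, x$gold_stage, x$mmrc, x$bmi))
  if (length(x$comorbidities)) {
    cat("  comorbidities:", paste(x$comorbidities, collapse = ", "), "\n")
  }
  cat("  severity group:", severity_group(x), "\n")
  invisible(x)
}

#' Severity (protection-level) group of a profile
#'
#' Maps a profile to one of four protection levels used to scope rule
#' applicability. The mapping is monotone in GOLD stage, and adding a
#' comorbidity can never lower the level:
#' \itemize{
#'   \item `low`: GOLD I-II, no comorbidities, age < 65
#'   \item `moderate`: GOLD I-II with at least one comorbidity or age >= 65
#'   \item `high`: GOLD III without comorbidities
#'   \item `very_high`: GOLD IV, or GOLD III with at least one comorbidity
#' }
#'
#' @param profile A [patient_profile()].
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very_high"`.
#' @export
severity_group <- function(profile) {
  stopifnot(inherits(profile, "copd_profile"))
  n_com <- length(profile$comorbidities)
  stage <- profile$gold_stage
  if (stage == "IV") return("very_high")
  if (stage == "III") return(if (n_com >= 1) "very_high" else "high")
  if (n_com >= 1 || profile$age >= 65) return("moderate")
  "low"
}

#' Ordered severity levels
#' @return Character vector `low < moderate < high < very_high`.
#' @export
severity_levels <- function() .severity_levels

#' Per-activity safe band of a vital for a profile
#'
#' Looks up the profile's safe range for a vital under an activity category.
#' Bands absent from the source record were synthesized from the baseline at
#' construction time, so the lookup is total over known vitals.
#'
#' @param profile A [patient_profile()].
#' @param vital Canonical vital name (see [vital_names()]).
#' @param category Activity category: `"sedentary"`, `"light"`, `"moderate"`
#'   or `"vigorous"`.
#' @return A [band()].
#' @export
activity_band <- function(profile, vital, category) {
  stopifnot(inherits(profile, "copd_profile"))
  if (!vital %in% .vital_names) {
    stop("unknown vital: ", vital, call. = FALSE)
  }
  category <- match.arg(category, .activity_categories)
  profile$activity_bands[[paste(vital, category, sep = ".")]]
}

#' Activity categories
#' @return `c("sedentary", "light", "moderate", "vigorous")`.
#' @export
activity_categories <- function() .activity_categories

# ---------------------------------------------------------------------------
# I/O: CSV (one row per patient) and JSON mirrors. Banded fields are encoded
# "low-high"; list fields are ";"-separated in CSV.

.mandatory_columns <- c("id", "age", "gender", "height", "weight", "smoker",
                        "gold_stage", "mmrc",
                        paste0("baseline_", .vital_names))

#' Load patient profiles from CSV or JSON
#'
#' @param path File path. Format is inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return List of [patient_profile()] objects. Unknown columns are preserved
#'   in each profile's `extras`.
#' @export
load_profiles <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rows <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    missing_cols <- setdiff(.mandatory_columns, names(df))
    if (length(missing_cols)) {
      stop("profile schema error: missing mandatory field(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  lapply(rows, parse_profile_row)
}

parse_profile_row <- function(row) {
  missing_cols <- setdiff(.mandatory_columns, names(row))
  if (length(missing_cols)) {
    stop("profile schema error: missing mandatory field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(field) {
    x <- suppressWarnings(as.numeric(row[[field]]))
    if (is.na(x)) {
      stop(sprintf("parse error in profile '%s': field '%s' is not numeric",
                   row$id, field), call. = FALSE)
    }
    x
  }
  split_list <- function(x) {
    if (is.null(x) || length(x) == 0L) return(character())
    if (length(x) > 1L) return(as.character(x))
    x <- as.character(x)
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1]]
  }
  baselines <- vapply(.vital_names, function(v) num(paste0("baseline_", v)),
                      numeric(1))
  band_cols <- grep("^band_", names(row), value = TRUE)
  ab <- NULL
  if (length(band_cols)) {
    parsed <- lapply(band_cols, function(cn) {
      spec <- sub("^band_", "", cn)
      cat <- sub(".*_", "", spec)
      vital <- sub(paste0("_", cat, "$"), "", spec)
      val <- as.character(row[[cn]])
      if (is.na(val) || !nzchar(val)) return(NULL)
      # "low-high" with possibly negative edges: split on the separating
      # hyphen, not a leading sign
      num_re <- "-?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"
      m <- regmatches(val, regexec(paste0("^(", num_re, ")-(", num_re, ")$"),
                                   val))[[1]]
      edges <- suppressWarnings(as.numeric(m[-1]))
      if (length(edges) != 2L || any(is.na(edges))) {
        stop(sprintf("parse error in profile '%s': band field '%s' = '%s'",
                     row$id, cn, val), call. = FALSE)
      }
      data.frame(vital = vital, category = cat, low = edges[1],
                 high = edges[2], stringsAsFactors = FALSE)
    })
    parsed <- parsed[!vapply(parsed, is.null, logical(1))]
    if (length(parsed)) ab <- do.call(rbind, parsed)
  }
  known <- c(.mandatory_columns, "bmi", "comorbidities", "medications",
             band_cols)
  extras <- row[setdiff(names(row), known)]
  extras <- extras[!vapply(extras, function(x)
    length(x) == 1L && (is.na(x) || identical(as.character(x), "")),
    logical(1))]
  patient_profile(
    id = as.character(row$id), age = num("age"),
    gender = as.character(row$gender),
    height = num("height"), weight = num("weight"),
    bmi = if (!is.null(row$bmi) && !is.na(row$bmi)) num("bmi") else NULL,
    smoker = as.logical(row$smoker), gold_stage = as.character(row$gold_stage),
    mmrc = num("mmrc"),
    comorbidities = split_list(row$comorbidities),
    medications = split_list(row$medications),
    baselines = baselines, activity_bands = ab, extras = extras
  )
}

#' Write patient profiles to CSV or JSON
#'
#' Inverse of [load_profiles()]; a write-then-load round trip reproduces every
#' typed field.
#'
#' @param profiles List of [patient_profile()] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (inferred from extension by default).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  rows <- lapply(profiles, profile_row)
  if (format == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

profile_row <- function(p) {
  row <- list(id = p$id, age = p$age, gender = p$gender, height = p$height,
              weight = p$weight, bmi = p$bmi, smoker = p$smoker,
              gold_stage = p$gold_stage, mmrc = p$mmrc,
              comorbidities = paste(p$comorbidities, collapse = ";"),
              medications = paste(p$medications, collapse = ";"))
  for (v in .vital_names) row[[paste0("baseline_", v)]] <- p$baselines[[v]]
  for (key in names(p$activity_bands)) {
    b <- p$activity_bands[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    row[[paste0("band_", parts[1], "_", parts[2])]] <-
      paste0(b$low, "-", b$high)
  }
  for (nm in names(p$extras)) row[[nm]] <- p$extras[[nm]]
  row
}
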