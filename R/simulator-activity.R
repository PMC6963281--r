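# Markov-chain simulation of activities of daily living.
#
# A day is built from six successive sequences tied to six 4-hour time
# periods (starting 06:00). Within a period, the next activity is drawn from
# that period's row-stochastic transition matrix over the 18 activity
# labels; durations are drawn per activity; per-activity frequency bounds
# [f_min, f_max] constrain how often an activity may occur in a day. The
# profile's functional-capacity level (derived from GOLD stage and dyspnea
# grade) excludes activity categories the patient cannot perform.

.activities <- c(
  "sleeping", "resting", "watching_tv", "reading", "telephone_use",
  "driving", "traveling", "taking_medication", "eating", "dressing",
  "washing", "toileting", "cooking", "walking", "housekeeping", "laundry",
  "jogging", "running"
)

.activity_category_map <- c(
  sleeping = "sedentary", resting = "sedentary", watching_tv = "sedentary",
  reading = "sedentary", telephone_use = "sedentary", driving = "sedentary",
  traveling = "sedentary", taking_medication = "sedentary",
  eating = "light", dressing = "light", washing = "light",
  toileting = "light", cooking = "light", walking = "light",
  housekeeping = "moderate", laundry = "moderate",
  jogging = "vigorous", running = "vigorous"
)

.activity_location_map <- c(
  sleeping = "bedroom", resting = "living_room", watching_tv = "living_room",
  reading = "living_room", telephone_use = "living_room",
  driving = "outdoor", traveling = "outdoor", taking_medication = "indoor",
  eating = "indoor", dressing = "bedroom", washing = "indoor",
  toileting = "indoor", cooking = "indoor", walking = "outdoor",
  housekeeping = "indoor", laundry = "indoor",
  jogging = "outdoor", running = "outdoor"
)

# duration distribution (minutes): mean, sd per activity
.activity_durations <- list(
  sleeping = c(300, 60), resting = c(25, 10), watching_tv = c(60, 20),
  reading = c(40, 15), telephone_use = c(10, 5), driving = c(40, 15),
  traveling = c(60, 30), taking_medication = c(5, 2), eating = c(30, 10),
  dressing = c(10, 3), washing = c(15, 5), toileting = c(8, 3),
  cooking = c(35, 10), walking = c(30, 10), housekeeping = c(45, 15),
  laundry = c(30, 10), jogging = c(25, 10), running = c(20, 8)
)

# per-day frequency bounds
.activity_fbounds <- data.frame(
  activity = .activities,
  f_min = c(1, rep(0, 17)),
  f_max = c(4, 10, 6, 5, 8, 6, 2, 5, 5, 4, 4, 10, 4, 8, 4, 2, 2, 2),
  stringsAsFactors = FALSE
)

# daypart preference weights (rows: dayparts 1..6 starting 06:00)
.daypart_prefs <- local({
  w <- rbind(
    # 06-10: wake, wash, dress, breakfast, commute (driving high 08-09)
    c(sleeping = 0.5, resting = 0.5, watching_tv = 0.3, reading = 0.3,
      telephone_use = 0.3, driving = 2, traveling = 0.2,
      taking_medication = 1, eating = 2, dressing = 2, washing = 2,
      toileting = 1, cooking = 1, walking = 1, housekeeping = 0.5,
      laundry = 0.3, jogging = 0.5, running = 0.3),
    # 10-14: chores, errands
    c(sleeping = 0.1, resting = 1, watching_tv = 0.5, reading = 0.5,
      telephone_use = 0.5, driving = 0.5, traveling = 0.3,
      taking_medication = 0.3, eating = 1, dressing = 0.1, washing = 0.2,
      toileting = 0.5, cooking = 1.5, walking = 1.5, housekeeping = 2,
      laundry = 1, jogging = 0.3, running = 0.2),
    # 14-18: lunch (high 14-16), rest, leisure
    c(sleeping = 0.3, resting = 1.5, watching_tv = 1, reading = 1,
      telephone_use = 0.5, driving = 0.5, traveling = 0.3,
      taking_medication = 0.3, eating = 2.5, dressing = 0.1, washing = 0.2,
      toileting = 0.5, cooking = 0.5, walking = 1, housekeeping = 0.5,
      laundry = 0.3, jogging = 0.4, running = 0.2),
    # 18-22: dinner, tv
    c(sleeping = 0.8, resting = 1, watching_tv = 2.5, reading = 1,
      telephone_use = 0.8, driving = 0.3, traveling = 0.2,
      taking_medication = 1, eating = 2, dressing = 0.2, washing = 0.8,
      toileting = 0.5, cooking = 2, walking = 0.5, housekeeping = 0.3,
      laundry = 0.2, jogging = 0.1, running = 0.05),
    # 22-02: night
    c(sleeping = 8, resting = 0.5, watching_tv = 0.3, reading = 0.2,
      telephone_use = 0.02, driving = 0.02, traveling = 0.02,
      taking_medication = 0.1, eating = 0.05, dressing = 0.02,
      washing = 0.05, toileting = 0.3, cooking = 0.02, walking = 0.02,
      housekeeping = 0.02, laundry = 0.02, jogging = 0.01, running = 0.01),
    # 02-06: deep night
    c(sleeping = 12, resting = 0.2, watching_tv = 0.05, reading = 0.05,
      telephone_use = 0.01, driving = 0.01, traveling = 0.01,
      taking_medication = 0.05, eating = 0.02, dressing = 0.01,
      washing = 0.02, toileting = 0.2, cooking = 0.01, walking = 0.01,
      housekeeping = 0.01, laundry = 0.01, jogging = 0.01, running = 0.01)
  )
  w[, .activities]
})

#' Activity labels of the daily-living simulator
#' @return Character vector of the 18 activity labels.
#' @export
activity_labels <- function() .activities

#' Category of each activity label
#' @param activity Activity label(s).
#' @return Activity category for each label.
#' @export
activity_category_of <- function(activity) {
  unname(.activity_category_map[activity])
}

#' Functional-capacity level of a profile
#'
#' Highest activity category the patient can perform: all four for GOLD
#' I-II, up to moderate for GOLD III, up to light for GOLD IV or an mMRC
#' dyspnea grade of 3 or more.
#'
#' @param profile A [patient_profile()].
#' @return One of `"light"`, `"moderate"`, `"vigorous"`.
#' @export
icf_capacity <- function(profile) {
  stopifnot(inherits(profile, "copd_profile"))
  if (profile$gold_stage == "IV" || profile$mmrc >= 3) return("light")
  if (profile$gold_stage == "III") return("moderate")
  "vigorous"
}

#' Default Markov transition model for daily activities
#'
#' Six per-daypart row-stochastic transition matrices over the 18 activity
#' labels (built from daypart preference weights with no self-transitions),
#' per-activity duration distributions and per-day frequency bounds.
#'
#' @param capacity Highest allowed activity category (see [icf_capacity()]);
#'   activities above it get zero probability everywhere.
#' @return Object of class `copd_transition_model`.
#' @export
transition_model <- function(capacity = "vigorous") {
  capacity <- match.arg(capacity, c("light", "moderate", "vigorous"))
  cap_rank <- match(capacity, .activity_categories)
  allowed <- .activities[
    match(.activity_category_map[.activities], .activity_categories) <= cap_rank]
  mats <- lapply(seq_len(6), function(d) {
    w <- .daypart_prefs[d, ]
    w[setdiff(.activities, allowed)] <- 0
    m <- matrix(0, 18, 18, dimnames = list(.activities, .activities))
    for (i in seq_len(18)) {
      row <- w
      row[i] <- 0                      # no self-transitions
      if (sum(row) == 0) row["resting"] <- 1
      m[i, ] <- row / sum(row)
    }
    m
  })
  fb <- .activity_fbounds
  fb$f_max[!fb$activity %in% allowed] <- 0
  mean_dur <- vapply(.activity_durations, `[[`, numeric(1), 1)
  if (sum(fb$f_min * mean_dur[fb$activity]) > .minutes_per_day) {
    stop("unsatisfiable frequency bounds: minimum activity time exceeds a day",
         call. = FALSE)
  }
  structure(list(matrices = mats, activities = .activities,
                 categories = .activity_category_map,
                 durations = .activity_durations, fbounds = fb,
                 capacity = capacity),
            class = "copd_transition_model")
}

#' @export
print.copd_transition_model <- function(x, ...) {
  cat(sprintf("<transition model> 6 dayparts x %d activities, capacity %s\n",
              length(x$activities), x$capacity))
  invisible(x)
}

# draw next activity from the daypart matrix row, honouring f_max counts
sample_next_activity <- function(model, daypart, current, counts) {
  p <- model$matrices[[daypart]][current, ]
  saturated <- model$fbounds$activity[counts[model$fbounds$activity] >=
                                        model$fbounds$f_max]
  p[saturated] <- 0
  if (sum(p) == 0) return("resting")
  sample(model$activities, 1L, prob = p)
}

sample_duration <- function(model, activity) {
  d <- model$durations[[activity]]
  max(1L, round(stats::rnorm(1, d[1], d[2])))
}

#' Simulate one day of activities
#'
#' Generates a sequence of activity events tiling one day at 1-minute
#' resolution (no gaps, no overlaps), driven by the per-daypart transition
#' matrices. Activities above the profile's functional capacity never
#' appear; per-activity counts respect the model's frequency bounds. The
#' same seed reproduces the same day.
#'
#' @param model A [transition_model()]; its capacity should match the
#'   profile (it is tightened automatically if the profile allows less).
#' @param profile A [patient_profile()].
#' @param seed Optional integer seed.
#' @return Data frame of events: `start` and `end` (minutes from midnight,
#'   `end` exclusive), `activity`, `category`.
#' @export
generate_activity_day <- function(model = transition_model(), profile,
                                  seed = NULL) {
  stopifnot(inherits(model, "copd_transition_model"),
            inherits(profile, "copd_profile"))
  cap <- icf_capacity(profile)
  if (match(cap, .activity_categories) <
      match(model$capacity, .activity_categories)) {
    model <- transition_model(cap)
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::setNames(integer(length(model$activities)),
                            model$activities)
  t <- 0L
  current <- "sleeping"   # day starts at midnight, asleep
  counts[current] <- 1L
  starts <- integer(); ends <- integer(); acts <- character()
  while (t < .minutes_per_day) {
    dur <- sample_duration(model, current)
    end <- min(t + dur, .minutes_per_day)
    starts <- c(starts, t); ends <- c(ends, end); acts <- c(acts, current)
    t <- end
    if (t >= .minutes_per_day) break
    daypart <- daypart_of(t)
    nxt <- sample_next_activity(model, daypart, current, counts)
    counts[nxt] <- counts[nxt] + 1L
    current <- nxt
  }
  data.frame(start = starts, end = ends, activity = acts,
             category = unname(.activity_category_map[acts]),
             stringsAsFactors = FALSE)
}

# expand an event table to per-minute labels
activity_minutes <- function(events) {
  idx <- rep.int(seq_len(nrow(events)), events$end - events$start)
  data.frame(activity = events$activity[idx],
             activity_category = events$category[idx],
             location = unname(.activity_location_map[events$activity[idx]]),
             activity_duration = sequence(events$end - events$start),
             stringsAsFactors = FALSE)
}
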