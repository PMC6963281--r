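# End-to-end orchestration (simulate -> monitor -> aggregate) and
# confusion-matrix evaluation of alarm quality.

#' Run monitoring over a simulated cohort
#'
#' Streams each patient's joined per-minute records through the rule engine
#' with packs expanded to the patient's profile. Deterministic given the
#' cohort seeds; patients are evaluated independently.
#'
#' @param profiles List of [patient_profile()]s (or a [generate_cohort()]
#'   result, in which case `dataset` may be omitted).
#' @param dataset Named list of per-patient streams (names = patient ids).
#' @param packs A `copd_rulepack` or list of packs
#'   ([default_rulepacks()] by default).
#' @param refractory Compliant minutes before a fired rule re-arms.
#' @param expand Personalise vital-sign bands to each profile via
#'   [expand_rulepack()] before evaluation.
#' @param verbose Log per-patient progress to stderr.
#' @return Named list of per-patient alarm logs (data frames as in
#'   [evaluate_stream()], with `patient_id` attached).
#' @export
run_monitoring <- function(profiles, dataset = NULL,
                           packs = default_rulepacks(), refractory = 5,
                           expand = TRUE, verbose = FALSE) {
  if (is.list(profiles) && !is.null(profiles$streams)) {
    dataset <- profiles$streams
    profiles <- profiles$profiles
  }
  if (inherits(profiles, "copd_profile")) profiles <- list(profiles)
  if (is.data.frame(dataset)) dataset <- list(dataset)
  ids <- vapply(profiles, `[[`, character(1), "id")
  if (is.null(names(dataset))) names(dataset) <- ids[seq_along(dataset)]
  missing_streams <- setdiff(ids, names(dataset))
  if (length(missing_streams)) {
    stop("no stream for patient(s): ",
         paste(missing_streams, collapse = ", "), call. = FALSE)
  }
  for (id in ids) {
    s <- dataset[[id]]
    need <- c("timestamp", "activity_category", "location")
    absent <- setdiff(need, names(s))
    if (length(absent)) {
      stop("stream for ", id, " lacks mandatory field(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  if (inherits(packs, "copd_rulepack")) packs <- list(packs)
  logs <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (verbose) message("monitoring ", p$id, " (", nrow(dataset[[p$id]]),
                         " records)")
    pk <- if (expand) lapply(packs, expand_rulepack, profile = p) else packs
    log <- evaluate_stream(p, dataset[[p$id]], pk, refractory = refractory)
    log$patient_id <- rep(p$id, nrow(log))
    logs[[p$id]] <- log
  }
  logs
}

#' Aggregate an alarm log by season, month or category
#'
#' Season mapping: Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov
#' autumn. The counts always partition the log exactly.
#'
#' @param log Alarm log data frame (or list of per-patient logs, which are
#'   concatenated).
#' @param by `"season"`, `"month"` or `"category"`.
#' @return For `"season"`: a `season_table` (category x season matrix with
#'   a `Total` row); for `"month"`: category x month matrix; for
#'   `"category"`: named counts.
#' @export
aggregate_alarms <- function(log, by = c("season", "month", "category")) {
  by <- match.arg(by)
  if (is.list(log) && !is.data.frame(log)) log <- do.call(rbind, log)
  categories <- .rule_categories
  if (by == "category") {
    counts <- table(factor(log$category, levels = categories))
    return(stats::setNames(as.integer(counts), categories))
  }
  ts <- as.POSIXct(log$timestamp * 60, origin = "1970-01-01", tz = "UTC")
  key <- if (by == "season") {
    factor(season_of(ts), levels = .seasons)
  } else {
    factor(format(ts, "%Y-%m"))
  }
  m <- table(factor(log$category, levels = categories), key)
  m <- unclass(m)
  m <- rbind(m, Total = colSums(m))
  if (by == "season") class(m) <- c("season_table", class(m))
  m
}

#' @export
print.season_table <- function(x, ...) {
  cat("Alarms by season (columns partition the log):\n")
  print(unclass(x))
  invisible(x)
}

#' Build confusion counts from paired alarm/reference outcomes
#'
#' An alarm paired with a reference event (hospitalization) is a true
#' positive; an alarm without one a false positive; no alarm and no event a
#' true negative; a missed event a false negative.
#'
#' @param alarm Logical vector (or data frame with columns `alarm` and
#'   `reference`): did the system alarm?
#' @param reference Logical vector: did the reference event occur?
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' build_confusion(c(TRUE, FALSE), c(TRUE, TRUE))  # tp 1, fn 1
#' @export
build_confusion <- function(alarm, reference = NULL) {
  if (is.data.frame(alarm)) {
    reference <- alarm$reference
    alarm <- alarm$alarm
  }
  stopifnot(is.logical(alarm), is.logical(reference),
            length(alarm) == length(reference))
  c(tp = sum(alarm & reference), fp = sum(alarm & !reference),
    tn = sum(!alarm & !reference), fn = sum(!alarm & reference))
}

#' Diagnostic metrics from confusion counts
#'
#' Standard confusion-matrix metric set, as percentages: accuracy
#' (TP+TN)/total, sensitivity TP/(TP+FN), false negative fraction
#' FN/(TP+FN), specificity TN/(TN+FP), false positive fraction FP/(TN+FP),
#' positive predictive value TP/(TP+FP), negative predictive value
#' TN/(FN+TN), and F1 as the harmonic mean of PPV and sensitivity. A metric
#' with a zero denominator is returned as `NA` (undefined), not an error.
#'
#' @param tp,fp,tn,fn Non-negative counts (or `tp` may be the named vector
#'   from [build_confusion()]); total must be positive.
#' @return Object of class `copd_confusion`: the counts and the metric set
#'   in percent.
#' @examples
#' confusion_metrics(512, 88, 544, 56)
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L && !is.null(names(tp))) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("total count must be positive", call. = FALSE)
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- frac(tp, tp + fn)
  ppv <- frac(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
        else 2 * sens * ppv / (sens + ppv)
  structure(list(
    counts = counts,
    accuracy = 100 * (tp + tn) / total,
    sensitivity = sens,
    fnf = frac(fn, tp + fn),
    specificity = frac(tn, tn + fp),
    fpf = frac(fp, tn + fp),
    ppv = ppv,
    npv = frac(tn, fn + tn),
    f1 = f1
  ), class = "copd_confusion")
}

#' @export
print.copd_confusion <- function(x, digits = 2, ...) {
  with(as.list(x$counts), cat(sprintf(
    "confusion counts: TP %d  FP %d  TN %d  FN %d\n", tp, fp, tn, fn)))
  for (m in c("accuracy", "sensitivity", "fnf", "specificity", "fpf",
              "ppv", "npv", "f1")) {
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "undefined"
                else paste0(round(x[[m]], digits), "%")))
  }
  invisible(x)
}

#' Daily alarm/reference outcome pairs for a monitored patient
#'
#' Ground-truth oracle for evaluation on synthetic data: a day is
#' reference-positive when the stream carries at least `min_anomaly_minutes`
#' injected abnormal minutes, and alarm-positive when the log holds at least
#' one vital-sign alarm that day.
#'
#' @param stream A patient stream from [generate_cohort()].
#' @param log The patient's alarm log from [run_monitoring()].
#' @param min_anomaly_minutes Injected abnormal minutes for a day to count
#'   as hospitalization-worthy.
#' @return Data frame with `day`, `alarm`, `reference`.
#' @export
daily_outcomes <- function(stream, log, min_anomaly_minutes = 5) {
  day_of <- function(ts) format(ts, "%Y-%m-%d")
  days <- day_of(stream$timestamp)
  ref <- tapply(stream$anomaly, days, sum) >= min_anomaly_minutes
  alarm_days <- character()
  if (nrow(log)) {
    ts <- as.POSIXct(log$timestamp * 60, origin = "1970-01-01", tz = "UTC")
    alarm_days <- unique(day_of(ts[log$category == "vital"]))
  }
  data.frame(day = names(ref),
             alarm = names(ref) %in% alarm_days,
             reference = as.logical(ref),
             row.names = NULL, stringsAsFactors = FALSE)
}
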