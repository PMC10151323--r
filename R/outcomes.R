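#' @name outcomes
#' @title Adjudicated competing-risks outcomes
#'
#' @description
#' Each patient contributes exactly one record: the first adjudicated event
#' (acute coronary syndrome, all-cause death or revascularization) with its
#' time in days, or censoring at last follow-up.  Same-day ties are resolved
#' by clinical precedence: a death on the day of another event counts as a
#' death, and an ACS with same-day revascularization counts as an ACS.
NULL

#' Permitted event kinds, censoring first
#' @export
event_kinds <- function() c("censored", "ACS", "death", "revascularization")

# precedence for same-day ties: higher wins
.event_precedence <- c(death = 3, ACS = 2, revascularization = 1)

#' Adjudicate a patient's raw event list to a single first event
#'
#' @param raw_events A data.frame (or NULL/empty) with columns `kind`
#'   (one of "ACS", "death", "revascularization") and `day` (non-negative).
#' @param last_followup_day Last day of follow-up; must be >= every event day.
#' @return A list with `event_kind` and `time_days`.  With no events the
#'   patient is censored at `last_followup_day`.
#' @export
adjudicate_events <- function(raw_events, last_followup_day) {
  if (!is.numeric(last_followup_day) || last_followup_day < 0)
    stop("`last_followup_day` must be non-negative")
  if (is.null(raw_events) || NROW(raw_events) == 0)
    return(list(event_kind = "censored",
                time_days = as.integer(last_followup_day)))
  kind <- as.character(raw_events$kind)
  day <- raw_events$day
  if (!all(kind %in% names(.event_precedence)))
    stop("unknown event kind: ",
         paste(setdiff(kind, names(.event_precedence)), collapse = ", "))
  if (any(day < 0)) stop("event days must be non-negative")
  if (any(day > last_followup_day))
    stop("event after end of follow-up")
  first_day <- min(day)
  at_first <- kind[day == first_day]
  winner <- at_first[which.max(.event_precedence[at_first])]
  list(event_kind = winner, time_days = as.integer(first_day))
}

#' Build an outcome table from per-patient records
#'
#' @param event_kind Character vector over [event_kinds()].
#' @param time_days Non-negative integer vector (event or censoring day).
#' @param grid A [time_grid()] used to derive `bin_index`.
#' @param patient_id Optional ids; defaults to `P00001`-style labels.
#' @return A data.frame of class `outcome_table` with columns `patient_id`,
#'   `event_kind`, `time_days`, `bin_index`.
#' @export
outcome_table <- function(event_kind, time_days, grid,
                          patient_id = NULL) {
  stopifnot(length(event_kind) == length(time_days))
  if (!all(event_kind %in% event_kinds()))
    stop("unknown event kind(s): ",
         paste(unique(setdiff(event_kind, event_kinds())), collapse = ", "))
  if (is.null(patient_id))
    patient_id <- sprintf("P%05d", seq_along(event_kind))
  out <- data.frame(patient_id = as.character(patient_id),
                    event_kind = as.character(event_kind),
                    time_days = as.integer(time_days),
                    bin_index = discretize_time(time_days, grid),
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome_table", "data.frame")
  attr(out, "grid") <- grid
  out
}

#' Drop early revascularizations (sensitivity filter)
#'
#' Removes patients whose adjudicated first event is revascularization within
#' `window_days` of the scan; all other patients are retained.
#'
#' @param outcomes An [outcome_table()].
#' @param window_days Window in days (default 180).
#' @return The filtered outcome table (attributes preserved).
#' @export
filter_early_revasc <- function(outcomes, window_days = 180) {
  keep <- !(outcomes$event_kind == "revascularization" &
              outcomes$time_days <= window_days)
  out <- outcomes[keep, , drop = FALSE]
  attr(out, "grid") <- attr(outcomes, "grid")
  class(out) <- class(outcomes)
  out
}

#' Fixed-time binary labels for ROC analysis
#'
#' A patient is positive if the event of interest (any of the three, for
#' `"MACE"`) occurred on or before `t_days`, negative if followed beyond
#' `t_days` without it (events of other kinds after `t_days` also count as
#' event-free).  Patients censored before `t_days` without an event cannot be
#' labelled and are excluded via the mask.
#'
#' @param outcomes An [outcome_table()].
#' @param t_days Evaluation time in days; must not exceed the grid horizon.
#' @param event_kind One of "ACS", "death", "revascularization" or "MACE".
#' @return A list with logical vectors `label` (NA where excluded) and
#'   `include`.
#' @export
label_fixed_time <- function(outcomes, t_days, event_kind = "MACE") {
  grid <- attr(outcomes, "grid")
  if (!is.null(grid) && t_days > grid$horizon_days)
    stop("`t_days` beyond the grid horizon")
  if (!event_kind %in% c("MACE", setdiff(event_kinds(), "censored")))
    stop("unknown `event_kind`: ", event_kind)
  is_event <- if (event_kind == "MACE") outcomes$event_kind != "censored"
              else outcomes$event_kind == event_kind
  positive <- is_event & outcomes$time_days <= t_days
  # followed beyond t without the event of interest: either any record with
  # time > t, or a competing event at <= t does NOT make the patient
  # labelable as negative (their later follow-up is truncated), so exclude.
  negative <- outcomes$time_days > t_days & !positive
  competing_before <- !positive & outcomes$event_kind != "censored" &
    outcomes$time_days <= t_days & !is_event
  include <- positive | negative
  # patients with a competing first event before t are excluded alongside
  # the early-censored: their event-free status at t is unobservable
  include[competing_before] <- FALSE
  label <- ifelse(include, positive, NA)
  list(label = label, include = include)
}
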