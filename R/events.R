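#' Clinical event records
#'
#' Events are plain data frames with columns `patient_id`, `time_s`,
#' `event_type` (one of `alarm`, `hypotension_onset`, `treatment`),
#' `detail` (treatment option, empty otherwise) and, after merging,
#' `merged_into` (the anchor event's time, `NA` for anchors).
#'
#' @param patient_id Identifier.
#' @param time_s Event times, seconds from case start (non-negative).
#' @param event_type Event type, recycled.
#' @param detail Treatment option name; must be non-empty exactly for
#'   treatment events.
#' @return A data frame of events sorted by time.
#' @export
clinical_events <- function(patient_id, time_s, event_type, detail = "") {
  n <- length(time_s)
  event_type <- rep_len(as.character(event_type), n)
  detail <- rep_len(as.character(detail), n)
  if (any(time_s < 0)) stop("event times must be >= 0", call. = FALSE)
  bad <- !event_type %in% c("alarm", "hypotension_onset", "treatment")
  if (any(bad)) stop("unknown event_type: ", event_type[bad][1], call. = FALSE)
  mism <- (event_type == "treatment") != nzchar(detail)
  if (any(mism))
    stop("detail must be non-empty exactly for treatment events", call. = FALSE)
  out <- data.frame(patient_id = rep_len(as.character(patient_id), n),
                    time_s = as.numeric(time_s),
                    event_type = event_type,
                    detail = detail,
                    stringsAsFactors = FALSE)
  out[order(out$time_s), , drop = FALSE]
}

#' Detect hypotensive episodes in a MAP series
#'
#' A hypotensive event is MAP < 65 mmHg sustained for at least one minute;
#' on a 20-s grid that is three or more consecutive sub-threshold samples.
#' One `hypotension_onset` event is emitted at the first sample of every
#' maximal qualifying run.
#'
#' @param series A [vital_series()].
#' @param threshold Pressure threshold, mmHg (strict `<`).
#' @param min_duration_s Minimum sustained duration, seconds.
#' @return Event data frame (possibly zero rows).
#' @export
detect_hypotension_events <- function(series, threshold = 65,
                                      min_duration_s = 60) {
  stopifnot(is_vital_series(series))
  cad <- attr(series, "cadence_s")
  below <- series$map_mmhg < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * cad >= min_duration_s)
  onset_idx <- starts[keep]
  clinical_events(attr(series, "patient_id"),
                  series$time_s[onset_idx],
                  rep("hypotension_onset", length(onset_idx)))
}

#' Detect predictive-index alarms
#'
#' The monitor alarms when the index strictly exceeds the threshold; one
#' alarm event is emitted per upward crossing (a sample above the threshold
#' whose predecessor was at or below it, or the first sample).
#'
#' @inheritParams detect_hypotension_events
#' @param alarm_threshold Index threshold (strict `>`), default 85.
#' @return Event data frame of `alarm` events.
#' @export
detect_alarm_events <- function(series, alarm_threshold = 85) {
  stopifnot(is_vital_series(series))
  idx <- series$index
  if (all(is.na(idx)))
    stop("series has no index channel", call. = FALSE)
  above <- idx > alarm_threshold
  prev <- c(FALSE, above[-length(above)])
  cross <- which(above & !prev)
  clinical_events(attr(series, "patient_id"),
                  series$time_s[cross],
                  rep("alarm", length(cross)))
}

# Anchored merging on raw times: the earliest unmerged time anchors the
# window [anchor, anchor + window); everything inside merges into it; the
# first time at or beyond the window's end becomes the next anchor.
# Returns, for each input time, the anchor time it belongs to.
merge_anchor_times <- function(time_s, window_s) {
  n <- length(time_s)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(time_s)) stop("times must be sorted", call. = FALSE)
  anchor <- numeric(n)
  cur <- time_s[1]
  for (i in seq_len(n)) {
    if (time_s[i] - cur >= window_s) cur <- time_s[i]
    anchor[i] <- cur
  }
  anchor
}

#' Merge repeated events within a 15-minute window
#'
#' Repeats within 15 min of an initial event count as a single event. The
#' merge is anchored, not chained: the first event fixes a window of
#' `window_min` minutes; all events inside it merge into that anchor, and
#' the first event at or beyond the window's end starts a new anchor.
#' Windows are closed on the left, open on the right.
#'
#' @param events Event data frame of a single `event_type`, time-sorted.
#' @param window_min Merge window, minutes.
#' @return The same events with a `merged_into` column: `NA` for anchors,
#'   otherwise the anchor's `time_s`.
#' @export
merge_events <- function(events, window_min = 15) {
  if (nrow(events) == 0L) {
    events$merged_into <- numeric(0)
    return(events)
  }
  if (length(unique(events$event_type)) > 1L)
    stop("merge_events expects events of a single type", call. = FALSE)
  events <- events[order(events$time_s), , drop = FALSE]
  anchors <- merge_anchor_times(events$time_s, window_min * 60)
  events$merged_into <- ifelse(events$time_s == anchors, NA_real_, anchors)
  events
}

#' Extract anchor events from a merged event list
#'
#' @param merged Output of [merge_events()].
#' @return The anchor rows only.
#' @export
event_anchors <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  merged[is.na(merged$merged_into), , drop = FALSE]
}

#' Reconstruct silent alarm times for reactively managed patients
#'
#' In the control arm the predictive index runs but is not shown; the time
#' the alarm would have sounded (the silent alarm time, SAT) is
#' reconstructed post hoc for each merged hypotension anchor as the
#' earliest sample with index above the alarm threshold within the 15
#' minutes preceding the onset (inclusive of the onset sample). Anchors
#' with no qualifying sample yield no SAT and are reported as
#' unreconstructable.
#'
#' @param series A [vital_series()] with an index channel.
#' @param hypotension_anchors Anchor events from merged hypotension onsets.
#' @param alarm_threshold Index threshold (strict `>`).
#' @param window_min Look-back window, minutes.
#' @return A list with `sat` (event-style data frame with columns
#'   `patient_id`, `time_s`, `event_type = "alarm"`, `anchor_time_s`) and
#'   `unreconstructable` (anchor times with no index exceedance in window).
#' @export
silent_alarm_times <- function(series, hypotension_anchors,
                               alarm_threshold = 85, window_min = 15) {
  stopifnot(is_vital_series(series))
  if (all(is.na(series$index)))
    stop("series has no index channel", call. = FALSE)
  ht <- hypotension_anchors$time_s
  sat <- rep(NA_real_, length(ht))
  for (i in seq_along(ht)) {
    in_win <- series$time_s >= ht[i] - window_min * 60 &
      series$time_s <= ht[i] &
      series$index > alarm_threshold
    if (any(in_win)) sat[i] <- series$time_s[which(in_win)[1]]
  }
  ok <- !is.na(sat)
  list(
    sat = data.frame(patient_id = rep(attr(series, "patient_id"), sum(ok)),
                     time_s = sat[ok],
                     event_type = rep("alarm", sum(ok)),
                     anchor_time_s = ht[ok],
                     stringsAsFactors = FALSE),
    unreconstructable = ht[!ok]
  )
}

#' Latency from an anchor event to the first treatment
#'
#' For each anchor, the first treatment at or after the anchor and within
#' its window gives `latency_s = first_treatment_time_s - anchor_time_s`.
#' A treatment can satisfy only one anchor (greedy, earliest first).
#' Anchors with no in-window treatment are reported with `NA` latency.
#'
#' @param anchors Data frame with `time_s` (anchor times) and optionally
#'   `anchor_type` labels (`AT`, `HT` or `SAT`).
#' @param treatments Event data frame of treatments, time-sorted.
#' @param window_min Matching window, minutes.
#' @param anchor_type Label used when `anchors` carries none.
#' @return Data frame with columns `patient_id`, `anchor_type`,
#'   `anchor_time_s`, `first_treatment_time_s`, `latency_s`, `treated`.
#' @export
compute_latencies <- function(anchors, treatments, window_min = 15,
                              anchor_type = "HT") {
  tt <- sort(treatments$time_s)
  used <- logical(length(tt))
  at <- sort(anchors$time_s)
  types <- if ("anchor_type" %in% names(anchors))
    anchors$anchor_type[order(anchors$time_s)] else rep(anchor_type, length(at))
  ftt <- rep(NA_real_, length(at))
  for (i in seq_along(at)) {
    cand <- which(!used & tt >= at[i] & tt < at[i] + window_min * 60)
    if (length(cand)) {
      ftt[i] <- tt[cand[1]]
      used[cand[1]] <- TRUE
    }
  }
  pid <- if (nrow(anchors)) anchors$patient_id[1] else character(0)
  data.frame(patient_id = rep(pid, length(at)),
             anchor_type = types,
             anchor_time_s = at,
             first_treatment_time_s = ftt,
             latency_s = ftt - at,
             treated = !is.na(ftt),
             stringsAsFactors = FALSE)
}

#' Write / read an event log as CSV
#'
#' Columns `time_s`, `event_type`, `detail` (treatment option or empty).
#'
#' @param events Event data frame.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("time_s", "event_type", "detail")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param patient_id Patient id to attach (defaults to the file stem).
#' @export
read_events_csv <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(detail = "character"))
  if (is.null(patient_id))
    patient_id <- sub("^events_", "", tools::file_path_sans_ext(basename(path)))
  df$detail[is.na(df$detail)] <- ""
  clinical_events(patient_id, df$time_s, df$event_type, df$detail)
}
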