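#' Area under a pressure threshold
#'
#' Cumulative depth-times-time of MAP excursions below the threshold:
#' each sample with MAP strictly below the threshold contributes
#' `(threshold - MAP) * cadence` (rectangle rule on the monitor's grid; a
#' sample exactly at the threshold contributes nothing). Missing samples
#' are excluded from the numerator.
#'
#' @param series A [vital_series()].
#' @param threshold Pressure threshold, mmHg (> 0).
#' @return AUC in mmHg.min (non-negative scalar).
#' @examples
#' vs <- vital_series("p", seq(0, 580, 20), rep(60, 30), 20, 10)
#' auc_below(vs, 65)  # 5 mmHg depth for 10 min = 50
#' @export
auc_below <- function(series, threshold = 65) {
  stopifnot(is_vital_series(series))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  depth <- pmax(0, threshold - series$map_mmhg)
  sum(depth, na.rm = TRUE) * attr(series, "cadence_s") / 60
}

#' Time spent below a pressure threshold
#'
#' @inheritParams auc_below
#' @return Duration in minutes (samples strictly below the threshold times
#'   the cadence).
#' @export
duration_below <- function(series, threshold = 65) {
  stopifnot(is_vital_series(series))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  sum(series$map_mmhg < threshold, na.rm = TRUE) *
    attr(series, "cadence_s") / 60
}

#' Area above a pressure threshold (hypertension burden)
#'
#' Mirror of [auc_below()] with depth `max(0, MAP - threshold)`; used to
#' quantify severe hypertension (MAP above 130 mmHg) as an overtreatment
#' signal.
#'
#' @inheritParams auc_below
#' @export
auc_above <- function(series, threshold = 130) {
  stopifnot(is_vital_series(series))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  excess <- pmax(0, series$map_mmhg - threshold)
  sum(excess, na.rm = TRUE) * attr(series, "cadence_s") / 60
}

#' @rdname auc_above
#' @export
duration_above <- function(series, threshold = 130) {
  stopifnot(is_vital_series(series))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  sum(series$map_mmhg > threshold, na.rm = TRUE) *
    attr(series, "cadence_s") / 60
}

#' Time-weighted average excursion
#'
#' `TWA = AUC / total surgical duration`. The denominator is the whole
#' surgical duration, including time above the threshold and gaps, not
#' just monitored or excursion time.
#'
#' @param auc Area under (or above) the threshold, mmHg.min.
#' @param total_duration Total surgical duration, min (> 0).
#' @return TWA in mmHg.
#' @examples
#' twa(852.8, 538)  # 1.585..., reported as 1.59
#' @export
twa <- function(auc, total_duration) {
  if (!is.finite(total_duration) || total_duration <= 0)
    stop("total_duration must be positive", call. = FALSE)
  if (!is.finite(auc) || auc < 0) stop("auc must be >= 0", call. = FALSE)
  auc / total_duration
}

#' @rdname twa
#' @param series A [vital_series()].
#' @param threshold Pressure threshold, mmHg.
#' @export
twa_below <- function(series, threshold = 65) {
  twa(auc_below(series, threshold), attr(series, "surgical_duration_min"))
}

#' @rdname twa
#' @export
twa_above <- function(series, threshold = 130) {
  twa(auc_above(series, threshold), attr(series, "surgical_duration_min"))
}

#' Threshold-excursion burden summary
#'
#' One row per (threshold, direction): AUC, duration, TWA and the total
#' duration used as the TWA denominator. A gap fraction above 10% of the
#' expected sample count flags the series.
#'
#' @param series A [vital_series()].
#' @param thresholds Hypotension thresholds, mmHg, default `c(65, 60, 55)`.
#' @param hypertension_threshold Upper threshold, mmHg, default 130.
#' @return Data frame of class `threshold_burden` with columns
#'   `patient_id`, `threshold`, `direction`, `auc`, `duration`, `twa`,
#'   `total_duration`, `gap_flag`.
#' @export
threshold_burden <- function(series, thresholds = c(65, 60, 55),
                             hypertension_threshold = 130) {
  stopifnot(is_vital_series(series))
  tot <- attr(series, "surgical_duration_min")
  expected_n <- floor(tot * 60 / attr(series, "cadence_s")) + 1
  gap_frac <- 1 - sum(!is.na(series$map_mmhg)) / expected_n
  gap_flag <- gap_frac > 0.10

  rows <- lapply(thresholds, function(th) {
    a <- auc_below(series, th)
    data.frame(patient_id = attr(series, "patient_id"), threshold = th,
               direction = "below", auc = a,
               duration = duration_below(series, th),
               twa = twa(a, tot), total_duration = tot,
               gap_flag = gap_flag, stringsAsFactors = FALSE)
  })
  if (!is.null(hypertension_threshold)) {
    a <- auc_above(series, hypertension_threshold)
    rows <- c(rows, list(
      data.frame(patient_id = attr(series, "patient_id"),
                 threshold = hypertension_threshold, direction = "above",
                 auc = a, duration = duration_above(series, hypertension_threshold),
                 twa = twa(a, tot), total_duration = tot,
                 gap_flag = gap_flag, stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_burden", "data.frame")
  out
}

#' Whole-case MAP summary
#'
#' Sample mean, median and quartiles of MAP over the case. Quantiles use
#' the standard linear-interpolation convention (R type 7).
#'
#' @param series A [vital_series()].
#' @return Named list with `mean`, `median`, `q1`, `q3`, `min`, `max`,
#'   `n_samples`.
#' @export
case_map_summary <- function(series) {
  stopifnot(is_vital_series(series))
  x <- series$map_mmhg[!is.na(series$map_mmhg)]
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
       min = min(x), max = max(x), n_samples = length(x))
}
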