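#' Fixed-cadence vital-sign series for one patient
#'
#' The container every burden and event computation operates on: mean
#' arterial pressure (MAP) sampled on a strict grid, an optional 0-100
#' predictive index channel, and the auxiliary hemodynamics the treatment
#' protocol consumes (stroke volume variation, dynamic arterial elastance,
#' systolic slope, systemic vascular resistance).
#'
#' @param patient_id Identifier string.
#' @param time_s Sample times in seconds from case start; must start at 0
#'   and be equally spaced at `cadence_s`.
#' @param map_mmhg MAP per sample, mmHg; finite and positive.
#' @param cadence_s Sampling interval, seconds.
#' @param surgical_duration_min Total surgical duration, minutes; at least
#'   the last sample time.
#' @param index Optional predictive index per sample (0-100).
#' @param svv_pct,eadyn,dpdtmax,svr Optional auxiliary channels.
#' @return An object of class `vital_series` (a data frame with one row
#'   per sample and metadata attributes).
#' @examples
#' vs <- vital_series("p1", time_s = seq(0, 580, by = 20),
#'                    map_mmhg = rep(80, 30), cadence_s = 20,
#'                    surgical_duration_min = 10)
#' nrow(vs)
#' @export
vital_series <- function(patient_id, time_s, map_mmhg, cadence_s,
                         surgical_duration_min,
                         index = NULL, svv_pct = NULL, eadyn = NULL,
                         dpdtmax = NULL, svr = NULL) {
  n <- length(time_s)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (surgical_duration_min <= 0)
    stop("surgical duration must be positive", call. = FALSE)
  if (time_s[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (n > 1L && any(abs(diff(time_s) - cadence_s) > 1e-9))
    stop("time grid must be equally spaced at the cadence", call. = FALSE)
  if (length(map_mmhg) != n)
    stop("map_mmhg length does not match time grid", call. = FALSE)
  if (any(!is.finite(map_mmhg)) || any(map_mmhg <= 0))
    stop("MAP must be finite and positive", call. = FALSE)
  if (surgical_duration_min * 60 < time_s[n] - 1e-9)
    stop("surgical duration shorter than the series", call. = FALSE)

  opt <- function(x) if (is.null(x)) rep(NA_real_, n) else {
    stopifnot(length(x) == n); as.numeric(x)
  }
  out <- data.frame(
    time_s = as.numeric(time_s),
    map_mmhg = as.numeric(map_mmhg),
    index = opt(index),
    svv_pct = opt(svv_pct),
    eadyn = opt(eadyn),
    dpdtmax = opt(dpdtmax),
    svr = opt(svr)
  )
  structure(out,
            patient_id = as.character(patient_id),
            cadence_s = cadence_s,
            surgical_duration_min = surgical_duration_min,
            class = c("vital_series", "data.frame"))
}

#' @export
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series> patient %s: %d samples at %g s, %.1f min surgery\n",
              attr(x, "patient_id"), nrow(x), attr(x, "cadence_s"),
              attr(x, "surgical_duration_min")))
  cat(sprintf("  MAP %.1f-%.1f mmHg; index channel %s\n",
              min(x$map_mmhg), max(x$map_mmhg),
              if (all(is.na(x$index))) "absent" else "present"))
  invisible(x)
}

#' @rdname vital_series
#' @param x Object to test.
#' @export
is_vital_series <- function(x) inherits(x, "vital_series")

#' Write / read one patient's vitals as CSV
#'
#' Column layout `time_s, map_mmhg, index, svv_pct, eadyn, dpdtmax, svr`
#' with a mandatory header, decimal point and comma separator.
#'
#' @param series A `vital_series`.
#' @param path Output CSV path.
#' @return `write_vitals_csv` returns `path` invisibly; `read_vitals_csv`
#'   returns a `vital_series`.
#' @export
write_vitals_csv <- function(series, path) {
  stopifnot(is_vital_series(series))
  df <- as.data.frame(series)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vitals_csv
#' @param patient_id Patient id to attach (defaults to the file stem).
#' @param cadence_s Cadence; inferred from the time column when `NULL`.
#' @param surgical_duration_min Duration; defaults to the last sample time.
#' @export
read_vitals_csv <- function(path, patient_id = NULL, cadence_s = NULL,
                            surgical_duration_min = NULL) {
  if (!file.exists(path)) stop("vitals file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "map_mmhg")
  if (!all(need %in% names(df)))
    stop("vitals CSV must contain columns time_s and map_mmhg", call. = FALSE)
  if (is.null(patient_id))
    patient_id <- sub("^vitals_", "", tools::file_path_sans_ext(basename(path)))
  if (is.null(cadence_s))
    cadence_s <- if (nrow(df) > 1L) df$time_s[2] - df$time_s[1] else 20
  if (is.null(surgical_duration_min))
    surgical_duration_min <- df$time_s[nrow(df)] / 60
  grab <- function(col) if (col %in% names(df) && !all(is.na(df[[col]]))) df[[col]] else NULL
  vital_series(patient_id, df$time_s, df$map_mmhg, cadence_s,
               surgical_duration_min,
               index = grab("index"), svv_pct = grab("svv_pct"),
               eadyn = grab("eadyn"), dpdtmax = grab("dpdtmax"),
               svr = grab("svr"))
}
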