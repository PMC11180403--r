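#' Per-patient outcome extraction
#'
#' Runs the burden and event analytics over a simulated (or loaded)
#' cohort bundle: threshold-excursion burdens at 65/60/55 mmHg and above
#' 130 mmHg, the whole-case MAP summary, treatment counts, and the
#' treatment latencies anchored at the alarm (intervention), the
#' hypotension onset and the reconstructed silent alarm (control).
#'
#' @param bundle Output of [generate_cohort()] (elements `cohort`,
#'   `series`, `events`).
#' @param alarm_threshold Index alarm threshold.
#' @param window_min Event-merge and matching window, minutes.
#' @return Data frame, one row per patient.
#' @export
patient_outcomes <- function(bundle, alarm_threshold = 85, window_min = 15) {
  cohort <- bundle$cohort
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    arm <- cohort$arm[i]
    ser <- bundle$series[[pid]]
    ev <- bundle$events[[pid]]
    bt <- threshold_burden(ser)
    g <- function(th, dir, col) bt[bt$threshold == th & bt$direction == dir, col]
    ms <- case_map_summary(ser)
    treatments <- ev[ev$event_type == "treatment", , drop = FALSE]
    lat <- patient_latencies(ser, ev, arm, alarm_threshold, window_min)
    data.frame(
      patient_id = pid, arm = arm,
      twa65 = g(65, "below", "twa"), auc65 = g(65, "below", "auc"),
      dur65 = g(65, "below", "duration"),
      twa60 = g(60, "below", "twa"), auc60 = g(60, "below", "auc"),
      dur60 = g(60, "below", "duration"),
      twa55 = g(55, "below", "twa"), auc55 = g(55, "below", "auc"),
      dur55 = g(55, "below", "duration"),
      twa_above130 = g(130, "above", "twa"),
      map_median = ms$median, map_mean = ms$mean,
      n_treatments = nrow(treatments),
      latency_primary_s = lat$primary_s,
      latency_sat_s = lat$sat_s,
      n_anchors = lat$n_anchors,
      n_unreconstructable = lat$n_unreconstructable,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-patient median latencies; anchors are arm-specific
patient_latencies <- function(series, events, arm, alarm_threshold = 85,
                              window_min = 15) {
  treatments <- events[events$event_type == "treatment", , drop = FALSE]
  if (arm == "intervention") {
    alarms <- events[events$event_type == "alarm", , drop = FALSE]
    if (nrow(alarms) == 0L && !all(is.na(series$index)))
      alarms <- detect_alarm_events(series, alarm_threshold)
    anchors <- event_anchors(merge_events(alarms, window_min))
    lat <- compute_latencies(anchors, treatments, window_min, "AT")
    med <- stats::median(lat$latency_s[lat$treated])
    return(list(primary_s = med, sat_s = med, n_anchors = nrow(anchors),
                n_unreconstructable = 0L))
  }
  onsets <- detect_hypotension_events(series)
  anchors <- event_anchors(merge_events(onsets, window_min))
  lat <- compute_latencies(anchors, treatments, window_min, "HT")
  sat <- silent_alarm_times(series, anchors, alarm_threshold, window_min)
  sat_lat <- rep(NA_real_, nrow(sat$sat))
  if (nrow(sat$sat)) {
    ftt <- lat$first_treatment_time_s[match(sat$sat$anchor_time_s,
                                            lat$anchor_time_s)]
    sat_lat <- ftt - sat$sat$time_s
  }
  list(primary_s = stats::median(lat$latency_s[lat$treated]),
       sat_s = stats::median(sat_lat[!is.na(sat_lat)]),
       n_anchors = nrow(anchors),
       n_unreconstructable = length(sat$unreconstructable))
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Report-style row formatting
#'
#' `fmt_median_iqr` renders `"0.02 [0.003, 0.08]"`; `fmt_mean_sd` renders
#' `"517.5 ± 222.1"`; `fmt_n_pct` renders `"6 (20.0%)"`.
#'
#' @param x Numeric sample.
#' @param digits Decimal places.
#' @return Character scalar.
#' @export
fmt_median_iqr <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("-")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%s [%s, %s]", fmt_num(q[2], digits), fmt_num(q[1], digits),
          fmt_num(q[3], digits))
}

#' @rdname fmt_median_iqr
#' @export
fmt_mean_sd <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("-")
  sprintf("%s ± %s", fmt_num(mean(x), digits),
          fmt_num(stats::sd(x), digits))
}

#' @rdname fmt_median_iqr
#' @param n Count.
#' @param total Denominator.
#' @export
fmt_n_pct <- function(n, total) {
  sprintf("%d (%s%%)", n, fmt_num(100 * n / total, 1))
}

row_continuous_mean <- function(label, xi, xc, digits = 1) {
  ti <- t_test_from_summary(mean(xi), stats::sd(xi), length(xi),
                            mean(xc), stats::sd(xc), length(xc))
  data.frame(variable = label,
             intervention = fmt_mean_sd(xi, digits),
             control = fmt_mean_sd(xc, digits),
             estimate = ti$estimate, ci_low = ti$ci_low,
             ci_high = ti$ci_high, p_value = ti$p_value,
             method = ti$method_notes, stringsAsFactors = FALSE)
}

row_continuous_median <- function(label, xi, xc, digits = 2) {
  hl <- hodges_lehmann(xi, xc)
  data.frame(variable = label,
             intervention = fmt_median_iqr(xi, digits),
             control = fmt_median_iqr(xc, digits),
             estimate = hl$estimate, ci_low = hl$ci_low,
             ci_high = hl$ci_high, p_value = hl$p_value,
             method = paste("Hodges-Lehmann;", hl$method_notes),
             stringsAsFactors = FALSE)
}

row_proportion <- function(label, x1, n1, x2, n2) {
  # a zero margin (feature absent or universal in both arms) admits no
  # test; the row is kept with an empty p, as trial tables do
  degenerate <- (x1 + x2) %in% c(0L, n1 + n2)
  if (degenerate) {
    p <- NA_real_
    which_test <- "none (zero margin)"
  } else {
    which_test <- select_test(x1, n1 - x1, x2, n2 - x2)
    tst <- if (which_test == "fisher") fisher_2x2(x1, n1 - x1, x2, n2 - x2)
    else chi_square_2x2(x1, n1 - x1, x2, n2 - x2)
    p <- tst$p_value
  }
  ci <- proportion_diff_ci(x1, n1, x2, n2)
  data.frame(variable = label,
             intervention = fmt_n_pct(x1, n1),
             control = fmt_n_pct(x2, n2),
             estimate = ci$estimate, ci_low = ci$ci_low,
             ci_high = ci$ci_high, p_value = p,
             method = paste(which_test, "+ continuity-corrected Wald"),
             stringsAsFactors = FALSE)
}

#' Assemble the trial report tables
#'
#' Builds the four report tables from a cohort bundle: baseline
#' characteristics, burden and clinician-behaviour outcomes,
#' intraoperative treatment usage, and a placeholder postoperative table
#' (postoperative follow-up is outside the simulator's scope; the row is
#' an explicit placeholder, never a silent omission).
#'
#' @param bundle Output of [generate_cohort()].
#' @param outcomes Optional precomputed [patient_outcomes()] table.
#' @return Named list of data frames `table1` ... `table4`.
#' @export
build_tables <- function(bundle, outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- patient_outcomes(bundle)
  ch <- bundle$cohort
  ii <- ch$arm == "intervention"
  oi <- outcomes[outcomes$arm == "intervention", ]
  oc <- outcomes[outcomes$arm == "control", ]
  ni <- sum(ii); nc <- sum(!ii)

  surg_tab <- table(ch$arm, ch$surgery_type)
  surg_p <- tryCatch(
    suppressWarnings(stats::chisq.test(surg_tab)$p.value),
    error = function(e) NA_real_)
  table1 <- rbind(
    row_continuous_mean("Age, years", ch$age[ii], ch$age[!ii]),
    row_proportion("Men, n (%)", sum(ch$sex[ii] == "M"), ni,
                   sum(ch$sex[!ii] == "M"), nc),
    row_proportion("Pancreas, n (%)",
                   sum(ch$surgery_type[ii] == "pancreas"), ni,
                   sum(ch$surgery_type[!ii] == "pancreas"), nc),
    row_proportion("Oral cancer, n (%)",
                   sum(ch$surgery_type[ii] == "oral"), ni,
                   sum(ch$surgery_type[!ii] == "oral"), nc),
    row_proportion("Esophagus, n (%)",
                   sum(ch$surgery_type[ii] == "esophagus"), ni,
                   sum(ch$surgery_type[!ii] == "esophagus"), nc),
    row_continuous_mean("Surgical duration, min",
                        ch$surgical_duration[ii], ch$surgical_duration[!ii]))
  table1 <- rbind(table1, data.frame(
    variable = "Surgery type (overall)", intervention = "-", control = "-",
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = surg_p, method = "chi-square on the 2x3 table",
    stringsAsFactors = FALSE))

  med_row <- function(lab, col, digits = 2)
    row_continuous_median(lab, oi[[col]], oc[[col]], digits)
  table2 <- rbind(
    med_row("TWA-MAP < 65 mmHg, mmHg", "twa65"),
    med_row("AUC < 65 mmHg, mmHg x min", "auc65"),
    med_row("Duration of MAP < 65 mmHg, min", "dur65"),
    med_row("TWA-MAP < 60 mmHg, mmHg", "twa60", 3),
    med_row("AUC < 60 mmHg, mmHg x min", "auc60"),
    med_row("Duration of MAP < 60 mmHg, min", "dur60"),
    med_row("TWA-MAP < 55 mmHg, mmHg", "twa55", 3),
    med_row("AUC < 55 mmHg, mmHg x min", "auc55"),
    med_row("Duration of MAP < 55 mmHg, min", "dur55"),
    med_row("TWA-MAP > 130 mmHg, mmHg", "twa_above130", 3),
    med_row("Median intraoperative MAP, mmHg", "map_median"),
    med_row("Number of treatments per patient", "n_treatments", 1),
    row_continuous_median("Duration from AT or HT to FTT, s",
                          oi$latency_primary_s[!is.na(oi$latency_primary_s)],
                          oc$latency_primary_s[!is.na(oc$latency_primary_s)], 1),
    row_continuous_median("Duration from AT or SAT to FTT, s",
                          oi$latency_sat_s[!is.na(oi$latency_sat_s)],
                          oc$latency_sat_s[!is.na(oc$latency_sat_s)], 1))

  opt_used <- function(evs, opt)
    sum(vapply(evs, function(e)
      any(e$event_type == "treatment" & e$detail == opt), logical(1)))
  ev_i <- bundle$events[ch$patient_id[ii]]
  ev_c <- bundle$events[ch$patient_id[!ii]]
  table3 <- do.call(rbind, lapply(treatment_options(), function(opt)
    row_proportion(sprintf("%s, n (%%)", opt),
                   opt_used(ev_i, opt), ni, opt_used(ev_c, opt), nc)))

  table4 <- data.frame(
    variable = "Postoperative outcomes",
    intervention = "not simulated", control = "not simulated",
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_,
    method = "placeholder: postoperative follow-up outside generator scope",
    stringsAsFactors = FALSE)

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4)
}

#' Run the full pipeline: simulate, measure, analyse, report
#'
#' Executes simulate -> burden -> events -> analyse in order, writing
#' every intermediate as CSV under `out_dir` and recording a run manifest
#' (config hash, seed, output digests). Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [sim_config()] or the path of a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return A `run_manifest` list (invisibly): `config_hash`, `seed`,
#'   `outputs` (named md5 digests), `tables`, `outcomes`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config, seed = seed)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_sim_config(config)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  bundle <- generate_cohort(config, out_dir = file.path(out_dir, "data"))
  outcomes <- patient_outcomes(bundle,
                               alarm_threshold = config$index_alarm_threshold)

  burden_rows <- do.call(rbind, lapply(bundle$series, threshold_burden))
  utils::write.csv(burden_rows, file.path(out_dir, "burden.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  tables <- build_tables(bundle, outcomes)
  tab_paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    tab_paths <- c(tab_paths, p)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  outs <- c(bundle$paths, file.path(out_dir, c("burden.csv", "outcomes.csv")),
            tab_paths)
  digests <- tools::md5sum(outs)
  names(digests) <- basename(outs)

  manifest <- structure(list(config_hash = config_hash, seed = config$seed,
                             n_per_arm = config$n_per_arm,
                             outputs = digests, tables = tables,
                             outcomes = outcomes),
                        class = "run_manifest")
  yaml::write_yaml(list(config_hash = config_hash, seed = config$seed,
                        outputs = as.list(digests)),
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run: seed %d, %d patients per arm, config %s\n",
              x$seed, x$n_per_arm, substr(x$config_hash, 1, 8)))
  cat(sprintf("  %d output files; primary-outcome medians: intervention %s, control %s mmHg\n",
              length(x$outputs),
              fmt_num(stats::median(x$outcomes$twa65[x$outcomes$arm == "intervention"]), 3),
              fmt_num(stats::median(x$outcomes$twa65[x$outcomes$arm == "control"]), 3)))
  invisible(x)
}
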