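#' @section Signal model:
#' MAP follows a discrete-time mean-reverting (Ornstein-Uhlenbeck-style)
#' update on the monitor's 20-s grid,
#' `m[k] = m[k-1] + theta * (target[k] - m[k-1]) * dt + sigma * sqrt(dt) * e[k]`,
#' where the set-point `target` is the patient's baseline plus any active
#' provocation offset plus any active treatment effect, `dt` is the
#' cadence in minutes and `e[k]` are standard normal innovations. Values
#' are clamped to the physiological range 20-200 mmHg.
#' @name hpitrial-simulation
#' @keywords internal
NULL

# run the mean-reverting recursion; eps of length n (eps[1] unused)
ou_path <- function(target, baseline, theta, sigma, dt, eps,
                    lo = 20, hi = 200) {
  n <- length(target)
  m <- numeric(n)
  m[1] <- min(hi, max(lo, baseline))
  s <- sigma * sqrt(dt)
  for (k in seq_len(n)[-1]) {
    mk <- m[k - 1] + theta * (target[k] - m[k - 1]) * dt + s * eps[k]
    m[k] <- min(hi, max(lo, mk))
  }
  m
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Patient covariates for the synthetic trial
#'
#' @param patient_id Identifier.
#' @param arm `"intervention"` or `"control"`.
#' @param age Years; the trial enrols adults aged 20 to 80.
#' @param sex `"M"` or `"F"`.
#' @param surgery_type One of `pancreas`, `oral`, `esophagus`.
#' @param surgical_duration Minutes, positive.
#' @return One-row data frame of validated covariates.
#' @export
patient_covariates <- function(patient_id, arm, age, sex, surgery_type,
                               surgical_duration) {
  arm <- match.arg(arm, c("intervention", "control"))
  sex <- match.arg(sex, c("M", "F"))
  surgery_type <- match.arg(surgery_type, c("pancreas", "oral", "esophagus"))
  if (age < 20 || age > 80)
    stop("age must lie in [20, 80] years", call. = FALSE)
  if (surgical_duration <= 0)
    stop("surgical_duration must be positive", call. = FALSE)
  data.frame(patient_id = as.character(patient_id), arm = arm,
             age = age, sex = sex, surgery_type = surgery_type,
             surgical_duration = surgical_duration,
             stringsAsFactors = FALSE)
}

# draw provocation episodes for one case
draw_provocations <- function(config, duration_min) {
  k <- stats::rpois(1, config$provocation_rate * duration_min / 60)
  if (k == 0L)
    return(data.frame(start_min = numeric(0), depth = numeric(0),
                      duration_min = numeric(0), cause = character(0),
                      stringsAsFactors = FALSE))
  lo <- min(5, duration_min * 0.05)
  start <- sort(stats::runif(k, lo, max(lo, duration_min - 5)))
  depth <- stats::runif(k, config$provocation_depth_range[1],
                        config$provocation_depth_range[2])
  dur <- pmax(2, stats::rexp(k, 1 / config$provocation_duration_mean))
  cause <- sample(c("preload", "tone", "contractility"), k,
                  replace = TRUE, prob = c(0.45, 0.40, 0.15))
  data.frame(start_min = start, depth = depth, duration_min = dur,
             cause = cause, stringsAsFactors = FALSE)
}

#' Simulate one patient's MAP trace
#'
#' Generates the untreated mean-arterial-pressure path: a mean-reverting
#' process around the patient's baseline, perturbed by randomly timed
#' hypotensive provocations (set-point drops with a physiological cause
#' that also shapes the auxiliary channels). Treatment effects are added
#' later by [simulate_treatments()].
#'
#' @param config A [sim_config()].
#' @param covariates One-row data frame from [patient_covariates()].
#' @param seed Substream seed; defaults to the per-patient stream derived
#'   from `config$seed` and the patient id.
#' @param provocations Optional data frame (`start_min`, `depth`,
#'   `duration_min`, `cause`) forcing the provocation schedule; `NULL`
#'   draws it randomly.
#' @return A [vital_series()] with MAP and auxiliary channels filled; the
#'   index channel is filled by [simulate_index_series()].
#' @export
simulate_map_series <- function(config, covariates, seed = NULL,
                                provocations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dur_min <- covariates$surgical_duration
  if (is.null(dur_min) || dur_min <= 0)
    stop("surgical duration must be positive", call. = FALSE)
  if (is.null(seed))
    seed <- patient_seed(config$seed, covariates$patient_id)

  with_seed(seed, {
    n <- floor(dur_min * 60 / config$cadence_s) + 1L
    t_s <- (seq_len(n) - 1L) * config$cadence_s
    dt <- config$cadence_s / 60

    baseline <- stats::rnorm(1, config$baseline_map_mean,
                             config$baseline_map_sd)
    if (is.null(provocations)) provocations <- draw_provocations(config, dur_min)

    offset <- numeric(n)
    cause_at <- rep(NA_character_, n)
    if (nrow(provocations)) {
      for (i in seq_len(nrow(provocations))) {
        in_ep <- t_s >= provocations$start_min[i] * 60 &
          t_s < (provocations$start_min[i] + provocations$duration_min[i]) * 60
        offset[in_ep] <- offset[in_ep] + provocations$depth[i]
        cause_at[in_ep] <- provocations$cause[i]
      }
    }
    target <- baseline + offset
    eps <- stats::rnorm(n)
    map <- ou_path(target, baseline, config$ou_reversion_rate,
                   config$ou_noise_sd, dt, eps)

    # auxiliary hemodynamics: calm baselines shifted by the active cause
    svv <- 8 + stats::rnorm(n, 0, 1.2)
    eadyn <- 1.05 + stats::rnorm(n, 0, 0.08)
    dpdt <- 900 + stats::rnorm(n, 0, 60)
    svr <- 1100 + stats::rnorm(n, 0, 80)
    pre <- !is.na(cause_at) & cause_at == "preload"
    ton <- !is.na(cause_at) & cause_at == "tone"
    ctr <- !is.na(cause_at) & cause_at == "contractility"
    svv[pre] <- svv[pre] + 9
    eadyn[pre] <- eadyn[pre] + 0.15
    svr[ton] <- svr[ton] - 450
    eadyn[ton] <- eadyn[ton] - 0.35
    dpdt[ctr] <- dpdt[ctr] - 450
    svv <- pmax(svv, 0)

    out <- vital_series(covariates$patient_id, t_s, map, config$cadence_s,
                        dur_min, svv_pct = svv, eadyn = eadyn,
                        dpdtmax = dpdt, svr = svr)
    attr(out, "sim_baseline") <- baseline
    attr(out, "sim_target") <- target
    attr(out, "sim_eps") <- eps
    attr(out, "sim_provocations") <- provocations
    out
  })
}

# forward rolling minimum over the next `w` samples (inclusive of current)
roll_forward_min <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(k) min(x[k:min(n, k + w)]), numeric(1))
}

#' Fill the predictive index channel
#'
#' The index proxy is a saturating (logistic) transform of the projected
#' MAP minimum over the next 15 minutes, centred so that the index
#' strictly exceeds the alarm threshold exactly when that projected
#' minimum lies below 65 mmHg, plus bounded noise. The projection is the
#' noise-free mean-reverting relaxation of the current (untreated) mean
#' MAP toward the currently active set-point - the index reacts once a
#' hemodynamic deterioration is in progress, before pressure itself has
#' crossed the threshold, and forecasts what would happen absent
#' intervention. This gives the proxy the one property the analysis
#' relies on: with noise off, every sustained sub-65 excursion is
#' preceded by an alarm with positive lead time.
#'
#' @param map_series Output of [simulate_map_series()].
#' @param config A [sim_config()].
#' @param seed Substream seed for the index noise (defaults to the map
#'   substream shifted by one).
#' @param horizon_min Forward projection horizon, minutes.
#' @return The series with the index channel filled (values in 0-100).
#' @export
simulate_index_series <- function(map_series, config, seed = NULL,
                                  horizon_min = 15) {
  stopifnot(is_vital_series(map_series), inherits(config, "sim_config"))
  target <- attr(map_series, "sim_target")
  baseline <- attr(map_series, "sim_baseline")
  n <- nrow(map_series)
  dt <- config$cadence_s / 60
  if (!is.null(target)) {
    mbar <- ou_path(target, baseline, config$ou_reversion_rate, 0, dt, numeric(n))
    # relaxation from the current mean toward the active set-point is
    # monotone, so its minimum over the horizon is attained at an endpoint
    horizon_end <- target + (mbar - target) *
      exp(-config$ou_reversion_rate * horizon_min)
    fmin <- pmin(mbar, horizon_end)
  } else {
    # observed-data fallback: realised forward minimum over the horizon
    w <- floor(horizon_min * 60 / config$cadence_s)
    fmin <- roll_forward_min(map_series$map_mmhg, w)
  }

  scale <- 2.5
  centre <- 65 + scale * stats::qlogis(config$index_alarm_threshold / 100)
  idx <- 100 * stats::plogis((centre - fmin) / scale)
  if (config$index_noise_sd > 0) {
    if (is.null(seed))
      seed <- patient_seed(config$seed, attr(map_series, "patient_id")) + 1L
    noise <- with_seed(seed, stats::rnorm(n, 0, config$index_noise_sd))
    noise <- pmin(pmax(noise, -2.5 * config$index_noise_sd),
                  2.5 * config$index_noise_sd)
    idx <- idx + noise
  }
  map_series$index <- pmin(100, pmax(0, idx))
  map_series
}

# lognormal delay with a given median, clamped
draw_delay <- function(median_s, sdlog, lo, hi) {
  min(hi, max(lo, stats::rlnorm(1, log(median_s), sdlog)))
}

#' Apply arm-specific treatment triggering to a simulated case
#'
#' Walks the case forward in time. In the intervention arm a treatment
#' follows each merged (15-min anchored) index alarm within the
#' two-minute action window; in both arms a reactive treatment follows
#' each merged MAP < 65 mmHg crossing after the control detection delay
#' (in the intervention arm this is the standard-of-care backstop for
#' breakthrough hypotension). The treatment option is chosen by the
#' decision protocol from the auxiliary hemodynamics at the anchor; each
#' non-observation option injects a pressure-effect pulse
#' (instantaneous-onset exponential decay for vasopressor-type options, a
#' 5-minute linear ramp for fluid-containing options) into the MAP
#' set-point from the treatment time onward, and the MAP path is
#' re-propagated through the same innovations.
#'
#' @param map_series Output of [simulate_map_series()].
#' @param index_series Output of [simulate_index_series()] (same patient).
#' @param arm `"intervention"` or `"control"`.
#' @param config A [sim_config()].
#' @param seed Substream seed (defaults to the map substream shifted by
#'   two).
#' @param thresholds Protocol thresholds for option choice.
#' @return List with `series` (the treated [vital_series()], index channel
#'   carried over) and `events` (alarms in the intervention arm, plus all
#'   treatment events with their option in `detail`).
#' @export
simulate_treatments <- function(map_series, index_series, arm, config,
                                seed = NULL,
                                thresholds = protocol_thresholds()) {
  arm <- match.arg(arm, c("intervention", "control"))
  stopifnot(is_vital_series(map_series), is_vital_series(index_series))
  target <- attr(map_series, "sim_target")
  baseline <- attr(map_series, "sim_baseline")
  eps <- attr(map_series, "sim_eps")
  if (is.null(target) || is.null(eps))
    stop("map_series lacks simulation internals; use simulate_map_series()",
         call. = FALSE)
  pid <- attr(map_series, "patient_id")
  if (is.null(seed)) seed <- patient_seed(config$seed, pid) + 2L

  n <- nrow(map_series)
  t_s <- map_series$time_s
  dt <- config$cadence_s / 60
  tau <- config$treatment_effect_decay_min
  amp_rng <- config$treatment_effect_amplitude_range

  with_seed(seed, {
    # intervention: alarm anchors and their action delays are fixed by the
    # (untreated-path) index, so they can be scheduled up front
    pending_time <- numeric(0)   # treatment times
    pending_anchor <- integer(0) # sample index of the anchor snapshot
    alarm_events <- NULL
    if (arm == "intervention") {
      alarms <- detect_alarm_events(index_series, config$index_alarm_threshold)
      merged <- merge_events(alarms, window_min = 15)
      anchors <- event_anchors(merged)
      if (nrow(anchors)) {
        delays <- vapply(seq_len(nrow(anchors)), function(i)
          draw_delay(42, 0.55, 10, config$intervention_response_delay_s),
          numeric(1))
        pending_time <- anchors$time_s + delays
        pending_anchor <- match(anchors$time_s, t_s)
      }
      alarm_events <- alarms
    }

    effect <- numeric(n)
    m <- numeric(n)
    m[1] <- min(200, max(20, baseline))
    s_step <- config$ou_noise_sd * sqrt(dt)
    last_reactive_anchor <- -Inf
    treat_time <- numeric(0)
    treat_option <- character(0)

    apply_treatment <- function(tt, anchor_k) {
      snap <- list(svv = map_series$svv_pct[anchor_k],
                   eadyn = map_series$eadyn[anchor_k],
                   dpdtmax = map_series$dpdtmax[anchor_k],
                   svr = map_series$svr[anchor_k])
      opt <- recommend(snap, thresholds)$option
      treat_time <<- c(treat_time, tt)
      treat_option <<- c(treat_option, opt)
      if (opt == "observation") return(invisible())
      a <- stats::runif(1, amp_rng[1], amp_rng[2])
      el <- t_s - tt
      on <- el >= 0
      pulse <- numeric(n)
      if (opt %in% c("fluid", "fluid_plus_inotrope")) {
        pulse[on] <- a * pmin(1, el[on] / 300) *
          exp(-pmax(0, el[on] - 300) / (tau * 60))
      } else {
        pulse[on] <- a * exp(-el[on] / (tau * 60))
      }
      effect <<- effect + pulse
      invisible()
    }

    for (k in 2:n) {
      due <- which(pending_time <= t_s[k])
      if (length(due)) {
        for (j in due) apply_treatment(pending_time[j], pending_anchor[j])
        pending_time <- pending_time[-due]
        pending_anchor <- pending_anchor[-due]
      }
      mk <- m[k - 1] +
        config$ou_reversion_rate * (target[k] + effect[k] - m[k - 1]) * dt +
        s_step * eps[k]
      m[k] <- min(200, max(20, mk))
      # reactive rule: new sub-65 crossing outside the previous merge window
      if (m[k] < 65 && m[k - 1] >= 65 &&
          t_s[k] - last_reactive_anchor >= 15 * 60) {
        last_reactive_anchor <- t_s[k]
        d <- draw_delay(config$control_detection_delay_s, 0.4, 20, 180)
        pending_time <- c(pending_time, t_s[k] + d)
        pending_anchor <- c(pending_anchor, k)
      }
    }

    series <- vital_series(pid, t_s, m, config$cadence_s,
                           attr(map_series, "surgical_duration_min"),
                           index = index_series$index,
                           svv_pct = map_series$svv_pct,
                           eadyn = map_series$eadyn,
                           dpdtmax = map_series$dpdtmax,
                           svr = map_series$svr)
    attr(series, "sim_baseline") <- baseline
    attr(series, "sim_target") <- target
    attr(series, "sim_eps") <- eps
    attr(series, "sim_effect") <- effect

    ev <- if (length(treat_time)) {
      clinical_events(pid, treat_time, "treatment", treat_option)
    } else {
      clinical_events(pid, numeric(0), character(0), character(0))
    }
    if (!is.null(alarm_events) && nrow(alarm_events))
      ev <- rbind(alarm_events, ev)
    ev <- ev[order(ev$time_s), , drop = FALSE]
    rownames(ev) <- NULL
    list(series = series, events = ev)
  })
}

#' Generate the full two-arm synthetic cohort
#'
#' Draws covariates, simulates each patient's vitals, runs arm-specific
#' treatment triggering, detects hypotension onsets on the treated trace,
#' and (optionally) writes the three CSV products: `vitals_<id>.csv`,
#' `events_<id>.csv` and `cohort.csv`. The whole bundle is deterministic
#' under `config$seed`, and per-patient substreams are derived by hashing
#' the patient id, so adding patients never perturbs existing ones.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for the CSV products.
#' @param thresholds Protocol thresholds forwarded to
#'   [simulate_treatments()].
#' @return Invisibly, a list with `cohort` (covariate table), `series`
#'   (named list of treated [vital_series()]), `events` (named list of
#'   event logs) and `paths` (written files, when `out_dir` is given).
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            thresholds = protocol_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  ids <- c(sprintf("int_%02d", seq_len(config$n_per_arm)),
           sprintf("ctl_%02d", seq_len(config$n_per_arm)))
  arms <- rep(c("intervention", "control"), each = config$n_per_arm)

  cov_list <- vector("list", length(ids))
  series_list <- vector("list", length(ids))
  events_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cov_list[[i]] <- with_seed(patient_seed(config$seed, ids[i]) + 3L, {
      age <- min(80, max(20, stats::rnorm(1, 60, 10.5)))
      sex <- if (stats::runif(1) < 0.8) "M" else "F"
      sg <- sample(c("pancreas", "oral", "esophagus"), 1,
                   prob = c(0.33, 0.37, 0.30))
      dur <- min(960, max(180, stats::rlnorm(1, config$duration_lognorm_params[1],
                                             config$duration_lognorm_params[2])))
      patient_covariates(ids[i], arms[i], age, sex, sg, dur)
    })
    ms <- simulate_map_series(config, cov_list[[i]])
    is_ <- simulate_index_series(ms, config)
    tr <- simulate_treatments(ms, is_, arms[i], config,
                              thresholds = thresholds)
    onsets <- detect_hypotension_events(tr$series)
    ev <- rbind(tr$events, onsets)
    ev <- ev[order(ev$time_s, ev$event_type), , drop = FALSE]
    rownames(ev) <- NULL
    series_list[[i]] <- tr$series
    events_list[[i]] <- ev
  }
  cohort <- do.call(rbind, cov_list)
  names(series_list) <- names(events_list) <- ids

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok || !dir.exists(out_dir))
        stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    ctab <- cohort
    names(ctab)[names(ctab) == "surgical_duration"] <- "duration_min"
    p <- file.path(out_dir, "cohort.csv")
    utils::write.csv(format(ctab, digits = 10, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    paths <- p
    for (id in ids) {
      pv <- file.path(out_dir, paste0("vitals_", id, ".csv"))
      pe <- file.path(out_dir, paste0("events_", id, ".csv"))
      write_vitals_csv(series_list[[id]], pv)
      write_events_csv(events_list[[id]], pe)
      paths <- c(paths, pv, pe)
    }
  }
  invisible(list(cohort = cohort, series = series_list,
                 events = events_list, paths = paths))
}
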