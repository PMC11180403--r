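#' Simulation configuration for the synthetic two-arm cohort
#'
#' Bundles every tunable of the cohort generator. The defaults encode the
#' study conditions the downstream analysis assumes: vital signs sampled
#' every 20 s, an alarm threshold of 85 on the 0-100 predictive index,
#' clinicians acting within 2 min of an alarm in the intervention arm, and
#' reactive treatment once mean arterial pressure (MAP) has crossed
#' 65 mmHg in the control arm.
#'
#' @param n_per_arm Patients per arm (1:1 allocation).
#' @param seed Integer master seed; expanded into per-patient substreams by
#'   a stable hash of the patient id, so adding patients never perturbs
#'   existing ones.
#' @param cadence_s Sampling cadence of the monitor, seconds.
#' @param baseline_map_mean,baseline_map_sd Population distribution of each
#'   patient's intraoperative baseline MAP, mmHg.
#' @param ou_reversion_rate Mean-reversion rate of the MAP process, 1/min.
#' @param ou_noise_sd Diffusion scale of the MAP process, mmHg per sqrt(min).
#' @param provocation_rate Rate of hypotensive provocations, events/hour.
#' @param provocation_depth_range Length-2 numeric, mmHg; each provocation
#'   shifts the MAP set-point by a draw from this (negative) range.
#' @param provocation_duration_mean Mean provocation duration, min
#'   (exponential, floored at 2 min).
#' @param index_alarm_threshold Alarm threshold on the predictive index.
#' @param index_noise_sd SD of the bounded noise added to the index proxy;
#'   0 gives the deterministic transform.
#' @param intervention_response_delay_s Upper bound, seconds, on the delay
#'   from alarm to treatment in the intervention arm (at most 120 s, the
#'   trial's two-minute action window).
#' @param control_detection_delay_s Typical delay, seconds, from hypotension
#'   onset to treatment in the control arm.
#' @param treatment_effect_amplitude_range Length-2 numeric, mmHg; pressure
#'   effect amplitude of one treatment.
#' @param treatment_effect_decay_min Exponential decay time constant of a
#'   treatment effect, min.
#' @param duration_lognorm_params Length-2 numeric `c(meanlog, sdlog)` of
#'   the surgical-duration distribution (minutes); the default centres the
#'   median near 490 min, typical of long oncological surgery.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_per_arm = 2, seed = 1)
#' cfg$cadence_s
#' @export
sim_config <- function(n_per_arm = 30,
                       seed = 1L,
                       cadence_s = 20,
                       baseline_map_mean = 85,
                       baseline_map_sd = 7,
                       ou_reversion_rate = 0.5,
                       ou_noise_sd = 3,
                       provocation_rate = 1.2,
                       provocation_depth_range = c(-35, -22),
                       provocation_duration_mean = 8,
                       index_alarm_threshold = 85,
                       index_noise_sd = 3,
                       intervention_response_delay_s = 120,
                       control_detection_delay_s = 40,
                       treatment_effect_amplitude_range = c(15, 30),
                       treatment_effect_decay_min = 20,
                       duration_lognorm_params = c(meanlog = log(490), sdlog = 0.4)) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm),
    seed = as.integer(seed),
    cadence_s = cadence_s,
    baseline_map_mean = baseline_map_mean,
    baseline_map_sd = baseline_map_sd,
    ou_reversion_rate = ou_reversion_rate,
    ou_noise_sd = ou_noise_sd,
    provocation_rate = provocation_rate,
    provocation_depth_range = sort(as.numeric(provocation_depth_range)),
    provocation_duration_mean = provocation_duration_mean,
    index_alarm_threshold = index_alarm_threshold,
    index_noise_sd = index_noise_sd,
    intervention_response_delay_s = intervention_response_delay_s,
    control_detection_delay_s = control_detection_delay_s,
    treatment_effect_amplitude_range = sort(as.numeric(treatment_effect_amplitude_range)),
    treatment_effect_decay_min = treatment_effect_decay_min,
    duration_lognorm_params = as.numeric(duration_lognorm_params)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "n_per_arm must be >= 1" = cfg$n_per_arm >= 1L,
    "cadence_s must be > 0" = cfg$cadence_s > 0,
    "index_alarm_threshold must lie in (0, 100)" =
      cfg$index_alarm_threshold > 0 && cfg$index_alarm_threshold < 100,
    "intervention_response_delay_s must be <= 120 s" =
      cfg$intervention_response_delay_s <= 120,
    "intervention_response_delay_s must be > 0" =
      cfg$intervention_response_delay_s > 0
  )
  nonneg <- c("baseline_map_sd", "ou_reversion_rate", "ou_noise_sd",
              "provocation_rate", "provocation_duration_mean",
              "index_noise_sd", "control_detection_delay_s",
              "treatment_effect_decay_min")
  for (f in nonneg) {
    if (cfg[[f]] < 0) stop(sprintf("'%s' must be >= 0", f), call. = FALSE)
  }
  if (length(cfg$duration_lognorm_params) != 2L)
    stop("duration_lognorm_params must be c(meanlog, sdlog)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat(sprintf("  %d patients per arm, seed %d, cadence %g s\n",
              x$n_per_arm, x$seed, x$cadence_s))
  cat(sprintf("  baseline MAP %g +/- %g mmHg; OU rate %g /min, noise %g\n",
              x$baseline_map_mean, x$baseline_map_sd,
              x$ou_reversion_rate, x$ou_noise_sd))
  cat(sprintf("  provocations %g /h, depth [%g, %g] mmHg, mean %g min\n",
              x$provocation_rate, x$provocation_depth_range[1],
              x$provocation_depth_range[2], x$provocation_duration_mean))
  cat(sprintf("  alarm threshold %g; response delays: intervention <= %g s, control ~%g s\n",
              x$index_alarm_threshold, x$intervention_response_delay_s,
              x$control_detection_delay_s))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds a flat key set mirroring [sim_config()] arguments; keys
#' absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

# Stable polynomial hash of a string; used to derive per-patient RNG
# substreams so the stream for patient k does not depend on n_per_arm.
stable_hash <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

patient_seed <- function(seed, patient_id) {
  as.integer((stable_hash(patient_id) + (as.numeric(seed) %% 65536) * 30011) %%
               2147483647)
}
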