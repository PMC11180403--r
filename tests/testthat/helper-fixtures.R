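# quick constructor for grid series used throughout the tests
make_series <- function(map, cadence_s = 20, patient_id = "t",
                        duration_min = NULL, index = NULL) {
  n <- length(map)
  if (is.null(duration_min)) duration_min <- (n - 1) * cadence_s / 60
  duration_min <- max(duration_min, (n - 1) * cadence_s / 60)
  vital_series(patient_id, time_s = (seq_len(n) - 1) * cadence_s,
               map_mmhg = map, cadence_s = cadence_s,
               surgical_duration_min = duration_min, index = index)
}

# random MAP trace wandering around 80 with occasional deep excursions
random_series <- function(n = 200, cadence_s = 20) {
  map <- 80 + cumsum(rnorm(n, 0, 2))
  map <- pmin(pmax(map, 30), 180)
  make_series(map, cadence_s = cadence_s)
}

# independently coded rectangle-sum oracle for the burden metrics
oracle_auc_below <- function(map, threshold, cadence_s) {
  total <- 0
  for (v in map) if (!is.na(v) && v < threshold) total <- total + (threshold - v)
  total * cadence_s / 60
}

oracle_duration_below <- function(map, threshold, cadence_s) {
  k <- 0
  for (v in map) if (!is.na(v) && v < threshold) k <- k + 1
  k * cadence_s / 60
}

default_cov <- function(id = "p1", arm = "control", duration = 300) {
  patient_covariates(id, arm, 60, "M", "pancreas", duration)
}
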