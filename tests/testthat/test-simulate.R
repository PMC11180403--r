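no_noise_cfg <- function(...) {
  sim_config(n_per_arm = 1, seed = 5, baseline_map_sd = 0,
             ou_noise_sd = 0, index_noise_sd = 0, provocation_rate = 0, ...)
}

test_that("with no disturbance and no noise the MAP trace is flat at baseline", {
  cfg <- no_noise_cfg()
  vs <- simulate_map_series(cfg, default_cov(duration = 60))
  expect_equal(unique(vs$map_mmhg), cfg$baseline_map_mean)
  expect_equal(vs$time_s, seq(0, 60 * 60, by = 20))
})

test_that("a forced provocation drags the deterministic path well below baseline", {
  cfg <- no_noise_cfg()
  prov <- data.frame(start_min = 20, depth = -25, duration_min = 12,
                     cause = "tone")
  vs <- simulate_map_series(cfg, default_cov(duration = 90),
                            provocations = prov)
  expect_lt(min(vs$map_mmhg), cfg$baseline_map_mean - 15)
  # and the trace returns toward baseline afterwards
  expect_gt(vs$map_mmhg[nrow(vs)], cfg$baseline_map_mean - 2)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_per_arm = 1, seed = 42)
  cov <- default_cov(duration = 120)
  a <- simulate_map_series(cfg, cov)
  b <- simulate_map_series(cfg, cov)
  expect_identical(a$map_mmhg, b$map_mmhg)
  ia <- simulate_index_series(a, cfg)
  ib <- simulate_index_series(b, cfg)
  expect_identical(ia$index, ib$index)
  ta <- simulate_treatments(a, ia, "control", cfg)
  tb <- simulate_treatments(b, ib, "control", cfg)
  expect_identical(ta$series$map_mmhg, tb$series$map_mmhg)
  expect_identical(ta$events, tb$events)
})

test_that("the index proxy stays calm on a healthy flat trace and is clamped", {
  cfg <- no_noise_cfg(baseline_map_mean = 90)
  vs <- simulate_map_series(cfg, default_cov(duration = 60))
  is_ <- simulate_index_series(vs, cfg)
  expect_true(all(is_$index < 85))

  cfg2 <- sim_config(n_per_arm = 1, seed = 9, provocation_rate = 3,
                     index_noise_sd = 15)
  vs2 <- simulate_map_series(cfg2, default_cov(duration = 200))
  is2 <- simulate_index_series(vs2, cfg2)
  expect_true(all(is2$index >= 0 & is2$index <= 100))
})

test_that("with noise off every sustained sub-65 crossing is preceded by an alarm", {
  for (seed in 1:5) {
    cfg <- sim_config(n_per_arm = 1, seed = seed, ou_noise_sd = 0,
                      index_noise_sd = 0)
    vs <- simulate_map_series(cfg, default_cov(id = paste0("p", seed),
                                               duration = 400))
    is_ <- simulate_index_series(vs, cfg)
    onsets <- detect_hypotension_events(is_)
    if (nrow(onsets) == 0) next
    for (t0 in onsets$time_s) {
      lead_samples <- is_$index[is_$time_s < t0] > 85
      expect_true(any(lead_samples))
      # earliest exceedance strictly precedes the crossing
      expect_lt(min(is_$time_s[is_$index > 85]), t0)
    }
    # and the silent-alarm reconstruction finds every anchor
    anchors <- event_anchors(merge_events(onsets))
    sat <- silent_alarm_times(is_, anchors)
    expect_length(sat$unreconstructable, 0)
    expect_true(all(sat$sat$time_s <= sat$sat$anchor_time_s))
  }
})

test_that("a quiet case yields an empty treatment log", {
  cfg <- no_noise_cfg()
  vs <- simulate_map_series(cfg, default_cov(duration = 60))
  is_ <- simulate_index_series(vs, cfg)
  for (arm in c("intervention", "control")) {
    tr <- simulate_treatments(vs, is_, arm, cfg)
    expect_equal(sum(tr$events$event_type == "treatment"), 0L)
  }
  expect_error(simulate_treatments(vs, is_, "placebo", cfg), "arg")
})

test_that("intervention treatments follow each merged alarm within two minutes", {
  cfg <- sim_config(n_per_arm = 1, seed = 17, ou_noise_sd = 0,
                    index_noise_sd = 0)
  prov <- data.frame(start_min = c(30, 120), depth = c(-30, -28),
                     duration_min = c(8, 8), cause = c("tone", "preload"))
  vs <- simulate_map_series(cfg, default_cov(duration = 200),
                            provocations = prov)
  is_ <- simulate_index_series(vs, cfg)
  tr <- simulate_treatments(vs, is_, "intervention", cfg)
  alarms <- tr$events[tr$events$event_type == "alarm", ]
  anchors <- event_anchors(merge_events(alarms))
  treatments <- tr$events[tr$events$event_type == "treatment", ]
  lat <- compute_latencies(anchors, treatments, anchor_type = "AT")
  expect_true(all(lat$treated))
  expect_true(all(lat$latency_s > 0))
  expect_true(all(lat$latency_s <= 120))
})

test_that("treatment effects reduce the hypotension burden on the same noise path", {
  cfg <- sim_config(n_per_arm = 1, seed = 23)
  cov <- default_cov(duration = 300)
  vs <- simulate_map_series(cfg, cov)
  is_ <- simulate_index_series(vs, cfg)
  untreated_twa <- twa_below(vs, 65)
  for (arm in c("intervention", "control")) {
    tr <- simulate_treatments(vs, is_, arm, cfg)
    expect_lte(twa_below(tr$series, 65), untreated_twa)
  }
})

test_that("generate_cohort allocates 1:1, is reproducible, and writes the bundle", {
  cfg <- sim_config(n_per_arm = 3, seed = 31)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  b1 <- generate_cohort(cfg, out_dir = d1)
  b2 <- generate_cohort(cfg, out_dir = d2)
  expect_equal(nrow(b1$cohort), 6L)
  expect_equal(sum(b1$cohort$arm == "intervention"), 3L)
  expect_setequal(basename(b1$paths),
                  c("cohort.csv",
                    paste0("vitals_", b1$cohort$patient_id, ".csv"),
                    paste0("events_", b1$cohort$patient_id, ".csv")))
  # byte-identical outputs under the same seed
  for (f in basename(b1$paths)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # vitals round-trip preserves the burden metrics
  pid <- b1$cohort$patient_id[1]
  back <- read_vitals_csv(file.path(d1, paste0("vitals_", pid, ".csv")),
                          surgical_duration_min =
                            attr(b1$series[[pid]], "surgical_duration_min"))
  expect_equal(auc_below(back, 65), auc_below(b1$series[[pid]], 65),
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("per-patient substreams do not shift when the cohort grows", {
  cfg3 <- sim_config(n_per_arm = 2, seed = 8)
  cfg5 <- sim_config(n_per_arm = 4, seed = 8)
  b3 <- generate_cohort(cfg3)
  b5 <- generate_cohort(cfg5)
  for (pid in b3$cohort$patient_id) {
    expect_identical(b3$series[[pid]]$map_mmhg, b5$series[[pid]]$map_mmhg)
  }
})

test_that("cohort covariates stay in the calibrated demographic bands", {
  meds <- vapply(1:10, function(s) {
    b <- generate_cohort(sim_config(n_per_arm = 6, seed = 100 + s))
    median(b$cohort$age)
  }, 0)
  expect_true(all(meds >= 50 & meds <= 70))
  b <- generate_cohort(sim_config(n_per_arm = 10, seed = 55))
  expect_true(all(b$cohort$age >= 20 & b$cohort$age <= 80))
  expect_true(all(b$cohort$surgical_duration > 0))
  expect_true(all(b$cohort$surgery_type %in% c("pancreas", "oral", "esophagus")))
})
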