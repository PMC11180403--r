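test_that("hypotensive episodes require one sustained minute below 65", {
  # two sub-65 samples (40 s) then recovery: no event
  vs <- make_series(c(80, 60, 60, 80, 80, 80))
  expect_equal(nrow(detect_hypotension_events(vs)), 0L)

  # three consecutive sub-65 samples starting at t = 100 s
  map <- rep(80, 12); map[6:8] <- 60
  vs <- make_series(map)
  ev <- detect_hypotension_events(vs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_s, 100)
})

test_that("episode detection equals a run-length oracle on random series", {
  set.seed(501)
  for (i in 1:100) {
    vs <- random_series(150)
    ev <- detect_hypotension_events(vs)
    # oracle: scan runs manually
    below <- vs$map_mmhg < 65
    onsets <- c()
    run <- 0
    for (k in seq_along(below)) {
      run <- if (below[k]) run + 1 else 0
      if (run == 3) onsets <- c(onsets, vs$time_s[k - 2])
    }
    expect_equal(ev$time_s,
                 if (is.null(onsets)) numeric(0) else as.numeric(onsets))
  }
})

test_that("alarms fire once per strict upward crossing of the threshold", {
  vs <- make_series(rep(80, 10), index = rep(85, 10))
  expect_equal(nrow(detect_alarm_events(vs)), 0L)  # strict exceedance

  idx <- c(80, 80, 80, 80, 80, 80, 80, 80, 80, 80, 90, 90, 90)
  vs <- make_series(rep(80, 13), index = idx)
  ev <- detect_alarm_events(vs)
  expect_equal(ev$time_s, 200)

  # oscillation: one alarm per upward crossing, before merging
  set.seed(502)
  for (i in 1:50) {
    idx <- runif(120, 70, 100)
    vs <- make_series(rep(80, 120), index = idx)
    ev <- detect_alarm_events(vs)
    above <- idx > 85
    crossings <- sum(above & !c(FALSE, head(above, -1)))
    expect_equal(nrow(ev), crossings)
  }
  expect_error(detect_alarm_events(make_series(rep(80, 5))), "index")
})

test_that("merging is anchored at the first event, not chained", {
  mk <- function(min_times) clinical_events("p", min_times * 60, "alarm")
  m <- merge_events(mk(c(0, 5, 12)))
  expect_equal(sum(is.na(m$merged_into)), 1L)
  expect_equal(m$merged_into[-1], c(0, 0))

  m <- merge_events(mk(c(0, 16)))
  expect_equal(sum(is.na(m$merged_into)), 2L)

  # chained merging would put 28 into the window extended by the event at 14
  m <- merge_events(mk(c(0, 14, 28)))
  expect_equal(event_anchors(m)$time_s, c(0, 28) * 60)

  expect_error(merge_events(clinical_events("p", c(1, 2),
                                            c("alarm", "hypotension_onset"))),
               "single type")
})

test_that("anchored merging semantics hold on enumerated configurations", {
  # exhaustively check all event patterns on a 5-slot grid of 8-min spacing
  for (mask in 1:31) {
    times <- (which(bitwAnd(mask, 2^(0:4)) > 0) - 1) * 8 * 60
    ev <- clinical_events("p", times, "alarm")
    m <- merge_events(ev, window_min = 15)
    anchors <- event_anchors(m)$time_s
    # oracle: greedy scan
    exp_anchor <- c()
    cur <- -Inf
    for (t in times) {
      if (t - cur >= 15 * 60) { cur <- t; exp_anchor <- c(exp_anchor, t) }
    }
    expect_equal(anchors, exp_anchor)
    # invariants: spacing, conservation, idempotence
    expect_true(all(diff(anchors) >= 15 * 60))
    expect_equal(nrow(m), length(times))
    m2 <- merge_events(event_anchors(m), window_min = 15)
    expect_true(all(is.na(m2$merged_into)))
    # every merged member points to the anchor at or before it
    mem <- m[!is.na(m$merged_into), ]
    if (nrow(mem)) {
      expect_true(all(mem$time_s - mem$merged_into > 0))
      expect_true(all(mem$time_s - mem$merged_into < 15 * 60))
    }
  }
})

test_that("silent alarms are the earliest index exceedance before the onset", {
  n <- 61  # 20 min
  idx <- rep(50, n)
  idx[(6 * 3 + 1):n] <- 90  # index exceeds 85 from t = 6 min on
  map <- rep(80, n)
  map[(12 * 3 + 1):n] <- 60  # hypotension onset at t = 12 min
  vs <- make_series(map, index = idx)
  anchors <- event_anchors(merge_events(detect_hypotension_events(vs)))
  sat <- silent_alarm_times(vs, anchors)
  expect_equal(nrow(sat$sat), 1L)
  expect_equal(sat$sat$time_s, 6 * 60)
  expect_lte(sat$sat$time_s, sat$sat$anchor_time_s)

  # no exceedance in the window: unreconstructable
  vs2 <- make_series(map, index = rep(50, n))
  sat2 <- silent_alarm_times(vs2, anchors)
  expect_equal(nrow(sat2$sat), 0L)
  expect_equal(sat2$unreconstructable, anchors$time_s)
})

test_that("latencies match the first in-window treatment at or after the anchor", {
  anchors <- data.frame(patient_id = "p", time_s = 600)
  tr <- clinical_events("p", c(580, 650), "treatment", "fluid")
  lat <- compute_latencies(anchors, tr)
  expect_equal(lat$latency_s, 50)

  # no treatment within 15 min: untreated record
  tr2 <- clinical_events("p", 600 + 16 * 60, "treatment", "fluid")
  lat2 <- compute_latencies(anchors, tr2)
  expect_false(lat2$treated)
  expect_true(is.na(lat2$latency_s))

  # a treatment satisfies only one anchor (greedy earliest-first)
  anchors3 <- data.frame(patient_id = "p", time_s = c(0, 1200))
  tr3 <- clinical_events("p", c(100, 1300), "treatment", "fluid")
  lat3 <- compute_latencies(anchors3, tr3)
  expect_equal(lat3$latency_s, c(100, 100))
})

test_that("event logs round-trip through CSV", {
  ev <- clinical_events("p9", c(10, 400, 430), c("alarm", "hypotension_onset",
                                                 "treatment"),
                        c("", "", "vasopressor"))
  p <- tempfile(fileext = ".csv")
  write_events_csv(ev, p)
  back <- read_events_csv(p, "p9")
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$event_type, ev$event_type)
  expect_equal(back$detail, ev$detail)
  unlink(p)
})
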