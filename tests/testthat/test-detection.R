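cfg <- detection_config()

test_that("speeding uses a strict grace boundary and 10-s re-warnings", {
  spec <- mini_spec(limit = 50)
  # exactly limit + grace is compliant
  expect_equal(nrow(detect_speeding(seg_stream(list(v = 60, dur = 30)),
                                    spec, cfg)), 0)
  # persistent violation: onset, +10 s, +20 s
  err <- detect_speeding(seg_stream(list(v = 61, dur = 25)), spec, cfg)
  expect_equal(nrow(err), 3)
  expect_equal(err$t[2] - err$t[1], 10, tolerance = 0.11)
  expect_equal(err$t[3] - err$t[1], 20, tolerance = 0.11)
  # short violation: single error
  short <- seg_stream(list(v = 61, dur = 4), list(v = 55, dur = 10))
  expect_equal(nrow(detect_speeding(short, spec, cfg)), 1)
  # episode counting mode records one error per episode
  cfg1 <- detection_config(count_rewarnings = FALSE)
  expect_equal(nrow(detect_speeding(seg_stream(list(v = 61, dur = 25)),
                                    spec, cfg1)), 1)
})

test_that("speeding limit comes from the zone under the vehicle", {
  spec <- ref_spec()
  run <- ref_compliant()
  bumped <- run
  idx <- which(bumped$s > 11000 & bumped$s < 11100) # inside a 70 zone
  bumped$speed[idx] <- 75 # legal in a 70 zone, illegal in a 50 zone
  expect_equal(nrow(detect_speeding(bumped, spec, cfg)), 0)
  idx50 <- which(bumped$s > 500 & bumped$s < 560) # inside the first 50 zone
  bumped$speed[idx50] <- 75
  expect_equal(nrow(detect_speeding(bumped, spec, cfg)), 1)
})

test_that("tailgating thresholds on a 2-s time headway", {
  spec <- mini_spec()
  base <- seg_stream(list(v = 50, dur = 8))
  # the printed worked example: 27.8 m at 50 km/h is just over 2 s
  ok <- base; ok$lead_gap <- 27.8
  expect_equal(nrow(detect_tailgating(ok, spec, cfg)), 0)
  # 20 m at 50 km/h is 1.44 s; an episode shorter than the re-warning
  # window records exactly one error
  bad <- base; bad$lead_gap <- 20
  expect_equal(nrow(detect_tailgating(bad, spec, cfg)), 1)
  # exact boundary: 40 m at 72 km/h (20 m/s) is exactly 2 s
  b72 <- seg_stream(list(v = 72, dur = 15)); b72$lead_gap <- 40
  expect_equal(nrow(detect_tailgating(b72, spec, cfg)), 0)
  # standing still with a lead present is compliant (headway undefined)
  still <- seg_stream(list(v = 0, dur = 15)); still$lead_gap <- 3
  still$s <- still$s + seq_len(nrow(still)) * 1e-9
  expect_equal(nrow(detect_tailgating(still, spec, cfg)), 0)
  # persisting violation re-warns after 10 s
  long_bad <- seg_stream(list(v = 50, dur = 25)); long_bad$lead_gap <- 20
  expect_equal(nrow(detect_tailgating(long_bad, spec, cfg)), 3)
})

test_that("weaving needs both offset beyond 17.5% and 10-s persistence", {
  spec <- mini_spec()
  thr <- cfg$weave_fraction * spec$lane_width # 0.6125 m
  mk <- function(offset, dur, tail = 5) {
    st <- seg_stream(list(v = 50, dur = dur + tail))
    st$lateral_offset[st$t <= dur] <- offset
    st
  }
  expect_equal(nrow(detect_weaving(mk(0.62, 10.5), spec, cfg)), 1)
  expect_equal(nrow(detect_weaving(mk(0.60, 60, 0), spec, cfg)), 0)
  expect_equal(nrow(detect_weaving(mk(0.70, 9.9), spec, cfg)), 0)
  expect_equal(nrow(detect_weaving(mk(thr, 60, 0), spec, cfg)), 0) # boundary
  # a 25-s excursion: persistence clock resets after each emission
  expect_equal(nrow(detect_weaving(mk(0.70, 25), spec, cfg)), 2)
})

test_that("weaving ignores samples around a lane-boundary crossing", {
  spec <- mini_spec()
  st <- seg_stream(list(v = 50, dur = 30))
  st$lane_index[st$t >= 15] <- 1L
  st$lateral_offset[st$t >= 13.2 & st$t <= 16.8] <- 1.7
  expect_equal(nrow(detect_weaving(st, spec, cfg)), 0)
})

test_that("lane changes check signal and blind-spot within the window", {
  spec <- mini_spec()
  mk <- function(signal = TRUE, yaw = 50) {
    st <- seg_stream(list(v = 50, dur = 30))
    st$lane_index[st$t >= 15] <- 1L
    if (signal) st$turn_signal[st$t >= 13 & st$t < 15] <- "left"
    st$head_yaw[st$t >= 13.5 & st$t < 14.2] <- yaw
    st
  }
  compliant <- detect_lane_changes(mk(), spec, cfg)
  expect_equal(nrow(compliant$events), 1)
  expect_true(compliant$events$signaled)
  expect_true(compliant$events$blindspot_checked)
  expect_equal(nrow(compliant$errors), 0)

  no_sig <- detect_lane_changes(mk(signal = FALSE), spec, cfg)
  expect_equal(no_sig$errors$kind, "signal_omission")

  neither <- detect_lane_changes(mk(signal = FALSE, yaw = 20), spec, cfg)
  expect_setequal(neither$errors$kind,
                  c("signal_omission", "blindspot_omission"))

  # wrong-direction signal does not count
  wrong <- mk(signal = FALSE)
  wrong$turn_signal[wrong$t >= 13 & wrong$t < 15] <- "right"
  expect_true("signal_omission" %in%
                detect_lane_changes(wrong, spec, cfg)$errors$kind)
  # signal outside the window does not count
  early <- mk(signal = FALSE)
  early$turn_signal[early$t >= 10 & early$t < 11.5] <- "left"
  expect_true("signal_omission" %in%
                detect_lane_changes(early, spec, cfg)$errors$kind)
})

stop_sign_spec <- function() {
  mini_spec(intersections = tibble::tibble(
    position = 800, control = "stop-sign", intersection_length = 20,
    light_schedule = list(NULL)
  ))
}

stop_stream <- function(dip_speed = 0.5, dwell = 1.5, stop_at = 799,
                        scan = TRUE) {
  # approach at 36 km/h to just before the line, dwell, then continue
  appr <- (stop_at - 0) / 10
  st <- seg_stream(list(v = 36, dur = appr), list(v = dip_speed, dur = dwell),
                   list(v = 36, dur = 15))
  if (scan) {
    t0 <- appr
    st$head_yaw[st$t >= t0 & st$t < t0 + 0.4] <- 40
    st$head_yaw[st$t >= t0 + 0.5 & st$t < t0 + 0.6] <- 0
    st$head_yaw[st$t >= t0 + 0.7 & st$t < t0 + 1.1] <- -40
  }
  st
}

test_that("stop-sign control requires a complete stop before the line", {
  spec <- stop_sign_spec()
  expect_equal(nrow(detect_stop_sign_control(stop_stream(), spec, cfg)), 0)
  rolling <- stop_stream(dip_speed = 3)
  err <- detect_stop_sign_control(rolling, spec, cfg)
  expect_equal(nrow(err), 1)
  expect_match(err$detail, "no complete stop")
  # full stop past the line
  past <- stop_stream(stop_at = 800.5)
  err2 <- detect_stop_sign_control(past, spec, cfg)
  expect_equal(nrow(err2), 1)
  expect_match(err2$detail, "beyond the stop line")
  # a sub-second dip does not count as a stop
  blip <- stop_stream(dip_speed = 0.5, dwell = 0.9)
  expect_equal(nrow(detect_stop_sign_control(blip, spec, cfg)), 1)
})

test_that("visual search needs left, right and an ahead return", {
  spec <- stop_sign_spec()
  expect_equal(nrow(detect_visual_search(stop_stream(), spec, cfg)), 0)
  no_scan <- stop_stream(scan = FALSE)
  expect_equal(nrow(detect_visual_search(no_scan, spec, cfg)), 1)
  left_only <- stop_stream(scan = FALSE)
  left_only$head_yaw[left_only$t >= 79.9 & left_only$t < 80.3] <- 40
  expect_equal(nrow(detect_visual_search(left_only, spec, cfg)), 1)
  # small glances below 30 degrees do not count
  small <- stop_stream(scan = FALSE)
  small$head_yaw[small$t >= 79.9 & small$t < 80.3] <- 10
  small$head_yaw[small$t >= 80.4 & small$t < 80.8] <- -10
  expect_equal(nrow(detect_visual_search(small, spec, cfg)), 1)
})

redlight_spec <- function() {
  mini_spec(intersections = tibble::tibble(
    position = 500, control = "traffic-light", intersection_length = 20,
    light_schedule = list(light_cycle()) # green 0-30, yellow 30-34, red 34-54
  ))
}

cross_stream <- function(entry_t, stop_at = NA, stop_from = NA, stop_dur = 10) {
  # approach at 10 m/s reaching the line (500 m) at entry_t, then cross at
  # 1 m/s; optionally stop at `stop_at` metres from `stop_from` seconds.
  dt <- 0.1
  t <- seq(dt, entry_t + 60, by = dt)
  s <- ifelse(t <= entry_t, 500 - 10 * (entry_t - t), 500 + (t - entry_t))
  v <- ifelse(t <= entry_t, 36, 3.6)
  if (!is.na(stop_at)) {
    hold <- t >= stop_from & t < stop_from + stop_dur
    s[hold] <- stop_at
    v[hold] <- 0
    after <- t >= stop_from + stop_dur
    s[after] <- stop_at + (t[after] - (stop_from + stop_dur))
  }
  keep <- s >= 0
  telemetry_stream(tibble::tibble(
    t = t[keep], s = cummax(s[keep]), lateral_offset = 0, speed = v[keep],
    accel_pedal = 0, brake_pedal = 0, turn_signal = "none", head_yaw = 0,
    lane_index = 0L, lead_gap = NA_real_
  ))
}

test_that("permissive yellow: only red-before-midpoint after yellow entry", {
  spec <- redlight_spec()
  # enters on green at t=25; midpoint at t=35 is red, but entry was legal
  expect_equal(nrow(detect_redlight_control(cross_stream(25), spec, cfg)), 0)
  # enters on yellow at t=33; red arrives before the midpoint (t=43)
  err <- detect_redlight_control(cross_stream(33), spec, cfg)
  expect_equal(nrow(err), 1)
  expect_match(err$detail, "entered on yellow")
  # enters early in green and clears: no error
  expect_equal(nrow(detect_redlight_control(cross_stream(5), spec, cfg)), 0)
})

test_that("stopping beyond the line on red is a traffic-light error", {
  spec <- redlight_spec()
  # enter on green at t=29, roll to 505, stand there through the red phase
  st <- cross_stream(29, stop_at = 505, stop_from = 36, stop_dur = 10)
  err <- detect_redlight_control(st, spec, cfg)
  expect_equal(nrow(err), 1)
  expect_match(err$detail, "beyond the stop line on red")
})

test_that("the refractory suppresses feedback but never counts", {
  spec <- mini_spec()
  st <- seg_stream(list(v = 61, dur = 1), list(v = 55, dur = 7),
                   list(v = 61, dur = 1), list(v = 55, dur = 5),
                   list(v = 61, dur = 2))
  # speeding onsets at ~0.1, ~8.1, ~14.1 s
  rep <- run_engine(st, spec, cfg)
  expect_equal(unname(rep$counts["speeding"]), 3)
  expect_equal(rep$errors$feedback_emitted, c(TRUE, TRUE, FALSE))
  # counts identical under a much shorter refractory
  rep2 <- run_engine(st, spec, detection_config(feedback_refractory = 0.001))
  expect_identical(rep2$counts, rep$counts)
  expect_equal(sum(rep2$errors$feedback_emitted), 3)
})

test_that("identical inputs give identical reports", {
  spec <- ref_spec()
  run <- ref_compliant()
  r1 <- run_engine(run, spec, cfg)
  r2 <- run_engine(run, spec, cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$errors, r2$errors)
})
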