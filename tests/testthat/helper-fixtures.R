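# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

ref_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- build_reference_scenario()
  .fixtures$spec
}

ref_compliant <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_compliant_run(ref_spec(), seed = seed)
  }
  .fixtures[[key]]
}

empty_intersections <- function() {
  tibble::tibble(position = numeric(), control = character(),
                 intersection_length = numeric(),
                 light_schedule = list())
}

empty_lane_changes <- function() {
  tibble::tibble(position = numeric(), direction = character(),
                 kind = character())
}

empty_leads <- function() {
  tibble::tibble(appear_position = numeric(), speed_profile = list())
}

# Minimal single-zone scenario for detector unit tests.
mini_spec <- function(limit = 50, len = 3000,
                      intersections = empty_intersections(),
                      lane_changes = empty_lane_changes(),
                      leads = empty_leads(), lane_width = 3.5) {
  scenario_spec(
    zones = tibble::tibble(start_position = 0, length = len, limit = limit),
    intersections = intersections, lane_changes = lane_changes,
    leads = leads, lane_width = lane_width
  )
}

# Telemetry from piecewise-constant speed segments: each segment is
# list(v = speed in km/h, dur = seconds). Position integrates the speed.
seg_stream <- function(..., dt = 0.1, s0 = 0) {
  segs <- list(...)
  v <- unlist(lapply(segs, function(g) rep(g$v, round(g$dur / dt))))
  n <- length(v)
  telemetry_stream(tibble::tibble(
    t = seq_len(n) * dt,
    s = s0 + cumsum(v / 3.6 * dt),
    lateral_offset = 0, speed = v, accel_pedal = 0, brake_pedal = 0,
    turn_signal = "none", head_yaw = 0, lane_index = 0L,
    lead_gap = NA_real_
  ))
}
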