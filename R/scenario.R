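#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# The eight error kinds scored by the engine, in canonical order.
#' Error kinds scored by the detection engine
#'
#' Returns the canonical vector of the eight driving-error kinds, in the
#' order used throughout the package: speeding, tailgating, weaving,
#' turn-signal omission at a lane change, blind-spot omission at a lane
#' change, vehicle control at stop-sign intersections, visual search at
#' stop-sign intersections, and vehicle control at red-light intersections.
#'
#' @return Character vector of length 8.
#' @export
error_kinds <- function() {
  c("speeding", "tailgating", "weaving", "signal_omission",
    "blindspot_omission", "stop_control", "visual_search",
    "redlight_control")
}

#' Construct a scenario specification
#'
#' A scenario describes the static route shared by the detection engine and
#' the synthetic-cohort generator: speed zones that tile the route,
#' intersections (stop-sign or traffic-light controlled), lane-change
#' prompts, and lead-vehicle episodes. All positions are metres from the
#' route origin; zone intervals are half-open `[start, start + length)`.
#'
#' @param zones Tibble with columns `start_position`, `length`, `limit`
#'   (km/h).
#' @param intersections Tibble with columns `position` (stop line, m),
#'   `control` (`"stop-sign"` or `"traffic-light"`), `intersection_length`
#'   (m), and a `light_schedule` list-column (one-cycle phase table per
#'   traffic light, `NULL` for stop signs; see [light_cycle()]).
#' @param lane_changes Tibble with columns `position`, `direction`
#'   (`"left"`/`"right"`), `kind` (`"commanded"`/`"merge"`).
#' @param leads Tibble with columns `appear_position` and a `speed_profile`
#'   list-column of `(position, speed)` tibbles; the last profile position
#'   is the end of the episode.
#' @param lane_width Lane width in metres (default 3.5).
#' @param vehicle_width Vehicle width in metres (default 1.975). The
#'   defaults jointly place the weaving threshold (17.5% of lane width,
#'   0.6125 m) at the point where the tires sit 15 cm from the nearest
#'   lane line: 3.5/2 - 0.6125 - 1.975/2 = 0.15 m.
#' @param total_length Total route length in metres; must equal the sum of
#'   zone lengths.
#' @return An object of class `scenario_spec`.
#' @seealso [build_reference_scenario()], [validate_scenario()], [zone_at()]
#' @export
scenario_spec <- function(zones, intersections, lane_changes, leads,
                          lane_width = 3.5, vehicle_width = 1.975,
                          total_length = sum(zones$length)) {
  spec <- structure(
    list(
      zones = as_tibble(zones),
      intersections = as_tibble(intersections),
      lane_changes = as_tibble(lane_changes),
      leads = as_tibble(leads),
      lane_width = lane_width,
      vehicle_width = vehicle_width,
      total_length = total_length
    ),
    class = "scenario_spec"
  )
  spec
}

#' One traffic-light cycle
#'
#' Builds the phase table for one signal cycle. Phases are contiguous and
#' repeat with period `sum(durations)`; `onset` values are absolute seconds
#' from the start of the run, taken modulo the cycle length.
#'
#' @param green_onset Second (mod cycle length) at which green begins.
#' @param green,yellow,red Phase durations in seconds.
#' @return Tibble with columns `phase`, `onset`, `duration`.
#' @export
light_cycle <- function(green_onset = 0, green = 30, yellow = 4, red = 20) {
  cycle <- green + yellow + red
  tibble(
    phase = c("green", "yellow", "red"),
    onset = c(green_onset, green_onset + green, green_onset + green + yellow) %% cycle,
    duration = c(green, yellow, red)
  )
}

#' Signal phase at a time point
#'
#' @param schedule A phase table from [light_cycle()].
#' @param t Time(s) in seconds from run start.
#' @return Character vector of phases (`"green"`, `"yellow"`, `"red"`).
#' @export
phase_at <- function(schedule, t) {
  cycle <- sum(schedule$duration)
  tt <- t %% cycle
  out <- character(length(tt))
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i] %% cycle
    end <- on + schedule$duration[i]
    inside <- (tt >= on & tt < end) | (end > cycle & tt < (end - cycle))
    out[inside] <- schedule$phase[i]
  }
  out
}

# Seconds until the next green onset (0 if currently green).
next_green_wait <- function(schedule, t) {
  if (phase_at(schedule, t) == "green") return(0)
  cycle <- sum(schedule$duration)
  g_on <- schedule$onset[schedule$phase == "green"][1] %% cycle
  (g_on - t) %% cycle
}

#' Build the reference training scenario
#'
#' Constructs the packaged 27.48-km reference route: speed zones totalling
#' 650 m at 35 km/h, 12,570 m at 50 km/h and 14,260 m at 70 km/h,
#' interleaved into nine subsections so that slow urban segments sit around
#' stop-sign clusters; 15 lane-change prompts (seven overtake pairs plus one
#' merge); 8 stop-sign and 4 traffic-light intersections; and 5 lead-vehicle
#' episodes. Traffic-light cycles are phased so that a compliant driver
#' arriving at the nominal route timing meets the light mid-red and waits
#' for green, which both forces realistic full stops and makes every light a
#' usable site for red-light violation injection.
#'
#' The layout is deterministic: repeated calls return identical objects.
#'
#' @return A `scenario_spec`.
#' @export
build_reference_scenario <- function() {
  zones <- tibble(
    start_position = c(0, 3000, 7000, 7325, 10325, 14325, 14650, 18220, 24480),
    length = c(3000, 4000, 325, 3000, 4000, 325, 3570, 6260, 3000),
    limit = c(50, 70, 35, 50, 70, 35, 50, 70, 50)
  )

  inter_pos <- c(1200, 2400, 7100, 7250, 8200, 9300, 14400, 14550, # stop signs
                 15200, 16600, 25000, 26300)                       # lights
  control <- c(rep("stop-sign", 8), rep("traffic-light", 4))
  intersections <- tibble(
    position = inter_pos,
    control = control,
    intersection_length = 20,
    light_schedule = vector("list", length(inter_pos))
  )

  pair_starts <- c(4000, 5500, 10800, 12300, 18700, 20500, 22500)
  lane_changes <- tibble(
    position = c(3500, as.vector(rbind(pair_starts, pair_starts + 400))),
    direction = c("left", rep(c("left", "right"), times = 7)),
    kind = c("merge", rep("commanded", 14))
  )
  lane_changes <- lane_changes[order(lane_changes$position), ]

  lead_start <- c(300, 6000, 9500, 13000, 21500)
  lead_end <- c(1000, 6800, 10200, 13800, 22300)
  leads <- tibble(
    appear_position = lead_start,
    speed_profile = lapply(seq_along(lead_start), function(i) {
      tibble(position = c(lead_start[i], lead_end[i]),
             speed = c(NA_real_, NA_real_))
    })
  )
  spec <- scenario_spec(zones, intersections, lane_changes, leads)
  # lead speed = local limit (compliant following pace)
  for (i in seq_along(lead_start)) {
    lim <- spec$zones$limit[findInterval(lead_start[i], spec$zones$start_position)]
    spec$leads$speed_profile[[i]]$speed <- c(lim, lim)
  }
  assign_light_schedules(spec)
}

# Phase each traffic light so the nominal compliant arrival is 8 s into red
# (12 s of red remaining). Arrival times come from the same route-timing
# routine the generator uses, processed in position order so that waits at
# upstream lights shift downstream arrivals.
assign_light_schedules <- function(spec, red_elapsed = 8) {
  prof <- route_speed_profile(spec)
  ev <- spec$intersections[order(spec$intersections$position), ]
  added <- 0
  for (i in seq_len(nrow(ev))) {
    ds <- prof$s[2] - prof$s[1]
    idx <- slow_point_index(ev$position[i], ds)
    t_arr <- prof$t[idx] + added
    if (ev$control[i] == "stop-sign") {
      added <- added + stop_dwell_s()
    } else {
      cyc <- light_cycle()
      cycle <- sum(cyc$duration)
      red_on <- cyc$onset[cyc$phase == "red"]
      red_dur <- cyc$duration[cyc$phase == "red"]
      # want (t_arr - shift) mod cycle to land red_elapsed s into red
      shift <- (t_arr - red_on - red_elapsed) %% cycle
      sched <- light_cycle(green_onset = shift %% cycle)
      j <- which(spec$intersections$position == ev$position[i])
      spec$intersections$light_schedule[[j]] <- sched
      added <- added + (red_dur - red_elapsed) + light_settle_s()
    }
  }
  spec
}

# Fixed generator timing constants shared by the scenario builder (which
# must predict arrival times) and the trajectory generator.
stop_dwell_s <- function() 1.6
light_settle_s <- function() 0.3

#' Validate a scenario specification
#'
#' Checks every structural invariant of a [scenario_spec()]: positive zone
#' lengths, gap- and overlap-free zone tiling summing to `total_length`,
#' intersections and prompts inside the route, contiguous light schedules
#' for every traffic light, non-negative lead speeds, and
#' `lane_width > vehicle_width > 0`. Violations are returned as data, not
#' raised as conditions.
#'
#' @param spec A `scenario_spec`.
#' @return Character vector of violation messages; empty if the scenario is
#'   valid. Each message names the offending element.
#' @export
validate_scenario <- function(spec) {
  v <- character()
  z <- spec$zones[order(spec$zones$start_position), ]
  if (any(z$length <= 0)) {
    v <- c(v, paste0("zone ", which(z$length <= 0), ": non-positive length"))
  }
  if (nrow(z) > 0) {
    if (z$start_position[1] != 0) {
      v <- c(v, "zone 1: tiling does not start at 0")
    }
    ends <- z$start_position + z$length
    if (nrow(z) > 1) {
      nxt <- z$start_position[-1]
      bad <- which(abs(ends[-nrow(z)] - nxt) > 1e-9)
      for (b in bad) {
        rel <- if (ends[b] > nxt[b]) "overlap" else "gap"
        v <- c(v, paste0("zones ", b, " and ", b + 1, ": ", rel, " in tiling"))
      }
    }
    if (abs(sum(z$length) - spec$total_length) > 1e-9) {
      v <- c(v, paste0("total_length ", spec$total_length,
                       " does not equal sum of zone lengths ", sum(z$length)))
    }
  }
  it <- spec$intersections
  for (i in seq_len(nrow(it))) {
    if (it$position[i] < 0 || it$position[i] >= spec$total_length) {
      v <- c(v, paste0("intersection ", i, ": position outside route"))
    }
    if (it$control[i] == "traffic-light") {
      sched <- it$light_schedule[[i]]
      if (is.null(sched)) {
        v <- c(v, paste0("intersection ", i, ": traffic light without schedule"))
      } else {
        cyc <- sum(sched$duration)
        ends <- (sched$onset + sched$duration) %% cyc
        nxt <- sched$onset[c(2:nrow(sched), 1)] %% cyc
        if (any(abs(ends - nxt) > 1e-9)) {
          v <- c(v, paste0("intersection ", i, ": light phases not contiguous"))
        }
      }
    }
  }
  lc <- spec$lane_changes
  if (any(lc$position < 0 | lc$position >= spec$total_length)) {
    v <- c(v, "lane change prompt outside route")
  }
  for (i in seq_len(nrow(spec$leads))) {
    sp <- spec$leads$speed_profile[[i]]
    if (any(sp$speed < 0)) {
      v <- c(v, paste0("lead ", i, ": negative speed"))
    }
    if (any(sp$position < spec$leads$appear_position[i])) {
      v <- c(v, paste0("lead ", i, ": profile point behind spawn"))
    }
  }
  if (!(spec$lane_width > spec$vehicle_width && spec$vehicle_width > 0)) {
    v <- c(v, "lane_width must exceed vehicle_width which must be positive")
  }
  v
}

#' Speed zone containing a position
#'
#' Zone intervals are half-open `[start, start + length)`, so every position
#' in `[0, total_length)` belongs to exactly one zone and `total_length`
#' itself is out of range.
#'
#' @param spec A `scenario_spec`.
#' @param position Position in metres from the route origin.
#' @return One-row tibble (the zone).
#' @export
zone_at <- function(spec, position) {
  if (length(position) != 1 || is.na(position) ||
      position < 0 || position >= spec$total_length) {
    stop("position ", position, " outside route [0, ", spec$total_length, ")",
         call. = FALSE)
  }
  z <- spec$zones[order(spec$zones$start_position), ]
  z[findInterval(position, z$start_position), ]
}

# Vectorised limit lookup (km/h) used by the detectors and generator.
limit_at <- function(spec, s) {
  z <- spec$zones[order(spec$zones$start_position), ]
  s <- pmin(pmax(s, 0), spec$total_length - 1e-9)
  z$limit[findInterval(s, z$start_position)]
}

#' Write / read a scenario as JSON
#'
#' Serialisation is lossless: `read_scenario(write_scenario(spec, f))`
#' reproduces the scenario exactly. Distances are metres, speeds km/h,
#' times seconds.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns a `scenario_spec`.
#' @export
write_scenario <- function(spec, path) {
  payload <- list(
    zones = spec$zones,
    intersections = spec$intersections[, c("position", "control",
                                           "intersection_length")],
    light_schedules = lapply(spec$intersections$light_schedule, function(x) x),
    lane_changes = spec$lane_changes,
    leads = list(
      appear_position = spec$leads$appear_position,
      speed_profile = spec$leads$speed_profile
    ),
    lane_width = spec$lane_width,
    vehicle_width = spec$vehicle_width,
    total_length = spec$total_length
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  inter <- as_tibble(p$intersections)
  scheds <- p$light_schedules
  inter$light_schedule <- lapply(seq_len(nrow(inter)), function(i) {
    s <- scheds[[i]]
    if (is.null(s) || length(s) == 0) NULL else as_tibble(s)
  })
  leads <- tibble(
    appear_position = p$leads$appear_position,
    speed_profile = lapply(p$leads$speed_profile, as_tibble)
  )
  scenario_spec(as_tibble(p$zones), inter, as_tibble(p$lane_changes), leads,
                lane_width = p$lane_width, vehicle_width = p$vehicle_width,
                total_length = p$total_length)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$total_length / 1000, " km\n", sep = "")
  lims <- sort(unique(x$zones$limit))
  for (l in lims) {
    cat("  zones @", l, " km/h: ",
        sum(x$zones$length[x$zones$limit == l]), " m\n", sep = "")
  }
  cat("  intersections: ", sum(x$intersections$control == "stop-sign"),
      " stop-sign, ", sum(x$intersections$control == "traffic-light"),
      " traffic-light\n", sep = "")
  cat("  lane-change prompts: ", nrow(x$lane_changes), "\n", sep = "")
  cat("  lead-vehicle episodes: ", nrow(x$leads), "\n", sep = "")
  invisible(x)
}
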