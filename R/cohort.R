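#' Driver profile for the synthetic cohort
#'
#' Per-driver, per-maneuver error propensities with a session learning
#' curve and a recall rebound. The expected number of injected errors of a
#' kind at training session `j` is `base_rate * learning_factor^(j - 1)`;
#' at the delayed recall session it is
#' `base_rate * (recall_rebound + (1 - recall_rebound) * learning_factor^(n - 1))`,
#' so `recall_rebound = 1` models complete loss of the trained improvement
#' (performance regresses to baseline) and `recall_rebound = 0` perfect
#' retention.
#'
#' @param driver_id Identifier string.
#' @param base_rates Named numeric vector over [error_kinds()]: expected
#'   error counts per run at session 1.
#' @param learning_factor Per-session multiplicative retention in (0, 1].
#' @param recall_rebound Fraction of the baseline rate restored at recall,
#'   in `[0, 1]`.
#' @param weave_sd Stationary SD (m) of the mean-reverting lateral noise.
#' @param seed Optional per-driver seed.
#' @return A list of class `driver_profile`.
#' @export
driver_profile <- function(driver_id = "d1", base_rates = default_base_rates(),
                           learning_factor = default_learning_factor(),
                           recall_rebound = 1, weave_sd = 0.15, seed = NULL) {
  stopifnot(all(base_rates >= 0), learning_factor > 0, learning_factor <= 1,
            recall_rebound >= 0, recall_rebound <= 1)
  missing <- setdiff(error_kinds(), names(base_rates))
  if (length(missing) > 0) {
    stop("base_rates missing kind(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(driver_id = driver_id,
                 base_rates = base_rates[error_kinds()],
                 learning_factor = learning_factor,
                 recall_rebound = recall_rebound,
                 weave_sd = weave_sd, seed = seed),
            class = "driver_profile")
}

#' Default session-1 error propensities
#'
#' Anchored to the study conditions being emulated: about four speeding
#' errors per driver at session 1, 1.7 signal omissions and 1.1 tailgating
#' events per session, with the remaining kinds set so that the expected
#' session-1 per-driver total is 21.6 errors.
#'
#' @return Named numeric vector over [error_kinds()].
#' @export
default_base_rates <- function() {
  c(speeding = 4.0, tailgating = 1.1, weaving = 4.5, signal_omission = 1.7,
    blindspot_omission = 3.0, stop_control = 3.0, visual_search = 3.8,
    redlight_control = 0.5)
}

#' Default learning factor
#'
#' Calibrated so that the expected per-driver total declines from 21.6 at
#' session 1 to 8.2 at session 5: `(8.2 / 21.6)^(1/4)`.
#'
#' @return Scalar in (0, 1).
#' @export
default_learning_factor <- function() (8.2 / 21.6)^(1 / 4)

#' Study design
#'
#' @param n_drivers Number of drivers (default 15).
#' @param n_training_sessions Number of training sessions (default 5).
#' @param include_recall Include the delayed recall session (default TRUE).
#' @param scenario_ref Label of the scenario driven.
#' @param master_seed Master seed; all per-run seeds derive from it.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_drivers = 15, n_training_sessions = 5,
                         include_recall = TRUE, scenario_ref = "reference",
                         master_seed = 1L) {
  stopifnot(n_drivers >= 1, n_training_sessions >= 1)
  structure(list(n_drivers = n_drivers,
                 n_training_sessions = n_training_sessions,
                 include_recall = include_recall,
                 scenario_ref = scenario_ref,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Default cohort profiles for a design
#'
#' One [driver_profile()] per driver with the default propensities.
#'
#' @param design A [study_design()].
#' @return List of `driver_profile` objects.
#' @export
default_profiles <- function(design = study_design()) {
  lapply(seq_len(design$n_drivers), function(i) {
    driver_profile(driver_id = paste0("d", i))
  })
}

# Expected injected errors per kind for a session ("recall" or 1..n).
session_error_means <- function(profile, session_index,
                                n_training_sessions = 5) {
  f <- profile$learning_factor
  if (identical(session_index, "recall")) {
    trained <- f^(n_training_sessions - 1)
    profile$base_rates * (profile$recall_rebound +
                            (1 - profile$recall_rebound) * trained)
  } else {
    profile$base_rates * f^(as.integer(session_index) - 1)
  }
}

# Deterministic per-run seed derivation; kept below 2^31.
derive_run_seed <- function(master_seed, driver_index, session_index, salt = 0) {
  (as.numeric(master_seed) * 7919 + driver_index * 104729 +
     session_index * 130363 + salt * 95279) %% 2147483563 + 1
}

#' Generate a fully compliant run
#'
#' Synthesises telemetry for a driver who breaks no rule on the given
#' scenario: cruises at the zone limit with comfortable deceleration into
#' zone drops, makes a complete stop with a left-ahead-right scan at every
#' stop sign, waits for green at every light, signals and checks the blind
#' spot at every lane-change prompt, keeps at least a 3-s headway to lead
#' vehicles, and keeps mean-reverting lateral noise clipped well below the
#' weaving threshold. Running the detection engine on the output yields
#' zero errors of every kind. Deterministic given `seed`.
#'
#' @param spec A `scenario_spec`.
#' @param profile A [driver_profile()] (controls the lateral noise scale).
#' @param seed Integer seed.
#' @param dt Sampling interval in seconds (default 0.05, i.e. 20 Hz).
#' @return A telemetry stream with attribute `route_events`.
#' @export
generate_compliant_run <- function(spec, profile = driver_profile(),
                                   seed = 1, dt = 0.05) {
  rt <- route_timing(spec)
  kn <- rt$knots
  times <- seq(0, max(kn$t), by = dt)
  n <- length(times)
  s_t <- stats::approx(kn$t, kn$s, xout = times, rule = 2,
                       ties = "ordered")$y
  v_t <- stats::approx(kn$t, kn$v, xout = times, rule = 2,
                       ties = "ordered")$y * 3.6
  s_t <- cummax(s_t)

  noise <- withr::with_seed(seed, {
    phi <- exp(-dt / 2) # 2-s mean-reversion time constant
    list(
      lat = as.numeric(stats::filter(
        stats::rnorm(n, 0, profile$weave_sd * sqrt(1 - phi^2)),
        phi, method = "recursive")),
      yaw = as.numeric(stats::filter(
        stats::rnorm(n, 0, 3 * sqrt(1 - phi^2)),
        phi, method = "recursive"))
    )
  })
  lat_cap <- 0.7 * 0.175 * spec$lane_width # stays clear of the weave line
  lat <- pmin(pmax(noise$lat, -lat_cap), lat_cap)
  yaw <- pmin(pmax(noise$yaw, -10), 10)

  lane_index <- rep(0L, n)
  signal <- rep("none", n)
  lc <- spec$lane_changes[order(spec$lane_changes$position), ]
  half <- spec$lane_width / 2
  for (i in seq_len(nrow(lc))) {
    ci <- crossing_index(s_t, lc$position[i])
    if (is.na(ci)) next
    tc <- times[ci]
    dsgn <- if (lc$direction[i] == "left") 1L else -1L
    lane_index[ci:n] <- lane_index[ci:n] + dsgn
    signal[times >= tc - 2.5 & times <= tc + 0.5] <- lc$direction[i]
    yaw[times >= tc - 1.8 & times <= tc - 1.0] <- 50 * dsgn
    ramp_in <- which(times >= tc - 1.5 & times < tc)
    if (length(ramp_in) > 0) {
      lat[ramp_in] <- dsgn * half * seq(0, 1, length.out = length(ramp_in))
    }
    ramp_out <- which(times >= tc & times < tc + 1.5)
    if (length(ramp_out) > 0) {
      lat[ramp_out] <- -dsgn * half * seq(1, 0, length.out = length(ramp_out))
    }
  }

  stops <- rt$events[rt$events$control == "stop-sign", ]
  for (i in seq_len(nrow(stops))) {
    td <- stops$t_arrive[i]
    yaw[times >= td & times < td + 0.5] <- 40
    yaw[times >= td + 0.5 & times < td + 0.8] <- 0
    yaw[times >= td + 0.8 & times < td + 1.3] <- -40
  }

  lead_gap <- rep(NA_real_, n)
  for (i in seq_len(nrow(spec$leads))) {
    a <- spec$leads$appear_position[i]
    b <- max(spec$leads$speed_profile[[i]]$position)
    mask <- s_t >= a & s_t <= b
    lead_gap[mask] <- pmax(3.0 * v_t[mask] / 3.6, 8) # >= 3-s headway
  }

  dv <- c(0, diff(v_t)) / dt
  stream <- telemetry_stream(
    tibble(
      t = times, s = s_t, lateral_offset = lat, speed = v_t,
      accel_pedal = pmin(pmax(v_t / 130 + pmax(dv, 0) * 0.02, 0), 1),
      brake_pedal = pmin(pmax(-dv * 0.03, 0), 1),
      turn_signal = signal, head_yaw = yaw, lane_index = lane_index,
      lead_gap = lead_gap
    ),
    driver_id = profile$driver_id, session_id = "s1",
    scenario_ref = "reference"
  )
  attr(stream, "route_events") <- rt$events
  stream
}

# Counts drawn from Poisson laws with the session means, capped at the
# number of usable sites per kind (a plan with more stop-sign errors than
# stop signs cannot be realised). Must be the FIRST random draws under the
# plan seed so that simulate_error_table() reproduces them exactly.
draw_capped_counts <- function(means, spec) {
  n_signs <- sum(spec$intersections$control == "stop-sign")
  n_lights <- sum(spec$intersections$control == "traffic-light")
  n_prompts <- nrow(spec$lane_changes)
  caps <- c(speeding = 30, tailgating = 3 * nrow(spec$leads), weaving = 14,
            signal_omission = n_prompts, blindspot_omission = n_prompts,
            stop_control = n_signs, visual_search = n_signs,
            redlight_control = n_lights)
  counts <- stats::setNames(
    vapply(error_kinds(), function(k) stats::rpois(1, means[[k]]), integer(1)),
    error_kinds())
  over <- counts > caps[error_kinds()]
  if (any(over)) {
    warning("injection plan truncated for: ",
            paste(error_kinds()[over], collapse = ", "), call. = FALSE)
    counts[over] <- caps[error_kinds()][over]
  }
  counts
}

#' Sample an error-injection plan for one run
#'
#' Draws the number of errors of each kind from a Poisson law whose mean
#' follows the profile's learning curve (see [driver_profile()]), then
#' places each injection at a valid, well-separated site: continuous-rule
#' violations (speeding, weaving, tailgating) at route positions clear of
#' intersections, prompts and zone boundaries; event violations at
#' stop-sign / prompt / traffic-light indices sampled without replacement.
#' Infeasible draws are truncated with a warning.
#'
#' @param profile A [driver_profile()].
#' @param session_index Training session number (1-based) or `"recall"`.
#' @param spec A `scenario_spec`.
#' @param seed Integer seed.
#' @param n_training_sessions Number of training sessions in the design.
#' @return Tibble of class `injection_plan` with columns `kind`, `site`,
#'   `magnitude`, `duration`. For event kinds `site` is the 1-based index
#'   into the position-sorted site list and `magnitude`/`duration` are
#'   `NA`; for continuous kinds `site` is a route position in metres.
#' @export
sample_injection_plan <- function(profile, session_index, spec, seed,
                                  n_training_sessions = 5) {
  means <- session_error_means(profile, session_index, n_training_sessions)
  plan <- withr::with_seed(seed, {
    counts <- draw_capped_counts(means, spec)
    place_injections(counts, spec)
  })
  attr(plan, "session_index") <- session_index
  class(plan) <- c("injection_plan", class(plan))
  plan
}

place_injections <- function(counts, spec) {
  L <- spec$total_length
  z <- spec$zones[order(spec$zones$start_position), ]
  boundaries <- c(z$start_position, L)
  inter_pos <- spec$intersections$position
  prompt_pos <- sort(spec$lane_changes$position)
  lead_iv <- cbind(spec$leads$appear_position,
                   vapply(spec$leads$speed_profile,
                          function(p) max(p$position), numeric(1)))
  near <- function(x, centers, pad) any(abs(x - centers) <= pad)
  in_lead <- function(x) any(x >= lead_iv[, 1] - 50 & x <= lead_iv[, 2] + 50)
  window_clear <- function(x, len, avoid_leads) {
    pts <- seq(x, x + len, by = 10)
    ok <- x > 300 && x + len < L - 300 &&
      !any(vapply(pts, function(p) near(p, boundaries, 130), logical(1))) &&
      !any(vapply(pts, function(p) near(p, inter_pos, 80), logical(1))) &&
      !any(vapply(pts, function(p) near(p, prompt_pos, 120), logical(1)))
    if (ok && avoid_leads) ok <- !any(vapply(pts, in_lead, logical(1)))
    ok
  }
  # intervals reserved by already-placed continuous injections (with a
  # 40-m buffer), shared across kinds so their windows can never overlap
  reserved <- matrix(numeric(0), ncol = 2)
  sample_positions <- function(k, len, avoid_leads = TRUE,
                               within_leads = FALSE) {
    placed <- numeric(0)
    for (i in seq_len(k)) {
      for (try in 1:400) {
        x <- if (within_leads) {
          row <- sample.int(nrow(lead_iv), 1)
          stats::runif(1, lead_iv[row, 1] + 50, lead_iv[row, 2] - 50 - len)
        } else {
          stats::runif(1, 300, L - 300 - len)
        }
        ok <- if (within_leads) TRUE else window_clear(x, len, avoid_leads)
        if (ok && nrow(reserved) > 0) {
          ok <- all(x + len + 40 < reserved[, 1] | x > reserved[, 2] + 40)
        }
        if (ok) {
          placed <- c(placed, x)
          reserved <<- rbind(reserved, c(x, x + len))
          break
        }
      }
    }
    placed
  }
  rows <- list()
  add <- function(kind, site, magnitude = NA_real_, duration = NA_real_) {
    if (length(site) == 0) return()
    rows[[length(rows) + 1]] <<- tibble(kind = kind, site = site,
                                        magnitude = magnitude,
                                        duration = duration)
  }
  if (counts[["speeding"]] > 0) {
    add("speeding", sample_positions(counts[["speeding"]], len = 90),
        magnitude = 5, duration = 3)
  }
  if (counts[["weaving"]] > 0) {
    add("weaving", sample_positions(counts[["weaving"]], len = 250,
                                    avoid_leads = FALSE),
        magnitude = 0.3, duration = 12)
  }
  if (counts[["tailgating"]] > 0) {
    add("tailgating", sample_positions(counts[["tailgating"]], len = 60,
                                       within_leads = TRUE),
        magnitude = 0.7, duration = 3)
  }
  n_prompts <- nrow(spec$lane_changes)
  n_signs <- sum(spec$intersections$control == "stop-sign")
  n_lights <- sum(spec$intersections$control == "traffic-light")
  if (counts[["signal_omission"]] > 0) {
    add("signal_omission",
        as.numeric(sample.int(n_prompts, counts[["signal_omission"]])))
  }
  if (counts[["blindspot_omission"]] > 0) {
    add("blindspot_omission",
        as.numeric(sample.int(n_prompts, counts[["blindspot_omission"]])))
  }
  if (counts[["stop_control"]] > 0) {
    add("stop_control", as.numeric(sample.int(n_signs, counts[["stop_control"]])))
  }
  if (counts[["visual_search"]] > 0) {
    add("visual_search", as.numeric(sample.int(n_signs, counts[["visual_search"]])))
  }
  if (counts[["redlight_control"]] > 0) {
    add("redlight_control",
        as.numeric(sample.int(n_lights, counts[["redlight_control"]])))
  }
  out <- if (length(rows) == 0) {
    tibble(kind = character(), site = numeric(), magnitude = numeric(),
           duration = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  out
}

#' Apply an injection plan to a compliant base stream
#'
#' Each injection locally rewrites the stream so that it violates exactly
#' its rule with the planned magnitude and duration, leaving the rest of
#' the stream compliant: speeding raises the speed channel above
#' limit + grace, weaving forces a sustained lateral excursion past the
#' offset threshold, tailgating shrinks the lead gap below the headway
#' threshold, signal/blind-spot omissions blank the turn signal or head-yaw
#' check before one prompt, stop-control turns a full stop into a rolling
#' one, visual-search removes the intersection scan, and red-light makes
#' the vehicle enter the intersection on red instead of waiting for green
#' (then hold past the intersection until the nominal timeline catches up).
#'
#' @param base A compliant telemetry stream from [generate_compliant_run()].
#' @param plan An [sample_injection_plan()] result.
#' @param spec The `scenario_spec` the stream was generated on.
#' @param config A [detection_config()] (supplies the thresholds the
#'   magnitudes are relative to).
#' @return The rewritten telemetry stream.
#' @export
apply_injections <- function(base, plan, spec, config = detection_config()) {
  stream <- base
  if (nrow(plan) == 0) return(stream)
  # overlap guard: time windows of continuous injections must not intersect
  cont <- plan[plan$kind %in% c("speeding", "weaving", "tailgating"), ]
  if (nrow(cont) > 1) {
    t0 <- vapply(cont$site, function(x) {
      i <- crossing_index(stream$s, x)
      if (is.na(i)) Inf else stream$t[i]
    }, numeric(1))
    iv <- cbind(t0, t0 + cont$duration)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("overlapping injections", call. = FALSE)
    }
  }
  prompts <- spec$lane_changes[order(spec$lane_changes$position), ]
  signs <- spec$intersections[spec$intersections$control == "stop-sign", ]
  lights <- spec$intersections[spec$intersections$control == "traffic-light", ]
  for (r in seq_len(nrow(plan))) {
    kind <- plan$kind[r]; site <- plan$site[r]
    mag <- plan$magnitude[r]; dur <- plan$duration[r]
    if (kind %in% c("speeding", "weaving", "tailgating")) {
      i0 <- crossing_index(stream$s, site)
      if (is.na(i0)) next
      w <- stream$t >= stream$t[i0] & stream$t <= stream$t[i0] + dur
      if (kind == "speeding") {
        lim <- limit_at(spec, site)
        stream$speed[w] <- lim + config$speed_grace + mag
      } else if (kind == "weaving") {
        thr <- config$weave_fraction * spec$lane_width
        stream$lateral_offset[w] <- thr * (1 + mag)
      } else {
        stream$lead_gap[w] <- config$headway_threshold * mag *
          stream$speed[w] / 3.6
      }
    } else if (kind %in% c("signal_omission", "blindspot_omission")) {
      ci <- crossing_index(stream$s, prompts$position[site])
      if (is.na(ci)) next
      tc <- stream$t[ci]
      if (kind == "signal_omission") {
        w <- stream$t >= tc - 3.5 & stream$t <= tc + 0.6
        stream$turn_signal[w] <- "none"
      } else {
        w <- stream$t >= tc - 3.3 & stream$t < tc
        stream$head_yaw[w] <- 0
      }
    } else if (kind == "stop_control") {
      line <- signs$position[site]
      w <- stream$s >= line - config$approach_window - 2 & stream$s <= line + 1
      stream$speed[w] <- pmax(stream$speed[w], 3) # rolling stop
    } else if (kind == "visual_search") {
      line <- signs$position[site]
      w <- stream$s >= line - config$approach_window - 1 & stream$s <= line + 0.5
      stream$head_yaw[w] <- 0
    } else if (kind == "redlight_control") {
      stream <- inject_redlight(stream, lights[site, ])
    }
  }
  stream
}

# Rewrite the wait-for-green dwell at one light into a slow crossing on
# red, then hold just past the intersection until the nominal (waiting)
# trajectory catches up, preserving monotone time and position.
inject_redlight <- function(stream, light) {
  line <- light$position; ilen <- light$intersection_length
  sched <- light$light_schedule[[1]]
  cand <- which(stream$s >= line - 3 & stream$s < line & stream$speed < 3.6)
  if (length(cand) == 0) {
    warning("red-light injection skipped: no waiting dwell found", call. = FALSE)
    return(stream)
  }
  i_w <- cand[1]
  t0 <- stream$t[i_w]; s0 <- stream$s[i_w]
  v_c <- 2.5 # m/s crossing speed
  s_hold <- line + ilen + 5
  t_entry <- t0 + (line - s0) / v_c
  t_mid <- t0 + (line + ilen / 2 - s0) / v_c
  if (!(phase_at(sched, t_entry) %in% c("yellow", "red")) ||
      phase_at(sched, t_mid) != "red") {
    warning("red-light injection skipped: arrival phase not red", call. = FALSE)
    return(stream)
  }
  t_cross_end <- t0 + (s_hold - s0) / v_c
  i_r <- which(stream$s >= s_hold & stream$t >= t_cross_end)[1]
  if (is.na(i_r) || i_r <= i_w + 1) {
    warning("red-light injection skipped: no resume point", call. = FALSE)
    return(stream)
  }
  w <- i_w:(i_r - 1)
  s_new <- pmin(s0 + v_c * (stream$t[w] - t0), s_hold)
  stream$s[w] <- s_new
  stream$speed[w] <- ifelse(s_new < s_hold, v_c * 3.6, 0)
  stream$lead_gap[w] <- NA_real_
  stream
}

#' Generate a full synthetic study
#'
#' One telemetry stream per driver and session (training sessions plus, if
#' designed, the recall session), each a compliant base run with that
#' driver's sampled injections applied. Per-run seeds derive
#' deterministically from the design's master seed, so the same design and
#' profiles always reproduce the identical study.
#'
#' @param design A [study_design()].
#' @param profiles List of [driver_profile()]s, one per driver.
#' @param spec A `scenario_spec` (default: the reference scenario).
#' @param config A [detection_config()].
#' @param dt Sampling interval in seconds.
#' @return Named list of telemetry streams (`"<driver>_<session>"`), with
#'   attribute `ground_truth`: a tibble of injected counts per run.
#' @export
generate_study <- function(design, profiles = default_profiles(design),
                           spec = build_reference_scenario(),
                           config = detection_config(), dt = 0.05) {
  runs <- study_runs(design)
  streams <- list()
  gt <- list()
  for (r in seq_len(nrow(runs))) {
    res <- generate_run(design, profiles, spec, config,
                        runs$driver_index[r], runs$session[r], dt)
    key <- paste0(profiles[[runs$driver_index[r]]]$driver_id, "_",
                  runs$session[r])
    streams[[key]] <- res$stream
    gt[[key]] <- tibble(driver = profiles[[runs$driver_index[r]]]$driver_id,
                        session = runs$session[r],
                        kind = error_kinds(),
                        count = as.integer(res$injected[error_kinds()]))
  }
  attr(streams, "ground_truth") <- dplyr::bind_rows(gt)
  streams
}

study_runs <- function(design) {
  sessions <- as.character(seq_len(design$n_training_sessions))
  if (design$include_recall) sessions <- c(sessions, "recall")
  expand.grid(driver_index = seq_len(design$n_drivers), session = sessions,
              stringsAsFactors = FALSE)
}

session_number <- function(design, session) {
  if (session == "recall") design$n_training_sessions + 1L
  else as.integer(session)
}

# Generate one run: compliant base + sampled injections.
generate_run <- function(design, profiles, spec, config, driver_index,
                         session, dt = 0.05) {
  s_num <- session_number(design, session)
  seed_gen <- derive_run_seed(design$master_seed, driver_index, s_num, salt = 1)
  seed_plan <- derive_run_seed(design$master_seed, driver_index, s_num, salt = 2)
  profile <- profiles[[driver_index]]
  base <- generate_compliant_run(spec, profile, seed = seed_gen, dt = dt)
  sess_idx <- if (session == "recall") "recall" else as.integer(session)
  plan <- sample_injection_plan(profile, sess_idx, spec, seed_plan,
                                design$n_training_sessions)
  stream <- apply_injections(base, plan, spec, config)
  attr(stream, "session_id") <- session
  injected <- table(factor(plan$kind, levels = error_kinds()))
  list(stream = stream, plan = plan,
       injected = stats::setNames(as.integer(injected), error_kinds()))
}

#' Generate, detect and tabulate a full study
#'
#' Runs the complete pipeline in memory, one run at a time: generate the
#' compliant base, apply the sampled injections, run the detection engine,
#' and collect per-kind counts into an [build_error_table()] array.
#'
#' @inheritParams generate_study
#' @return List with `table` (an `error_table` of detected counts),
#'   `ground_truth` (tibble of injected counts) and `lane_changes` (events
#'   per run).
#' @export
run_study <- function(design, profiles = default_profiles(design),
                      spec = build_reference_scenario(),
                      config = detection_config(), dt = 0.05) {
  runs <- study_runs(design)
  counts <- list()
  gt <- list()
  n_lc <- integer(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    res <- generate_run(design, profiles, spec, config,
                        runs$driver_index[r], runs$session[r], dt)
    rep <- run_engine(res$stream, spec, config)
    drv <- profiles[[runs$driver_index[r]]]$driver_id
    counts[[r]] <- tibble(driver = drv, session = runs$session[r],
                          kind = error_kinds(),
                          count = as.integer(rep$counts[error_kinds()]))
    gt[[r]] <- tibble(driver = drv, session = runs$session[r],
                      kind = error_kinds(),
                      count = as.integer(res$injected[error_kinds()]))
    n_lc[r] <- nrow(rep$lane_change_events)
  }
  list(table = build_error_table(dplyr::bind_rows(counts)),
       ground_truth = dplyr::bind_rows(gt),
       lane_changes = tibble(driver = runs$driver_index,
                             session = runs$session, events = n_lc))
}

#' Simulate a study at the error-count level
#'
#' Draws the per-run injected counts with exactly the same seeds and RNG
#' path as the full pipeline (the counts are the first draws under each
#' run's plan seed), skipping telemetry synthesis and detection. Because
#' detection recovers injected counts exactly (the injection-recovery
#' property), the resulting table equals the full pipeline's; this is the
#' fast path for replicate-level statistical studies.
#'
#' @inheritParams generate_study
#' @return An `error_table` of simulated counts.
#' @export
simulate_error_table <- function(design, profiles = default_profiles(design),
                                 spec = build_reference_scenario()) {
  runs <- study_runs(design)
  counts <- list()
  for (r in seq_len(nrow(runs))) {
    d <- runs$driver_index[r]; session <- runs$session[r]
    s_num <- session_number(design, session)
    seed_plan <- derive_run_seed(design$master_seed, d, s_num, salt = 2)
    sess_idx <- if (session == "recall") "recall" else as.integer(session)
    means <- session_error_means(profiles[[d]], sess_idx,
                                 design$n_training_sessions)
    kc <- withr::with_seed(seed_plan, draw_capped_counts(means, spec))
    counts[[r]] <- tibble(driver = profiles[[d]]$driver_id, session = session,
                          kind = error_kinds(), count = as.integer(kc))
  }
  build_error_table(dplyr::bind_rows(counts))
}
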