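# Internal route-timing machinery shared by the scenario builder (which must
# predict nominal arrival times at traffic lights) and the compliant-run
# generator. Everything here is deterministic given the scenario.

# Grid index of the intersection slow point (~1.5-3.5 m before the line).
slow_point_index <- function(position, ds) {
  max(floor((position - 1.5) / ds) + 1, 1)
}

# Speed-vs-position profile on a 2-m grid: cruise at the zone limit, with
# comfortable (1.5 m/s^2) deceleration/acceleration envelopes into zone
# drops and intersection slow points. Returns s (m), v (m/s) and the
# dwell-free cumulative time t (s).
route_speed_profile <- function(spec, ds = 2, a = 1.5) {
  s <- seq(0, spec$total_length, by = ds)
  n <- length(s)
  v <- limit_at(spec, s) / 3.6
  # slow points: near-stop at stop-sign lines, slow roll at light lines,
  # anchored at the last grid point clearly before the stop line
  it <- spec$intersections
  for (i in seq_len(nrow(it))) {
    idx <- slow_point_index(it$position[i], ds)
    v[idx] <- if (it$control[i] == "stop-sign") 0.15 else 1.0
  }
  v[1] <- min(v[1], 2.0) # rolling start
  for (i in (n - 1):1) v[i] <- min(v[i], sqrt(v[i + 1]^2 + 2 * a * ds))
  for (i in 1:(n - 1)) v[i + 1] <- min(v[i + 1], sqrt(v[i]^2 + 2 * a * ds))
  vm <- (v[-1] + v[-n]) / 2
  list(s = s, v = v, t = c(0, cumsum(ds / pmax(vm, 0.05))))
}

# Full nominal timing: knots (t, s, v) including intersection dwells, plus
# an event table (arrival time and dwell per intersection). Stop signs get
# a fixed full-stop dwell; traffic lights a conditional wait until the next
# green onset (plus a short settle) whenever the arrival phase is not green.
route_timing <- function(spec) {
  prof <- route_speed_profile(spec)
  ds <- prof$s[2] - prof$s[1]
  it <- spec$intersections[order(spec$intersections$position), ]
  n_ev <- nrow(it)
  ev_idx <- integer(n_ev)
  ev_arrive <- numeric(n_ev)
  ev_dwell <- numeric(n_ev)
  added <- 0
  for (i in seq_len(n_ev)) {
    idx <- slow_point_index(it$position[i], ds)
    arr <- prof$t[idx] + added
    if (it$control[i] == "stop-sign") {
      dw <- stop_dwell_s()
    } else {
      sched <- it$light_schedule[[i]]
      if (is.null(sched)) {
        dw <- 0
      } else {
        w <- next_green_wait(sched, arr)
        dw <- if (w == 0) 0 else w + light_settle_s()
      }
    }
    ev_idx[i] <- idx
    ev_arrive[i] <- arr
    ev_dwell[i] <- dw
    added <- added + dw
  }
  # shift grid times by dwells accumulated strictly upstream
  shift <- numeric(length(prof$t))
  for (i in seq_len(n_ev)) {
    if (ev_dwell[i] > 0 && ev_idx[i] < length(shift)) {
      rng <- (ev_idx[i] + 1):length(shift)
      shift[rng] <- shift[rng] + ev_dwell[i]
    }
  }
  kt <- prof$t + shift
  ks <- prof$s
  kv <- prof$v
  dwelling <- ev_dwell > 0
  if (any(dwelling)) {
    kt <- c(kt, ev_arrive[dwelling] + 0.1, ev_arrive[dwelling] + ev_dwell[dwelling])
    ks <- c(ks, prof$s[ev_idx[dwelling]], prof$s[ev_idx[dwelling]])
    kv <- c(kv, rep(0.05, sum(dwelling)), rep(0.05, sum(dwelling)))
    ord <- order(kt, ks)
    kt <- kt[ord]; ks <- ks[ord]; kv <- kv[ord]
  }
  list(
    knots = list(t = kt, s = ks, v = kv),
    events = tibble(
      control = it$control, position = it$position,
      intersection_length = it$intersection_length,
      t_arrive = ev_arrive, dwell = ev_dwell
    )
  )
}
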