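test_that("a compliant driver commits zero errors of every kind", {
  spec <- ref_spec()
  rep <- run_engine(ref_compliant(), spec)
  for (k in error_kinds()) {
    expect_equal(unname(rep$counts[k]), 0, info = k)
  }
  expect_equal(nrow(rep$lane_change_events), 15)
  expect_true(all(rep$lane_change_events$signaled))
  expect_true(all(rep$lane_change_events$blindspot_checked))
})

test_that("compliant generation is deterministic in the seed", {
  spec <- ref_spec()
  a <- generate_compliant_run(spec, seed = 99)
  b <- generate_compliant_run(spec, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_compliant_run(spec, seed = 100)
  expect_false(identical(a$lateral_offset, c$lateral_offset))
})

test_that("session means follow the learning curve closed form", {
  p <- driver_profile(base_rates = stats::setNames(
    c(4, rep(0, 7)), error_kinds()), learning_factor = 0.8)
  m5 <- drivescore:::session_error_means(p, 5)
  expect_equal(unname(m5[["speeding"]]), 4 * 0.8^4) # 1.6384
  p1 <- driver_profile(learning_factor = 1.0)
  expect_equal(drivescore:::session_error_means(p1, 5), p1$base_rates)
  # full rebound restores the baseline at recall
  pr <- driver_profile(recall_rebound = 1)
  expect_equal(drivescore:::session_error_means(pr, "recall"), pr$base_rates)
  # no rebound keeps the trained level
  p0 <- driver_profile(recall_rebound = 0, learning_factor = 0.8)
  expect_equal(drivescore:::session_error_means(p0, "recall"),
               p0$base_rates * 0.8^4)
})

test_that("expected totals decline strictly across training sessions", {
  p <- driver_profile()
  tot <- vapply(1:5, function(s) {
    sum(drivescore:::session_error_means(p, s))
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
  expect_equal(tot[1], 21.6)
  expect_equal(tot[5], 8.2, tolerance = 1e-10)
})

test_that("detected counts equal injected counts exactly", {
  spec <- ref_spec()
  prof <- driver_profile()
  for (case in list(list(seed = 31, session = 1),
                    list(seed = 32, session = "recall"),
                    list(seed = 33, session = 3))) {
    base <- generate_compliant_run(spec, prof, seed = case$seed)
    plan <- sample_injection_plan(prof, case$session, spec,
                                  seed = case$seed * 17)
    stream <- apply_injections(base, plan, spec)
    rep <- run_engine(stream, spec)
    injected <- table(factor(plan$kind, levels = error_kinds()))
    expect_equal(unname(rep$counts[error_kinds()]),
                 as.integer(injected),
                 info = paste("seed", case$seed))
  }
})

test_that("an infeasible plan is truncated with a warning", {
  spec <- ref_spec()
  rates <- default_base_rates()
  rates["stop_control"] <- 60
  prof <- driver_profile(base_rates = rates)
  expect_warning(
    plan <- sample_injection_plan(prof, 1, spec, seed = 5),
    "truncated"
  )
  expect_lte(sum(plan$kind == "stop_control"),
             sum(spec$intersections$control == "stop-sign"))
})

test_that("empty plans leave the stream unchanged", {
  spec <- ref_spec()
  base <- ref_compliant()
  empty <- sample_injection_plan(
    driver_profile(base_rates = stats::setNames(rep(0, 8), error_kinds())),
    1, spec, seed = 2)
  expect_equal(nrow(empty), 0)
  expect_identical(as.data.frame(apply_injections(base, empty, spec)),
                   as.data.frame(base))
})

test_that("studies are reproducible and sized by the design", {
  d_small <- study_design(n_drivers = 2, n_training_sessions = 2,
                          master_seed = 42)
  s1 <- generate_study(d_small)
  s2 <- generate_study(d_small)
  expect_equal(length(s1), 2 * 3) # 2 training sessions + recall
  expect_identical(names(s1), names(s2))
  expect_identical(as.data.frame(s1[[1]]), as.data.frame(s2[[1]]))
  expect_identical(attr(s1, "ground_truth"), attr(s2, "ground_truth"))

  no_recall <- study_design(n_drivers = 2, n_training_sessions = 2,
                            include_recall = FALSE, master_seed = 42)
  expect_equal(length(generate_study(no_recall)), 4)
  # the default design is 15 drivers x (5 + recall) = 90 runs
  expect_equal(nrow(drivescore:::study_runs(study_design())), 90)
})

test_that("count-level simulation equals the full pipeline exactly", {
  design <- study_design(n_drivers = 2, n_training_sessions = 2,
                         master_seed = 8)
  full <- run_study(design)
  fast <- simulate_error_table(design)
  expect_identical(unclass(fast), unclass(full$table))
  # and the full pipeline itself detects exactly what was injected
  expect_identical(unclass(full$table),
                   unclass(build_error_table(full$ground_truth)))
})

test_that("session-1 totals recover the calibrated rate within 3 SE", {
  design <- study_design(master_seed = 1234)
  tab <- simulate_error_table(design)
  m1 <- mean(error_totals(tab)[, "1"])
  lambda <- sum(default_base_rates())
  se <- sqrt(lambda / design$n_drivers)
  expect_lt(abs(m1 - lambda), 3 * se)
})
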