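#' Run the full generate - detect - analyse pipeline
#'
#' End-to-end orchestration: generates the synthetic study, runs the
#' detection engine over every run, tabulates the error counts, runs the
#' repeated-measures analysis, and writes everything under `out_dir`:
#' `telemetry/` (one CSV per run, optional), `error_table.csv` (one row
#' per driver/session/kind), `results.csv` (the [analyze_study()] table),
#' `session_summary.csv`, `ground_truth.csv`, optional PNG figures, and
#' `manifest.json` recording the seed and an MD5 hash of every written
#' file. Reruns with the same configuration reproduce byte-identical CSV
#' output.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [study_design()].
#' @param profiles List of [driver_profile()]s.
#' @param spec A `scenario_spec`.
#' @param config A [detection_config()].
#' @param write_telemetry Write the per-run telemetry CSVs (large; default
#'   `FALSE`).
#' @param figures Write learning-curve figures as PNG.
#' @param dt Sampling interval in seconds.
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_pipeline <- function(out_dir, design = study_design(),
                         profiles = default_profiles(design),
                         spec = build_reference_scenario(),
                         config = detection_config(),
                         write_telemetry = FALSE, figures = FALSE,
                         dt = 0.05) {
  stage <- "setup"
  tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()

    stage <- "scenario"
    sc_path <- file.path(out_dir, "scenario.json")
    write_scenario(spec, sc_path)
    files <- c(files, sc_path)

    stage <- "generate+detect"
    if (write_telemetry) {
      dir.create(file.path(out_dir, "telemetry"), showWarnings = FALSE)
      runs <- study_runs(design)
      counts <- list(); gt <- list()
      for (r in seq_len(nrow(runs))) {
        res <- generate_run(design, profiles, spec, config,
                            runs$driver_index[r], runs$session[r], dt)
        drv <- profiles[[runs$driver_index[r]]]$driver_id
        tp <- file.path(out_dir, "telemetry",
                        paste0(drv, "_", runs$session[r], ".csv"))
        write_telemetry(res$stream, tp)
        files <- c(files, tp)
        rep <- run_engine(res$stream, spec, config)
        counts[[r]] <- tibble(driver = drv, session = runs$session[r],
                              kind = error_kinds(),
                              count = as.integer(rep$counts[error_kinds()]))
        gt[[r]] <- tibble(driver = drv, session = runs$session[r],
                          kind = error_kinds(),
                          count = as.integer(res$injected[error_kinds()]))
      }
      study <- list(table = build_error_table(dplyr::bind_rows(counts)),
                    ground_truth = dplyr::bind_rows(gt))
    } else {
      study <- run_study(design, profiles, spec, config, dt)
    }

    stage <- "tabulate"
    et_path <- file.path(out_dir, "error_table.csv")
    et_long <- as_tibble(as.data.frame.table(unclass(study$table),
                                             responseName = "count"))
    names(et_long)[1:3] <- c("driver", "session", "kind")
    readr::write_csv(et_long, et_path)
    gt_path <- file.path(out_dir, "ground_truth.csv")
    readr::write_csv(study$ground_truth, gt_path)
    files <- c(files, et_path, gt_path)

    stage <- "analyze"
    res_path <- file.path(out_dir, "results.csv")
    readr::write_csv(analyze_study(study$table), res_path)
    sum_path <- file.path(out_dir, "session_summary.csv")
    readr::write_csv(session_summary(study$table), sum_path)
    files <- c(files, res_path, sum_path)

    if (figures) {
      stage <- "figures"
      f1 <- file.path(out_dir, "per_kind_means.png")
      ggplot2::ggsave(f1, plot_session_means(study$table), width = 9,
                      height = 6, dpi = 120)
      f2 <- file.path(out_dir, "total_errors.png")
      ggplot2::ggsave(f2, plot_session_means(study$table, total_only = TRUE),
                      width = 5, height = 4, dpi = 120)
      files <- c(files, f1, f2)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("drivescore")),
      master_seed = design$master_seed,
      n_drivers = design$n_drivers,
      n_sessions = design$n_training_sessions +
        as.integer(design$include_recall),
      files = lapply(files, function(f) {
        list(path = basename_rel(f, out_dir),
             md5 = unname(tools::md5sum(f)))
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

basename_rel <- function(path, root) {
  sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", root), "/?"), "",
      path)
}

#' Write small hand-checkable demonstration fixtures
#'
#' Builds, on a shortened single-zone scenario, one compliant run, one run
#' per error kind containing exactly one injected violation of that kind,
#' and a 3 x 3 worked example for the Friedman test. Used by the
#' documentation and the test-suite; everything is generated in code.
#'
#' @param out_dir Destination directory.
#' @return Named list of file paths, with attribute `scenario` (the demo
#'   `scenario_spec`, also written as `scenario.json`).
#' @export
make_demo_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- demo_scenario()
  paths <- list()
  sc <- file.path(out_dir, "scenario.json")
  write_scenario(spec, sc)
  paths$scenario <- sc

  base <- generate_compliant_run(spec, seed = 42)
  cp <- file.path(out_dir, "compliant.csv")
  write_telemetry(base, cp)
  paths$compliant <- cp

  for (k in error_kinds()) {
    plan <- demo_plan_for(k, spec)
    stream <- apply_injections(base, plan, spec)
    fp <- file.path(out_dir, paste0("one_", k, ".csv"))
    write_telemetry(stream, fp)
    paths[[paste0("one_", k)]] <- fp
  }

  fw <- file.path(out_dir, "friedman_worked.csv")
  readr::write_csv(tibble(s1 = c(1, 1, 2), s2 = c(2, 3, 1), s3 = c(3, 2, 3)),
                   fw)
  paths$friedman_worked <- fw
  attr(paths, "scenario") <- spec
  paths
}

# Compact scenario for fixtures: 4.5 km, one of everything.
demo_scenario <- function() {
  zones <- tibble(start_position = c(0, 1500, 3500),
                  length = c(1500, 2000, 1000), limit = c(50, 70, 50))
  intersections <- tibble(
    position = c(900, 4100),
    control = c("stop-sign", "traffic-light"),
    intersection_length = 20,
    light_schedule = list(NULL, NULL)
  )
  lane_changes <- tibble(position = c(2000, 2400),
                         direction = c("left", "right"),
                         kind = "commanded")
  leads <- tibble(
    appear_position = 200,
    speed_profile = list(tibble(position = c(200, 700), speed = c(50, 50)))
  )
  assign_light_schedules(
    scenario_spec(zones, intersections, lane_changes, leads))
}

demo_plan_for <- function(kind, spec) {
  site <- switch(kind,
    speeding = 1200, weaving = 2800, tailgating = 400,
    signal_omission = 1, blindspot_omission = 2,
    stop_control = 1, visual_search = 1, redlight_control = 1
  )
  mag <- switch(kind, speeding = 5, weaving = 0.3, tailgating = 0.7,
                NA_real_)
  dur <- switch(kind, speeding = 3, weaving = 12, tailgating = 3, NA_real_)
  structure(tibble(kind = kind, site = site, magnitude = mag, duration = dur),
            class = c("injection_plan", class(tibble())))
}
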