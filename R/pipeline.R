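#' Run configurations
#'
#' A run configuration is a plain nested list (serialisable losslessly to
#' JSON) describing an end-to-end run: the seed, an optional two-choice
#' session block and an optional wind-tunnel block with its scenarios and
#' tracking/kinematic parameters. \code{default_run_config()} returns the
#' bundled demonstration: a 12-day synthetic two-choice experiment
#' analysed for upwind and right-channel preference.
#'
#' @param seed integer master seed; all randomness in the run derives
#'   from it.
#' @return a named list of class \code{"run_config"}.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    choice = list(p_upwind = 0.644, p_right = 0.525, n_days = 12L,
                  flights_per_day = 244L),
    windtunnel = NULL,
    tracking = list(threshold = 0.2, min_area = 9L, gate_px = 30,
                    max_missed = 3L, min_len = 6L, stationary_eps = 0.5,
                    stationary_frames = 10L),
    kinematics = list(sinuosity_max = 1.1, min_ground_speed = 0.02,
                      min_height = 0.015, central_bounds = NULL)
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param path JSON file to read or write.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config must contain a `seed`", call. = FALSE)
  if (!is.null(cfg$windtunnel$scenarios) &&
      is.data.frame(cfg$windtunnel$scenarios)) {
    cfg$windtunnel$scenarios <- split(cfg$windtunnel$scenarios,
                                      seq_len(nrow(cfg$windtunnel$scenarios)))
    cfg$windtunnel$scenarios <- lapply(cfg$windtunnel$scenarios, as.list)
  }
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param config a run configuration.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Execute a full reproducible run
#'
#' Orchestrates simulate (optional) -> track -> kinematics -> statistics
#' for every block present in the configuration, writes all intermediate
#' CSV tables and a JSON report (when \code{out_dir} is given), and
#' returns the report. The report embeds the exact configuration, the
#' package version, the seed and stage-by-stage counts, and is identical
#' for identical config + seed.
#'
#' @param config a \code{"run_config"} list or a path to a JSON config.
#' @param out_dir optional output directory for CSVs and
#'   \code{report.json}.
#' @return the report, an ordinary nested list.
#' @examples
#' rep <- run_pipeline(default_run_config(seed = 42))
#' rep$choice$tests$upwind$V
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must contain a `seed`", call. = FALSE)
  seed <- as.integer(config$seed)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(
    package = "beeflight",
    version = as.character(packageVersion("beeflight")),
    seed = seed,
    config = unclass(config)
  )

  if (!is.null(config$choice)) {
    ch <- config$choice
    cp <- choice_model_params(
      p_upwind = ch$p_upwind %||% 0.644,
      p_right = ch$p_right %||% 0.525,
      n_days = ch$n_days %||% 12L,
      flights_per_day = ch$flights_per_day %||% 244L,
      seed = seed)
    tab <- simulate_choice_sessions(cp)
    tests <- choice_preference_tests(tab)
    report$choice <- list(
      n_days = nrow(tab),
      n_flights = sum(tab$n_total),
      mean_p_upwind = tests$summary$mean_p_upwind,
      sd_p_upwind = tests$summary$sd_p_upwind,
      mean_p_right = tests$summary$mean_p_right,
      sd_p_right = tests$summary$sd_p_right,
      tests = list(
        upwind = list(V = unname(tests$upwind$statistic["V"]),
                      p = tests$upwind$p.value,
                      exact = tests$upwind$exact),
        right_channel = list(V = unname(tests$right_channel$statistic["V"]),
                             p = tests$right_channel$p.value,
                             exact = tests$right_channel$exact)),
      per_day_binomial = tests$per_day
    )
    if (!is.null(out_dir)) {
      write_choice_table(tab, file.path(out_dir, "choice_table.csv"))
    }
  }

  if (!is.null(config$windtunnel)) {
    wt <- config$windtunnel
    trk <- config$tracking %||% default_run_config()$tracking
    kin <- config$kinematics %||% default_run_config()$kinematics
    cam <- camera_overhead(px_per_m = wt$px_per_m %||% 500)
    scen_out <- list()
    all_flights <- list()
    for (si in seq_along(wt$scenarios)) {
      sc <- wt$scenarios[[si]]
      recs <- simulate_and_analyze(
        n_flights = sc$n_flights %||% 5L,
        setpoint = sc$setpoint %||% 0.8,
        u = sc$u %||% 0,
        direction = sc$direction %||% "toward_feeder",
        seed = seed + 7919L * si,
        cam = cam,
        duration = wt$duration %||% 1.2,
        frame_rate = wt$frame_rate %||% 100,
        tracking = trk, kinematics = kin)
      kept <- recs[recs$retained, , drop = FALSE]
      scen_out[[si]] <- list(
        name = sc$name %||% sprintf("scenario_%d", si),
        u = sc$u %||% 0, direction = sc$direction %||% "toward_feeder",
        n_flights = nrow(recs), n_retained = nrow(kept),
        filter_counts = as.list(attr(recs, "filter_counts")),
        mean_vg = if (nrow(kept)) mean(kept$mean_vg) else NA_real_,
        mean_va = if (nrow(kept)) mean(kept$mean_va) else NA_real_,
        mean_sinuosity = if (nrow(kept)) mean(kept$sinuosity) else NA_real_)
      recs$scenario <- scen_out[[si]]$name
      all_flights[[si]] <- recs
    }
    flights <- do.call(rbind, all_flights)
    report$windtunnel <- list(scenarios = scen_out)
    if (!is.null(out_dir) && nrow(flights)) {
      write_flight_table(flights, file.path(out_dir, "flight_table.csv"))
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  report
}

#' Simulate, render, track and summarise a batch of flights
#'
#' The full synthetic chain behind the wind-tunnel scenarios: for each
#' flight a ground-truth trajectory is simulated, rendered into overhead
#' frames over a shared background, tracked, calibrated and summarised,
#' and the standard filters are applied.
#'
#' @param n_flights number of flights.
#' @param setpoint ground-speed set-point, m/s.
#' @param u signed flow velocity along x, m/s.
#' @param direction \code{"toward_feeder"} or \code{"toward_hive"}.
#' @param seed integer; flight i uses \code{seed + i}.
#' @param cam planar camera model (default overhead full-tunnel view).
#' @param duration,frame_rate clip length (s) and camera rate (Hz).
#' @param tracking,kinematics parameter lists as in
#'   [default_run_config()].
#' @return flight-record data.frame with filter flags (one row per
#'   recovered track).
#' @export
simulate_and_analyze <- function(n_flights, setpoint, u, direction,
                                 seed = 1L, cam = camera_overhead(),
                                 duration = 1.2, frame_rate = 100,
                                 tracking = NULL, kinematics = NULL) {
  trk <- tracking %||% default_run_config()$tracking
  kin <- kinematics %||% default_run_config()$kinematics
  bg <- make_background_texture(cam$nrow, cam$ncol, seed)
  out <- vector("list", n_flights)
  est_bg <- NULL  # median background estimated once; the scene is fixed
  for (i in seq_len(n_flights)) {
    p <- simulation_params(ground_speed_setpoint = setpoint,
                           flow_velocity = u, direction = direction,
                           duration = duration, frame_rate = frame_rate,
                           seed = seed + i)
    traj <- simulate_trajectory(p)
    stack <- render_frames(traj, cam, p, background = bg)
    if (is.null(est_bg)) est_bg <- compute_background(stack)
    recs <- analyze_stack(stack, u = abs(u), flow_dir = sign(u),
                          background = est_bg,
                          central_bounds = kin$central_bounds,
                          threshold = trk$threshold %||% 0.2,
                          min_area = trk$min_area %||% 9L,
                          gate_px = trk$gate_px %||% 30,
                          max_missed = trk$max_missed %||% 3L,
                          min_len = trk$min_len %||% 6L,
                          stationary_eps = trk$stationary_eps %||% 0.5,
                          stationary_frames = trk$stationary_frames %||% 10L)
    if (nrow(recs)) recs$flight_id <- paste0(i, "_", recs$flight_id)
    out[[i]] <- recs
  }
  recs <- do.call(rbind, out)
  rownames(recs) <- NULL
  apply_flight_filters(recs,
                       sinuosity_max = kin$sinuosity_max %||% 1.1,
                       min_ground_speed = kin$min_ground_speed %||% 0.02,
                       min_height = kin$min_height %||% 0.015)
}
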