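#' Step reference trajectory
#'
#' Builds the desired-output trajectory for a tracking scenario: a step of
#' the given amplitude starting at sample \code{start + delay}. The
#' \code{delay} argument is used by the scenario runner to pass the
#' reference through the plant's transport delay: no controller can move the
#' output during the dead time, so the achievable desired trajectory is the
#' commanded step delayed by \code{d} samples (see the methods vignette).
#'
#' @param n trajectory length (samples).
#' @param amplitude step height (normalized units).
#' @param start commanded step onset (sample index, 0-based).
#' @param delay additional delay in samples (typically the plant dead time).
#' @return numeric vector of length \code{n}.
#' @export
make_reference <- function(n, amplitude = 1, start = 0, delay = 0) {
  k <- seq_len(n) - 1L
  ifelse(k >= start + delay, amplitude, 0)
}

#' Sinusoidal output disturbance
#'
#' Zero-mean sinusoid expressed in display units (mmHg) and mapped to
#' normalized output units by the display span, added at the measured plant
#' output from sample \code{start} onward:
#' \deqn{d(k) = \frac{A}{\mathrm{span}}
#'       \sin\!\left(\frac{2\pi (t_k - t_{start})}{\mathrm{period}} + \phi\right).}
#'
#' @param n sequence length (samples).
#' @param amplitude amplitude in display units (mmHg), >= 0.
#' @param period period in seconds, > 0.
#' @param Ts sampling time (s).
#' @param start entry sample (0-based).
#' @param phase phase offset (radians).
#' @param display_span display mapping span in mmHg (difference between
#'   target and initial MAP; 40 by default).
#' @return numeric vector of length \code{n} in normalized output units.
#' @export
make_disturbance <- function(n, amplitude = 10, period = 100, Ts = 1,
                             start = 0, phase = 0, display_span = 40) {
  abort_if(amplitude < 0, "'amplitude' must be >= 0")
  abort_if(period <= 0, "'period' must be > 0")
  abort_if(display_span <= 0, "'display_span' must be > 0")
  k <- seq_len(n) - 1L
  t <- (k - start) * Ts
  ifelse(k >= start,
         amplitude / display_span * sin(2 * pi * t / period + phase),
         0)
}

#' Scenario definition
#'
#' Bundles plant, controller, reference, disturbance and window settings for
#' one closed-loop experiment. Defaults are the canonical study conditions:
#' the reference patient, GA-MPC with \code{P = 20}, \code{M = 2},
#' \code{mu = 1}, \code{lambda = 0.1}, infusion bounds \code{[0, 2]} ml/h,
#' horizon shift on, a unit-step reference, no disturbance, a 200-sample
#' window at \code{Ts = 1} s, and the 40 -> 80 mmHg display mapping.
#'
#' @param controller one of \code{"ga_mpc"}, \code{"pso_mpc"},
#'   \code{"grid_mpc"}, \code{"pid"}.
#' @param plant a \code{continuous_patient_model}; default the canonical
#'   patient.
#' @param window simulation window (samples).
#' @param Ts sampling time (s).
#' @param seed integer seed (mandatory for the stochastic controllers).
#' @param ref_amplitude,ref_start reference step height and onset.
#' @param dist_amplitude,dist_period,dist_start,dist_phase sinusoidal
#'   disturbance settings (display units / seconds / sample / radians);
#'   amplitude 0 disables the disturbance.
#' @param P,M,mu,lambda,u_min,u_max,horizon_shift MPC settings, see
#'   [mpc_config()].
#' @param ga,pso optimizer settings for the GA and PSO controllers.
#' @param grid_points grid resolution of the plain (grid-search) MPC.
#' @param map_initial,map_target display mapping endpoints (mmHg).
#' @return an object of class \code{map_scenario}.
#' @export
scenario <- function(controller = "ga_mpc", plant = canonical_patient_model(),
                     window = 200L, Ts = 1, seed = 1L,
                     ref_amplitude = 1, ref_start = 0,
                     dist_amplitude = 0, dist_period = 100,
                     dist_start = 0, dist_phase = 0,
                     P = 20L, M = 2L, mu = 1, lambda = 0.1,
                     u_min = 0, u_max = 2, horizon_shift = TRUE,
                     ga = ga_config(), pso = pso_config(),
                     grid_points = 15L,
                     map_initial = 40, map_target = 80) {
  abort_if(!controller %in% c("ga_mpc", "pso_mpc", "grid_mpc", "pid"),
           "'controller' must be one of ga_mpc, pso_mpc, grid_mpc, pid")
  abort_if(!inherits(plant, "continuous_patient_model"),
           "'plant' must be a continuous_patient_model")
  abort_if(controller %in% c("ga_mpc", "pso_mpc") && is.null(seed),
           "stochastic controllers require a seed")
  structure(list(controller = controller, plant = plant,
                 window = as.integer(window), Ts = Ts, seed = seed,
                 ref_amplitude = ref_amplitude, ref_start = ref_start,
                 dist_amplitude = dist_amplitude, dist_period = dist_period,
                 dist_start = dist_start, dist_phase = dist_phase,
                 P = as.integer(P), M = as.integer(M), mu = mu,
                 lambda = lambda, u_min = u_min, u_max = u_max,
                 horizon_shift = horizon_shift,
                 ga = ga, pso = pso, grid_points = as.integer(grid_points),
                 map_initial = map_initial, map_target = map_target),
            class = "map_scenario")
}

#' Read a scenario from a YAML configuration file
#'
#' Recognized keys mirror the [scenario()] arguments; \code{plant} may be a
#' mapping with keys \code{gain}, \code{time_constants} (length 3),
#' \code{alpha}, \code{dead_time_s} for the general patient family, or be
#' omitted for the canonical patient. GA/PSO sub-settings live under
#' \code{ga:} (\code{population}, \code{generations}, \code{p_crossover},
#' \code{p_mutation}, \code{elite}) and \code{pso:}.
#'
#' @param path path to a YAML file.
#' @return a \code{map_scenario}.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$plant)) {
    p <- cfg$plant
    missing <- setdiff(c("gain", "time_constants", "alpha", "dead_time_s"),
                       names(p))
    abort_if(length(missing) > 0,
             paste0("plant.", missing[1], ": missing required key"))
    abort_if(length(p$time_constants) != 3L,
             "plant.time_constants: expected exactly 3 values")
    args$plant <- build_continuous_model(
      K = p$gain, T1 = p$time_constants[[1]], T2 = p$time_constants[[2]],
      T3 = p$time_constants[[3]], alpha = p$alpha, theta = p$dead_time_s)
  }
  if (!is.null(cfg$sampling_time_s)) args$Ts <- cfg$sampling_time_s
  direct <- intersect(names(cfg),
                      c("controller", "window", "Ts", "seed",
                        "ref_amplitude", "ref_start", "dist_amplitude",
                        "dist_period", "dist_start", "dist_phase",
                        "P", "M", "mu", "lambda", "u_min", "u_max",
                        "horizon_shift", "grid_points",
                        "map_initial", "map_target"))
  args[direct] <- cfg[direct]
  if (!is.null(cfg$ga)) args$ga <- do.call(ga_config, cfg$ga)
  if (!is.null(cfg$pso)) args$pso <- do.call(pso_config, cfg$pso)
  do.call(scenario, args)
}

scenario_mpc_config <- function(sc) {
  mpc_config(P = sc$P, M = sc$M, mu = sc$mu, lambda = sc$lambda,
             u_min = sc$u_min, u_max = sc$u_max,
             horizon_shift = sc$horizon_shift)
}

scenario_optimizer <- function(sc) {
  switch(sc$controller,
         ga_mpc = ga_optimizer(sc$ga),
         pso_mpc = pso_optimizer(sc$pso),
         grid_mpc = grid_optimizer(sc$grid_points),
         NULL)
}

# PID closed loop sharing the plant-advance convention of run_closed_loop.
# The PID acts on the raw (undelayed) commanded reference — it has no
# preview, it reacts when the set point changes — while the recorded r
# column is the achievable (delay-aligned) trajectory used by the metrics.
run_pid_loop <- function(dmodel, reference, command, disturbance, gains,
                         n_samples, u_min, u_max,
                         map_initial = 40, map_target = 80) {
  N <- as.integer(n_samples)
  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  pad <- d + n
  y_true <- numeric(N + n); y_meas <- numeric(N + n)
  u_app <- numeric(N + pad)
  a <- dmodel$den_z; b <- dmodel$num_z
  state <- NULL
  for (k in seq_len(N)) {
    iy <- n + k; iu <- pad + k
    y_true[iy] <- sum(b * u_app[iu - d - (seq_along(b) - 1L)]) -
      sum(a[-1] * y_true[iy - seq_len(n)])
    y_meas[iy] <- y_true[iy] + disturbance[k]
    res <- pid_step(gains, command[k] - y_meas[iy], state,
                    Ts = dmodel$Ts, u_min = u_min, u_max = u_max)
    state <- res$state
    u_app[iu] <- res$u
  }
  y <- y_meas[n + seq_len(N)]
  hist <- data.frame(
    t_s = (seq_len(N) - 1L) * dmodel$Ts,
    r = reference[seq_len(N)],
    u = u_app[pad + seq_len(N)],
    y = y,
    d = disturbance[seq_len(N)],
    map_mmHg = map_initial + (map_target - map_initial) * y
  )
  structure(hist, Ts = dmodel$Ts, cost = rep(NA_real_, N),
            u_min = u_min, u_max = u_max,
            class = c("closed_loop_history", "data.frame"))
}

#' Run a scenario end to end
#'
#' Discretizes the plant, builds the reference and disturbance signals,
#' runs the selected controller over the window and computes the IAE / ISE /
#' MSE report. When \code{out_dir} is given, the time series is written as
#' \code{<name>_history.csv} (columns \code{t_s, r, u, y, d, map_mmHg}) and
#' the metrics as \code{<name>_metrics.json}.
#'
#' @param sc a [scenario()].
#' @param out_dir optional output directory (created if needed).
#' @param name basename for output files; defaults to the controller name.
#' @return list with \code{history} (a \code{closed_loop_history}),
#'   \code{metrics} (a \code{metrics_report}) and \code{scenario}.
#' @export
run_scenario <- function(sc, out_dir = NULL, name = sc$controller) {
  abort_if(!inherits(sc, "map_scenario"), "'sc' must be a map_scenario")
  dmodel <- discretize_zoh(sc$plant, sc$Ts)
  N <- sc$window
  w <- make_reference(N, amplitude = sc$ref_amplitude,
                      start = sc$ref_start, delay = dmodel$d)
  dist <- if (sc$dist_amplitude > 0) {
    make_disturbance(N, amplitude = sc$dist_amplitude,
                     period = sc$dist_period, Ts = sc$Ts,
                     start = sc$dist_start, phase = sc$dist_phase,
                     display_span = sc$map_target - sc$map_initial)
  } else numeric(N)

  if (sc$controller == "pid") {
    gains <- ziegler_nichols_tune(sc$plant)
    command <- make_reference(N, amplitude = sc$ref_amplitude,
                              start = sc$ref_start, delay = 0)
    history <- run_pid_loop(dmodel, w, command, dist, gains, N,
                            sc$u_min, sc$u_max, sc$map_initial, sc$map_target)
  } else {
    history <- run_closed_loop(dmodel, w, dist,
                               cfg = scenario_mpc_config(sc),
                               optimizer = scenario_optimizer(sc),
                               n_samples = N, seed = sc$seed,
                               map_initial = sc$map_initial,
                               map_target = sc$map_target)
  }
  metrics <- compute_metrics(history)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_history_csv(history, file.path(out_dir, paste0(name, "_history.csv")))
    jsonlite::write_json(
      list(scenario = name, controller = sc$controller, seed = sc$seed,
           IAE = metrics$IAE, ISE = metrics$ISE, MSE = metrics$MSE,
           N = metrics$N, Ts = metrics$Ts),
      file.path(out_dir, paste0(name, "_metrics.json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(history = history, metrics = metrics, scenario = sc)
}

#' Write a closed-loop history as CSV
#'
#' @param history a \code{closed_loop_history}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_history_csv <- function(history, path) {
  write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' Prediction-horizon sweep
#'
#' Reruns the base scenario for each prediction horizon and tabulates the
#' error criteria, one row per \code{P} (fixed-seed policy: every run uses
#' the scenario's seed).
#'
#' @param P_values integer vector of prediction horizons.
#' @param base a [scenario()].
#' @return data frame with columns \code{P}, \code{ISE}, \code{MSE},
#'   \code{IAE}.
#' @export
sweep_horizon <- function(P_values = c(5L, 20L, 40L), base = scenario()) {
  abort_if(any(P_values < base$M), "each P must be >= M")
  rows <- lapply(P_values, function(P) {
    sc <- base; sc$P <- as.integer(P)
    m <- run_scenario(sc)$metrics
    data.frame(P = P, ISE = m$ISE, MSE = m$MSE, IAE = m$IAE)
  })
  do.call(rbind, rows)
}

#' Controller comparison
#'
#' Runs the same scenario under each controller and tabulates IAE / ISE /
#' MSE (execution time is deliberately not reported: it is
#' hardware-dependent).
#'
#' @param base a [scenario()]; its \code{controller} field is overridden.
#' @param controllers character vector of controller names.
#' @return data frame with columns \code{controller}, \code{IAE},
#'   \code{ISE}, \code{MSE}.
#' @export
compare_controllers <- function(base = scenario(),
                                controllers = c("ga_mpc", "pso_mpc",
                                                "grid_mpc", "pid")) {
  rows <- lapply(controllers, function(ctrl) {
    sc <- base; sc$controller <- ctrl
    m <- run_scenario(sc)$metrics
    data.frame(controller = ctrl, IAE = m$IAE, ISE = m$ISE, MSE = m$MSE)
  })
  do.call(rbind, rows)
}
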