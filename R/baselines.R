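#' PID gains
#'
#' @param Kp,Ki,Kd proportional, integral and derivative gains (controller
#'   units per normalized error). Must be finite.
#' @return an object of class \code{pid_gains}.
#' @export
pid_gains <- function(Kp, Ki = 0, Kd = 0) {
  abort_if(!all(vapply(list(Kp, Ki, Kd), is_scalar_num, logical(1))),
           "PID gains must be finite scalars")
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd), class = "pid_gains")
}

#' One positional PID step
#'
#' Positional PID with trapezoidal integral, derivative on error, output
#' clamping to the plant input bounds and conditional-integration
#' anti-windup (the integral is not advanced when the output is saturated
#' and the error pushes it further into saturation).
#'
#' @param gains a [pid_gains()].
#' @param error current error \code{r - y}.
#' @param state controller state from the previous call, or \code{NULL} at
#'   the first step.
#' @param Ts sampling time (s).
#' @param u_min,u_max actuator bounds.
#' @return list with \code{u} (applied input) and \code{state}.
#' @export
pid_step <- function(gains, error, state = NULL, Ts = 1, u_min = 0, u_max = 2) {
  if (is.null(state)) state <- list(integral = 0, prev_error = NULL)
  e_prev <- state$prev_error
  deriv <- if (is.null(e_prev)) 0 else (error - e_prev) / Ts
  i_inc <- if (is.null(e_prev)) Ts * error else Ts * (error + e_prev) / 2
  integral <- state$integral + i_inc
  u_raw <- gains$Kp * error + gains$Ki * integral + gains$Kd * deriv
  u <- clip(u_raw, u_min, u_max)
  if (!isTRUE(all.equal(u, u_raw)) && sign(i_inc) == sign(u_raw - u)) {
    integral <- state$integral                      # anti-windup: freeze
    u <- clip(gains$Kp * error + gains$Ki * integral + gains$Kd * deriv,
              u_min, u_max)
  }
  list(u = u, state = list(integral = integral, prev_error = error))
}

# Frequency response of a continuous model at angular frequency w (rad/s),
# including the dead time.
freq_response <- function(model, w) {
  s <- 1i * w
  pw <- function(p) {
    acc <- 0 + 0i
    for (j in seq_along(p)) acc <- acc + p[j] * s^(j - 1L)
    acc
  }
  pw(model$num) / pw(model$den) * exp(-model$theta * s)
}

#' Ultimate gain and period of a continuous model
#'
#' Finds the phase-crossover frequency (unwrapped phase = -180 degrees) of
#' the model's frequency response by a log-spaced gain sweep followed by
#' root bisection, then returns the ultimate gain \code{Ku = 1/|G(j w180)|}
#' and ultimate period \code{Tu = 2 pi / w180}.
#'
#' @param model a \code{continuous_patient_model}.
#' @param w_range angular-frequency search interval (rad/s).
#' @return list with \code{Ku}, \code{Tu}, \code{w180}.
#' @export
ultimate_gain <- function(model, w_range = c(1e-5, 1e3)) {
  ws <- exp(seq(log(w_range[1]), log(w_range[2]), length.out = 4000L))
  ph <- Arg(freq_response(model, ws[1]))
  phs <- numeric(length(ws))
  for (i in seq_along(ws)) {                        # unwrap along the sweep
    p <- Arg(freq_response(model, ws[i]))
    while (p - ph > pi) p <- p - 2 * pi
    while (p - ph < -pi) p <- p + 2 * pi
    phs[i] <- p; ph <- p
  }
  idx <- which(phs[-1] <= -pi & phs[-length(phs)] > -pi)
  if (length(idx) == 0L) {
    stop(paste("phase never crosses -180 degrees in the searched range;",
               "no finite ultimate gain (consider the reaction-curve method)"),
         call. = FALSE)
  }
  i <- idx[1]
  f <- function(w) {
    # local unwrapped phase relative to the bracketing sweep point
    p <- Arg(freq_response(model, w))
    while (p - phs[i] > pi) p <- p - 2 * pi
    while (p - phs[i] < -pi) p <- p + 2 * pi
    p + pi
  }
  w180 <- uniroot(f, c(ws[i], ws[i + 1L]), tol = 1e-12)$root
  Ku <- 1 / Mod(freq_response(model, w180))
  list(Ku = Ku, Tu = 2 * pi / w180, w180 = w180)
}

#' Ziegler-Nichols PID tuning (ultimate-cycle method)
#'
#' Classic closed-loop Ziegler-Nichols rules applied to the automatically
#' determined ultimate gain and period:
#' \code{Kp = 0.6 Ku}, \code{Ki = 1.2 Ku / Tu}, \code{Kd = 0.075 Ku Tu}.
#'
#' @param model a \code{continuous_patient_model}. Models whose phase never
#'   reaches -180 degrees (e.g. a pure first-order lag without delay) have
#'   no finite ultimate gain and raise an error.
#' @return a [pid_gains()] object.
#' @examples
#' g <- ziegler_nichols_tune(canonical_patient_model())
#' @export
ziegler_nichols_tune <- function(model) {
  abort_if(!inherits(model, "continuous_patient_model"),
           "'model' must be a continuous_patient_model")
  uc <- ultimate_gain(model)
  pid_gains(Kp = 0.6 * uc$Ku,
            Ki = 1.2 * uc$Ku / uc$Tu,
            Kd = 0.075 * uc$Ku * uc$Tu)
}

#' Particle-swarm configuration
#'
#' Defaults are budget-matched to the GA (about 1000 objective evaluations
#' per control step): swarm 30, 33 iterations, inertia 0.7, cognitive and
#' social coefficients 1.5.
#'
#' @param swarm swarm size (>= 2).
#' @param iterations number of iterations (>= 1).
#' @param inertia inertia weight.
#' @param cognitive,social acceleration coefficients (>= 0).
#' @param seed optional integer seed.
#' @return an object of class \code{pso_config}.
#' @export
pso_config <- function(swarm = 30L, iterations = 33L, inertia = 0.7,
                       cognitive = 1.5, social = 1.5, seed = NULL) {
  abort_if(swarm < 2, "'swarm' must be >= 2")
  abort_if(iterations < 1, "'iterations' must be >= 1")
  abort_if(cognitive < 0 || social < 0, "acceleration coefficients must be >= 0")
  structure(list(swarm = as.integer(swarm), iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = seed),
            class = "pso_config")
}

#' Global-best particle swarm optimization
#'
#' Standard gbest PSO over a bounded box with velocity clamping (half the
#' bound width) and bound reflection. Seed candidates are injected as
#' initial particle positions. Deterministic given the RNG state (or
#' \code{cfg$seed}).
#'
#' @param objective function chromosome -> scalar cost.
#' @param bounds M x 2 matrix of per-gene bounds.
#' @param cfg a [pso_config()].
#' @param seeds optional matrix of initial candidate rows.
#' @return list with \code{par}, \code{value} and \code{trace} (global best
#'   per iteration, non-increasing).
#' @export
pso_optimize <- function(objective, bounds, cfg = pso_config(), seeds = NULL) {
  bounds <- check_bounds(bounds)
  M <- nrow(bounds)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  width <- hi - lo
  vmax <- 0.5 * width
  ns <- cfg$swarm

  X <- matrix(runif(ns * M, rep(lo, each = ns), rep(hi, each = ns)), ns, M)
  if (!is.null(seeds)) {
    seeds <- matrix(seeds, ncol = M)
    for (i in seq_len(min(nrow(seeds), ns))) X[i, ] <- clip(seeds[i, ], lo, hi)
  }
  V <- matrix(runif(ns * M, rep(-vmax, each = ns), rep(vmax, each = ns)), ns, M)
  fit <- eval_population(objective, X)
  Pb <- X; pbfit <- fit
  gi <- which.min(fit); gb <- X[gi, ]; gbfit <- fit[gi]
  trace <- numeric(cfg$iterations)

  for (it in seq_len(cfg$iterations)) {
    r1 <- matrix(runif(ns * M), ns, M)
    r2 <- matrix(runif(ns * M), ns, M)
    V <- cfg$inertia * V +
      cfg$cognitive * r1 * (Pb - X) +
      cfg$social * r2 * (matrix(gb, ns, M, byrow = TRUE) - X)
    V <- clip(V, matrix(-vmax, ns, M, byrow = TRUE),
              matrix(vmax, ns, M, byrow = TRUE))
    X <- X + V
    # reflect off the bounds, reversing the velocity component
    for (j in seq_len(M)) {
      under <- X[, j] < lo[j]; over <- X[, j] > hi[j]
      X[under, j] <- 2 * lo[j] - X[under, j]
      X[over, j] <- 2 * hi[j] - X[over, j]
      V[under | over, j] <- -V[under | over, j]
      X[, j] <- clip(X[, j], lo[j], hi[j])          # guard huge overshoots
    }
    fit <- eval_population(objective, X)
    better <- fit < pbfit
    Pb[better, ] <- X[better, , drop = FALSE]; pbfit[better] <- fit[better]
    gi <- which.min(pbfit)
    if (pbfit[gi] < gbfit) { gbfit <- pbfit[gi]; gb <- Pb[gi, ] }
    trace[it] <- gbfit
  }
  list(par = gb, value = gbfit, trace = trace)
}
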