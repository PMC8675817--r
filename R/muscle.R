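#' Viscoelastic heart-muscle model
#'
#' Mass-spring-damper idealization of the heart muscle together with the
#' pressure transducer and injection set: an inertia \code{J} rotating by
#' angle \eqn{\theta}, a series spring of stiffness \code{k} (muscle-tissue
#' tension) and a damper of viscosity \code{B} (resistance of muscle,
#' injection liquid and set). Torque balance plus the damper relation give
#' the third-order kinetic equation
#' \deqn{\frac{BJ}{k}\dddot\theta + J\ddot\theta + B\dot\theta
#'       = M_x(t) - M_0(t),}
#' with \eqn{M_x} the applied (pressure-increase) torque and \eqn{M_0} the
#' baseline torque the muscle produces at rest.
#'
#' @param J inertia (torque·s² per rad), > 0.
#' @param B viscosity (torque·s per rad), > 0.
#' @param k stiffness (torque per rad), > 0.
#' @return an object of class \code{muscle_model}.
#' @export
muscle_model <- function(J = 1, B = 1, k = 1) {
  for (nm in c("J", "B", "k")) {
    v <- get(nm)
    abort_if(!is_scalar_num(v) || v <= 0,
             sprintf("'%s' must be a positive scalar", nm))
  }
  structure(list(J = J, B = B, k = k), class = "muscle_model")
}

#' Transfer function of the muscle model
#'
#' Laplace form of the kinetic equation with zero initial conditions,
#' \eqn{\theta(s)/\Delta M(s) = 1 / (s ((BJ/k) s^2 + J s + B))} where
#' \eqn{\Delta M = M_x - M_0}. Returned as a \code{continuous_patient_model}
#' (zero dead time) so the generic transfer-function tooling — DC analysis,
#' [discretize_zoh()], [simulate_response()] — applies. The ascending
#' denominator coefficients read back as \code{(0, B, J, BJ/k)}.
#'
#' @param model a [muscle_model()].
#' @return a \code{continuous_patient_model} with \code{num = 1},
#'   \code{den = c(0, B, J, B*J/k)}, \code{theta = 0}.
#' @export
muscle_transfer_function <- function(model) {
  abort_if(!inherits(model, "muscle_model"), "'model' must be a muscle_model")
  new_continuous_model(num = 1,
                       den = c(0, model$B, model$J, model$B * model$J / model$k),
                       theta = 0)
}

#' Simulate the muscle model
#'
#' Integrates the kinetic equation numerically from rest with lsoda
#' (interval-wise constant torques, matching the sampled inputs), and
#' recovers the internal muscle torque from the torque balance,
#' \eqn{M(t) = M_x(t) - J\ddot\theta(t)}.
#'
#' For a constant torque difference \eqn{\Delta M = A} the angular velocity
#' settles at \eqn{A/B} (final-value theorem on
#' \eqn{\dot\theta(s)/\Delta M(s)}).
#'
#' @param model a [muscle_model()].
#' @param Mx applied-torque sequence, length \code{n}.
#' @param M0 baseline-torque sequence, length \code{n} (default zeros).
#' @param Ts sampling time (s).
#' @param n number of samples; defaults to \code{length(Mx)}.
#' @return data frame with columns \code{t_s}, \code{theta},
#'   \code{theta_dot}, \code{torque}.
#' @examples
#' mm <- muscle_model(J = 1, B = 2, k = 1)
#' out <- simulate_muscle(mm, Mx = rep(1, 200), Ts = 0.5)
#' tail(out$theta_dot, 1)  # approaches 1 / B = 0.5
#' @export
simulate_muscle <- function(model, Mx, M0 = NULL, Ts = 1, n = length(Mx)) {
  abort_if(!inherits(model, "muscle_model"), "'model' must be a muscle_model")
  abort_if(!is_scalar_num(Ts) || Ts <= 0, "'Ts' must be a positive scalar")
  n <- as.integer(n)
  abort_if(length(Mx) < n, "'Mx' shorter than the requested horizon")
  if (is.null(M0)) M0 <- numeric(n)
  abort_if(length(M0) < n, "'M0' shorter than the requested horizon")
  dM <- Mx[seq_len(n)] - M0[seq_len(n)]

  c3 <- model$B * model$J / model$k
  deriv <- function(t, y, parms) {
    # y = (theta, theta_dot, theta_ddot)
    list(c(y[2], y[3], (parms$dm - model$J * y[3] - model$B * y[2]) / c3))
  }
  state <- c(0, 0, 0)
  theta <- numeric(n); theta_dot <- numeric(n); theta_dd <- numeric(n)
  for (k in seq_len(n)) {
    # state at the start of the interval is the sample at t = (k-1) Ts
    theta[k] <- state[1]; theta_dot[k] <- state[2]; theta_dd[k] <- state[3]
    sol <- deSolve::lsoda(state, c(0, Ts), deriv, parms = list(dm = dM[k]),
                          rtol = 1e-11, atol = 1e-12)
    abort_if(any(!is.finite(sol[2, -1])),
             "integration failed; try a smaller Ts")
    state <- unname(sol[2, -1])
  }
  data.frame(t_s = (seq_len(n) - 1L) * Ts,
             theta = theta,
             theta_dot = theta_dot,
             torque = Mx[seq_len(n)] - model$J * theta_dd)
}
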