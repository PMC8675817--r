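#' Continuous MAP/SNP patient model
#'
#' The pharmacodynamic response of mean arterial pressure (MAP) to
#' sodium-nitroprusside (SNP) infusion is modelled as a rational transfer
#' function with a transport delay,
#' \deqn{G(s) = \frac{K (1 + T_3 s)\, e^{-\theta s}}
#'                   {((1 + T_3 s)(1 + T_2 s) - \alpha)(1 + T_1 s)},}
#' where \eqn{K} is the patient's drug sensitivity (mmHg per ml/h),
#' \eqn{T_1,T_2,T_3} are drug-effect time constants (s), \eqn{\alpha} is the
#' recirculation fraction and \eqn{\theta} the transport dead time (s).
#' The denominator is expanded to polynomial form and normalized to unit
#' constant term.
#'
#' @param K patient sensitivity (gain), any nonzero finite number.
#' @param T1,T2,T3 time constants in seconds, strictly positive.
#' @param alpha recirculation constant, \code{0 <= alpha < 1}.
#' @param theta transport dead time in seconds, \code{theta >= 0}.
#' @return an object of class \code{continuous_patient_model} with fields
#'   \code{num}, \code{den} (ascending-power polynomial coefficients in s,
#'   constant term of \code{den} normalized to 1) and \code{theta}.
#' @seealso [canonical_patient_model()], [discretize_zoh()], [dc_gain()]
#' @examples
#' m <- build_continuous_model(K = 5, T1 = 50, T2 = 20, T3 = 30,
#'                             alpha = 0.2, theta = 60)
#' dc_gain(m)  # K / (1 - alpha)
#' @export
build_continuous_model <- function(K, T1, T2, T3, alpha, theta) {
  abort_if(!is_scalar_num(K) || K == 0, "'K' must be a nonzero finite scalar")
  for (nm in c("T1", "T2", "T3")) {
    v <- get(nm)
    abort_if(!is_scalar_num(v) || v <= 0,
             sprintf("time constant '%s' must be a positive scalar", nm))
  }
  abort_if(!is_scalar_num(alpha) || alpha < 0 || alpha >= 1,
           "'alpha' must satisfy 0 <= alpha < 1")
  abort_if(!is_scalar_num(theta) || theta < 0, "'theta' must be >= 0")

  num <- K * c(1, T3)
  # ((1 + T3 s)(1 + T2 s) - alpha)(1 + T1 s), ascending powers of s
  inner <- poly_mul(c(1, T3), c(1, T2))
  inner[1] <- inner[1] - alpha
  den <- poly_mul(inner, c(1, T1))
  new_continuous_model(num / den[1], den / den[1], theta)
}

new_continuous_model <- function(num, den, theta) {
  abort_if(den[1] < 0, "denominator constant term must be nonnegative")
  structure(
    list(num = trim_poly(num), den = trim_poly(den), theta = theta),
    class = "continuous_patient_model"
  )
}

#' Canonical patient model instance
#'
#' The reference patient used throughout the experiments:
#' \deqn{G_p(s) = \frac{5 (1 + 30 s)\, e^{-60 s}}{1 + 130 s + 4600 s^2 + 30000 s^3}.}
#' Only this composite polynomial form is given for the reference patient;
#' the individual gain/time-constant decomposition is not, so the instance is
#' stored directly in polynomial form rather than through
#' [build_continuous_model()].
#'
#' @return a \code{continuous_patient_model}: DC gain 5, dead time 60 s,
#'   numerator degree 1, denominator degree 3, asymptotically stable.
#' @examples
#' g <- canonical_patient_model()
#' dc_gain(g)          # 5
#' g$theta             # 60
#' Re(poles(g))        # all negative
#' @export
canonical_patient_model <- function() {
  new_continuous_model(num = c(5, 150),
                       den = c(1, 130, 4600, 30000),
                       theta = 60)
}

#' DC gain of a model
#'
#' Steady-state gain: \eqn{G(0)} for a continuous model, \eqn{H(1)} for a
#' discrete one.
#' @param model a \code{continuous_patient_model} or \code{discrete_patient_model}.
#' @return scalar gain.
#' @export
dc_gain <- function(model) UseMethod("dc_gain")

#' @export
dc_gain.continuous_patient_model <- function(model) model$num[1] / model$den[1]

#' @export
dc_gain.discrete_patient_model <- function(model) sum(model$num_z) / sum(model$den_z)

#' Poles of a model
#'
#' Roots of the denominator: in the s-plane for a continuous model, in the
#' z-plane (delay-free part) for a discrete one.
#' @param model a patient model object.
#' @return complex vector of poles.
#' @export
poles <- function(model) UseMethod("poles")

#' @export
poles.continuous_patient_model <- function(model) {
  if (length(model$den) == 1L) return(complex(0))
  polyroot(model$den)
}

#' @export
poles.discrete_patient_model <- function(model) {
  if (length(model$den_z) == 1L) return(complex(0))
  polyroot(rev(model$den_z))
}

#' @export
print.continuous_patient_model <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = ", ")
  cat("Continuous patient model (ascending powers of s)\n")
  cat("  numerator:  ", fmt(x$num), "\n")
  cat("  denominator:", fmt(x$den), "\n")
  cat("  dead time:  ", x$theta, "s\n")
  cat("  DC gain:    ", signif(dc_gain(x), 6), "\n")
  invisible(x)
}

# ---- zero-order-hold discretization -----------------------------------------

# Controllable-canonical state-space realization of a proper rational
# transfer function given by ascending num/den coefficient vectors.
tf_to_ss <- function(num, den) {
  n <- length(den) - 1L                       # system order
  abort_if(length(num) > length(den),
           "transfer function must be proper (deg num <= deg den)")
  dend <- rev(den) / den[length(den)]         # descending, monic
  numd <- rev(num) / den[length(den)]         # descending, same scale
  numd <- c(numeric(n + 1L - length(numd)), numd)
  D <- numd[1]
  # remainder coefficients after removing the feedthrough
  bcoef <- numd[-1] - D * dend[-1]            # length n, descending z^(n-1)..z^0
  A <- rbind(-dend[-1],
             cbind(diag(1, n - 1L), numeric(n - 1L)))
  if (n == 1L) A <- matrix(-dend[2], 1L, 1L)
  B <- matrix(c(1, numeric(n - 1L)), n, 1L)
  C <- matrix(bcoef, 1L, n)
  list(A = A, B = B, C = C, D = D, n = n)
}

# Faddeev-LeVerrier: characteristic polynomial of A (monic, descending) and
# the coefficients of C adj(zI - A) B, so that
# H(z) = (C adj(zI-A) B) / charpoly(z) + D.
faddeev_tf <- function(A, B, C, D) {
  n <- nrow(A)
  Mk <- diag(1, n)
  cs <- numeric(n + 1L); cs[1] <- 1
  ns <- numeric(n)                            # numerator, descending z^(n-1)..z^0
  for (k in seq_len(n)) {
    ns[k] <- drop(C %*% Mk %*% B)
    AM <- A %*% Mk
    cs[k + 1L] <- -sum(diag(AM)) / k
    Mk <- AM + cs[k + 1L] * diag(1, n)
  }
  list(num = ns + D * cs[-1] , den = cs, num0 = D)
}

#' Zero-order-hold discretization
#'
#' Computes the exact ZOH equivalent of the delay-free part of a continuous
#' patient model via the augmented matrix exponential, and represents the
#' transport delay as an integer number of samples \code{d = round(theta/Ts)}
#' (a warning is issued when \code{theta} is not an integer multiple of
#' \code{Ts}).
#'
#' @param model a \code{continuous_patient_model}.
#' @param Ts sampling time in seconds, \code{Ts > 0}.
#' @return an object of class \code{discrete_patient_model} with fields
#'   \code{num_z}, \code{den_z} (descending powers of z, \code{den_z} monic,
#'   \code{num_z[1]} the direct feedthrough, zero for strictly proper models),
#'   integer sample delay \code{d} and \code{Ts}. For the canonical patient at
#'   \code{Ts = 1} the order-3 coefficients reproduce the benchmark values
#'   (a0 = -0.8578, a1 = 2.712, a2 = -2.854; b0 = -0.002233,
#'   b1 = -1.543e-5, b2 = 0.002403) and \code{d = 60}.
#' @examples
#' dp <- discretize_zoh(canonical_patient_model(), Ts = 1)
#' dp$d            # 60
#' dc_gain(dp)     # 5
#' @export
discretize_zoh <- function(model, Ts) {
  abort_if(!inherits(model, "continuous_patient_model"),
           "'model' must be a continuous_patient_model")
  abort_if(!is_scalar_num(Ts) || Ts <= 0, "'Ts' must be a positive scalar")
  d <- model$theta / Ts
  if (abs(d - round(d)) > 1e-9) {
    warning(sprintf("dead time %g s is not an integer multiple of Ts = %g s; rounding delay to %d samples",
                    model$theta, Ts, round(d)))
  }
  d <- as.integer(round(d))

  if (length(model$den) == 1L) {              # static gain
    K <- model$num[1] / model$den[1]
    return(new_discrete_model(num_z = K, den_z = 1, d = d, Ts = Ts))
  }
  ss <- tf_to_ss(model$num, model$den)
  n <- ss$n
  aug <- rbind(cbind(ss$A, ss$B), matrix(0, 1L, n + 1L))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(aug * Ts)))
  abort_if(any(!is.finite(E)),
           "matrix exponential of the ZOH map is not finite; check model conditioning")
  Ad <- E[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- E[seq_len(n), n + 1L, drop = FALSE]
  ft <- faddeev_tf(Ad, Bd, ss$C, ss$D)
  new_discrete_model(num_z = c(ft$num0, ft$num), den_z = ft$den, d = d, Ts = Ts)
}

new_discrete_model <- function(num_z, den_z, d, Ts) {
  structure(list(num_z = num_z, den_z = den_z, d = as.integer(d), Ts = Ts),
            class = "discrete_patient_model")
}

#' @export
print.discrete_patient_model <- function(x, ...) {
  fmt <- function(p) paste(signif(p, 6), collapse = ", ")
  cat("Discrete patient model (descending powers of z)\n")
  cat("  numerator:  ", fmt(x$num_z), "\n")
  cat("  denominator:", fmt(x$den_z), "\n")
  cat("  delay:      ", x$d, "samples   Ts:", x$Ts, "s\n")
  cat("  DC gain:    ", signif(dc_gain(x), 6), "\n")
  invisible(x)
}

# ---- simulation -------------------------------------------------------------

#' Simulate a discrete patient model
#'
#' Runs the difference equation of the delayed ARX form; for the canonical
#' order-3 patient this is
#' \deqn{y(k) = -a_2 y(k-1) - a_1 y(k-2) - a_0 y(k-3)
#'        + b_2 u(k-d-1) + b_1 u(k-d-2) + b_0 u(k-d-3),}
#' after which the (output-additive) disturbance sample is added to form the
#' measured output.
#'
#' @param dmodel a \code{discrete_patient_model}.
#' @param u input sequence (infusion rate, ml/h) for \code{k = 0..N-1}.
#' @param disturbance optional output-additive sequence of the same length.
#' @param init optional initial history, a list with components \code{y}
#'   (past noise-free outputs, most recent first, up to \code{n} values) and
#'   \code{u} (past inputs, most recent first, up to \code{d + n} values).
#'   Missing values default to zero (patient at baseline).
#' @param n_samples number of output samples to produce; defaults to
#'   \code{length(u)}. \code{u} must cover the horizon.
#' @return numeric vector of measured outputs \code{y(0..N-1)}.
#' @examples
#' dp <- discretize_zoh(canonical_patient_model(), Ts = 1)
#' y <- simulate_response(dp, u = rep(1, 400))
#' tail(y, 1)  # approaches 5
#' @export
simulate_response <- function(dmodel, u, disturbance = NULL, init = NULL,
                              n_samples = length(u)) {
  abort_if(!inherits(dmodel, "discrete_patient_model"),
           "'dmodel' must be a discrete_patient_model")
  N <- as.integer(n_samples)
  abort_if(length(u) < N, "input sequence shorter than the requested horizon")
  if (!is.null(disturbance)) {
    abort_if(length(disturbance) < N,
             "disturbance sequence shorter than the requested horizon")
  }
  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  hist_y <- numeric(n)
  hist_u <- numeric(d + n)
  if (!is.null(init)) {
    if (!is.null(init$y)) {
      abort_if(length(init$y) > n, "init$y longer than the model order")
      hist_y[seq_along(init$y)] <- init$y
    }
    if (!is.null(init$u)) {
      abort_if(length(init$u) > d + n, "init$u longer than delay + order")
      hist_u[seq_along(init$u)] <- init$u
    }
  }
  # padded arrays: index k maps to k + off
  ypad <- c(rev(hist_y), numeric(N))
  upad <- c(rev(hist_u), u[seq_len(N)])
  off_y <- n
  off_u <- d + n
  a <- dmodel$den_z
  b <- dmodel$num_z
  for (k in seq_len(N)) {
    ar <- if (n > 0L) sum(a[-1] * ypad[off_y + k - seq_len(n)]) else 0
    xr <- sum(b * upad[off_u + k - d - (seq_along(b) - 1L)])
    ypad[off_y + k] <- xr - ar
  }
  y <- ypad[off_y + seq_len(N)]
  if (!is.null(disturbance)) y <- y + disturbance[seq_len(N)]
  y
}

#' Unit-step response of a discrete patient model
#'
#' Thin wrapper over [simulate_response()] with a unit-step input from zero
#' initial conditions. The first \code{d} samples are exactly zero (transport
#' delay); the final value approaches the DC gain for a stable model.
#'
#' @param dmodel a \code{discrete_patient_model}.
#' @param n_samples number of samples; must exceed the sample delay.
#' @return numeric vector of outputs.
#' @export
step_response <- function(dmodel, n_samples) {
  abort_if(n_samples <= dmodel$d,
           "n_samples must exceed the sample delay for a visible response")
  simulate_response(dmodel, u = rep(1, n_samples))
}
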