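#' MPC configuration
#'
#' Settings for the receding-horizon predictive controller. The benchmark
#' tuning for the MAP loop is \code{P = 20}, \code{M = 2}, output weights
#' \code{mu = 1}, move weights \code{lambda = 0.1} and the infusion-rate
#' bound \code{u <= 2} ml/h; the lower bound 0 reflects that an infusion
#' pump cannot withdraw drug.
#'
#' `horizon_shift` addresses the transport delay: with a dead time of
#' \code{d} samples, the first \code{d} future outputs cannot be influenced
#' by the current move. With the flag on (default), the \code{P} costed
#' predictions are \eqn{\hat y(t+d+1), \ldots, \hat y(t+d+P)} — the cost
#' window starts where the plant becomes reachable, functionally a
#' Smith-predictor arrangement. With the flag off the literal window
#' \eqn{\hat y(t+1..t+P)} is costed, which is degenerate whenever
#' \code{P <= d}.
#'
#' @param P prediction horizon (samples, >= 1).
#' @param M control horizon (samples, \code{1 <= M <= P}).
#' @param mu per-step output weights (recycled to length \code{P}).
#' @param lambda per-step move weights (recycled to length \code{M}).
#' @param u_min,u_max input bounds (ml/h), \code{u_min < u_max}.
#' @param horizon_shift logical; shift the costed window past the dead time.
#' @return an object of class \code{mpc_config}.
#' @export
mpc_config <- function(P = 20L, M = 2L, mu = 1, lambda = 0.1,
                       u_min = 0, u_max = 2, horizon_shift = TRUE) {
  abort_if(P < 1, "'P' must be >= 1")
  abort_if(M < 1 || M > P, "'M' must satisfy 1 <= M <= P")
  mu <- rep_len(mu, P); lambda <- rep_len(lambda, M)
  abort_if(any(mu < 0) || any(lambda < 0), "weights must be nonnegative")
  abort_if(u_min >= u_max, "'u_min' must be < 'u_max'")
  structure(list(P = as.integer(P), M = as.integer(M), mu = mu,
                 lambda = lambda, u_min = u_min, u_max = u_max,
                 horizon_shift = isTRUE(horizon_shift)),
            class = "mpc_config")
}

# Reconstruct the future input sequence implied by a move chromosome:
# u(t+j) = u_prev + cumsum(moves), held after the M-th move, clipped to the
# input bounds. Returns the clipped sequence and the effective increments.
reconstruct_u <- function(u_prev, moves, L, cfg) {
  m_pad <- c(moves, numeric(max(0L, L - length(moves))))[seq_len(L)]
  u <- numeric(L)
  prev <- u_prev
  for (j in seq_len(L)) {                   # sequential clipped accumulation
    prev <- clip(prev + m_pad[j], cfg$u_min, cfg$u_max)
    u[j] <- prev
  }
  eff <- diff(c(u_prev, u[seq_len(min(length(moves), L))]))
  list(u = u, eff_moves = eff)
}

#' Model-based output prediction over the horizon
#'
#' Predicts the plant outputs at the \code{P} costed instants for a candidate
#' move sequence, holding the input constant after the \code{M}-th move.
#' The prediction runs the exact plant difference equation seeded with the
#' supplied history (the controller assumes no plant–model mismatch).
#' Histories run up to time \code{t - 1}; the first move applies at \code{t}
#' (the controller computes within one sampling period, so the newest
#' measurement it can use is one sample old).
#'
#' @param dmodel a \code{discrete_patient_model}.
#' @param past_y measured outputs through \code{t - 1}, most recent first;
#'   at least \code{n} values (model order).
#' @param past_u applied inputs through \code{t - 1}, most recent first;
#'   at least \code{d + n} values.
#' @param moves candidate move sequence \eqn{\Delta u} of length \code{M}.
#' @param cfg an [mpc_config()].
#' @return numeric vector of length \code{P}: predicted outputs at
#'   \eqn{t+d+1..t+d+P} (horizon shift on) or \eqn{t+1..t+P} (off).
#' @export
mpc_predict <- function(dmodel, past_y, past_u, moves, cfg) {
  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  abort_if(length(moves) != cfg$M, "'moves' must have length M")
  abort_if(length(past_y) < n,
           sprintf("'past_y' must supply at least %d values", n))
  abort_if(length(past_u) < d + n,
           sprintf("'past_u' must supply at least %d values", d + n))
  L <- cfg$P + 1L + if (cfg$horizon_shift) d else 0L
  u_prev <- past_u[1]
  rec <- reconstruct_u(u_prev, moves, L, cfg)
  y <- simulate_response(dmodel, u = rec$u, n_samples = L,
                         init = list(y = past_y[seq_len(n)],
                                     u = past_u[seq_len(d + n)]))
  tail(y, cfg$P)
}

#' Quadratic MPC cost
#'
#' \deqn{J = \sum_{i=1}^{P} \mu_i (\hat y_i - w_i)^2
#'         + \sum_{i=1}^{M} \lambda_i \Delta u_i^2.}
#'
#' @param predicted predicted outputs (length \code{P}).
#' @param desired reference trajectory at the same instants (length \code{P}).
#' @param moves control increments (length \code{M}).
#' @param cfg an [mpc_config()].
#' @return scalar cost.
#' @export
mpc_cost <- function(predicted, desired, moves, cfg) {
  abort_if(length(predicted) != cfg$P || length(desired) != cfg$P,
           "'predicted' and 'desired' must have length P")
  abort_if(length(moves) != cfg$M, "'moves' must have length M")
  sum(cfg$mu * (predicted - desired)^2) + sum(cfg$lambda * moves^2)
}

# Move-sequence objective for one control step. The prediction is affine in
# the (clipped) moves: yhat = free + S eff, so whole populations can be
# costed in one matrix product; the returned closure accepts either a single
# chromosome or a population matrix (rows = chromosomes) and carries
# attr "vectorized" so the optimizers can exploit it.
make_move_objective <- function(u_prev, free, S, wseg, cfg) {
  mu <- cfg$mu; lambda <- cfg$lambda
  u_min <- cfg$u_min; u_max <- cfg$u_max
  M <- cfg$M
  f <- function(m) {
    m <- if (is.matrix(m)) m else matrix(m, 1L)
    prev <- rep(u_prev, nrow(m))
    E <- matrix(0, nrow(m), M)
    for (j in seq_len(M)) {                 # clipped cumulative input
      uj <- clip(prev + m[, j], u_min, u_max)
      E[, j] <- uj - prev
      prev <- uj
    }
    err <- E %*% t(S) + rep(free - wseg, each = nrow(m))
    drop(err^2 %*% mu + E^2 %*% lambda)
  }
  attr(f, "vectorized") <- TRUE
  f
}

# Forced-response matrix: S[i, j] is the output contribution at the i-th
# costed instant of a unit input step applied at t + j - 1 and held. Shared
# by every control step (the plant is time-invariant).
forced_matrix <- function(dmodel, cfg) {
  d <- if (cfg$horizon_shift) dmodel$d else 0L
  L <- cfg$P + d
  ystep <- simulate_response(dmodel, u = rep(1, L + 1L))  # ystep[m+1] = y(m)
  S <- matrix(0, cfg$P, cfg$M)
  ci <- d + seq_len(cfg$P)
  for (j in seq_len(cfg$M)) {
    m <- ci - (j - 1L)
    S[, j] <- ifelse(m >= 0L, ystep[pmax(m, 0L) + 1L], 0)
  }
  S
}

#' One receding-horizon control step
#'
#' Optimizes the \code{M}-move sequence against [mpc_cost()] with the
#' supplied optimizer, applies only the first move and clips the applied
#' input to \code{[u_min, u_max]}. Candidate genes are bounded by
#' \code{[u_min - u_prev, u_max - u_prev]} so every evaluated input sequence
#' is feasible, and the all-zero move chromosome is always seeded into the
#' optimizer's initial candidate set (the optimized cost therefore never
#' exceeds the cost of inaction).
#'
#' @param dmodel a \code{discrete_patient_model}.
#' @param history list with \code{y} (measured outputs) and \code{u}
#'   (applied inputs), both most recent first.
#' @param reference desired outputs at the \code{P} costed instants.
#' @param cfg an [mpc_config()].
#' @param optimizer a move-sequence optimizer:
#'   \code{function(objective, bounds, seeds)} returning a list with
#'   \code{par} and \code{value}; see [ga_optimizer()], [grid_optimizer()],
#'   [pso_optimizer()].
#' @return list: \code{u} (applied input), \code{moves} (effective
#'   increments), \code{value} (optimized cost), \code{clipped} (logical),
#'   \code{opt} (raw optimizer result).
#' @export
mpc_control_step <- function(dmodel, history, reference, cfg, optimizer) {
  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  abort_if(length(reference) != cfg$P, "'reference' must have length P")
  abort_if(length(history$y) < n || length(history$u) < d + n,
           "insufficient history for the model order and delay")
  u_prev <- history$u[1]
  L <- cfg$P + 1L + if (cfg$horizon_shift) d else 0L

  free <- simulate_response(dmodel, u = rep(u_prev, L), n_samples = L,
                            init = list(y = history$y[seq_len(n)],
                                        u = history$u[seq_len(d + n)]))
  free <- tail(free, cfg$P)
  S <- forced_matrix(dmodel, cfg)
  lo <- cfg$u_min - u_prev; hi <- cfg$u_max - u_prev
  objective <- make_move_objective(u_prev, free, S, reference, cfg)
  bounds <- cbind(rep(lo, cfg$M), rep(hi, cfg$M))
  res <- optimizer(objective, bounds, seeds = matrix(0, 1L, cfg$M))
  abort_if(length(res$par) != cfg$M,
           "optimizer returned a chromosome of the wrong length")
  rec <- reconstruct_u(u_prev, res$par, L, cfg)
  u_t <- rec$u[1]
  list(u = u_t, moves = rec$eff_moves, value = res$value,
       clipped = !isTRUE(all.equal(u_prev + res$par[1], u_t)), opt = res)
}

#' Run the receding-horizon closed loop
#'
#' Executes optimize / apply-first-move / advance-plant / measure for
#' \code{n_samples} steps. The controller feeds back the measured output
#' (including any output-additive disturbance) through the model difference
#' equation, with one sample of computation latency: \code{u(t)} is computed
#' from measurements through \code{t - 1}, the standard timing when the move
#' optimization occupies a sizeable fraction of the sampling period. The
#' increment parameterization of the moves provides integral action, so step
#' references are tracked with zero steady-state error. The reference is
#' extended by last-value hold beyond the simulation window for prediction
#' purposes. Deterministic given \code{seed}.
#'
#' @param dmodel a \code{discrete_patient_model}.
#' @param reference desired-output trajectory \code{w(k)}, \code{k = 0..N-1}
#'   (normalized units).
#' @param disturbance optional output-additive sequence (normalized units).
#' @param cfg an [mpc_config()].
#' @param optimizer a move-sequence optimizer factory result; see
#'   [mpc_control_step()].
#' @param n_samples simulation window length; defaults to
#'   \code{length(reference)}.
#' @param seed optional integer seed applied once before the loop.
#' @param map_initial,map_target display mapping to absolute MAP:
#'   \code{map_mmHg = map_initial + (map_target - map_initial) * y}.
#' @return a \code{closed_loop_history}: data frame with columns \code{t_s},
#'   \code{r}, \code{u}, \code{y}, \code{d}, \code{map_mmHg}; attributes
#'   \code{Ts}, \code{cost} (per-step optimized cost), \code{u_min},
#'   \code{u_max}.
#' @export
run_closed_loop <- function(dmodel, reference, disturbance = NULL,
                            cfg = mpc_config(), optimizer = ga_optimizer(),
                            n_samples = length(reference), seed = NULL,
                            map_initial = 40, map_target = 80) {
  N <- as.integer(n_samples)
  abort_if(length(reference) < N, "reference shorter than the window")
  if (is.null(disturbance)) disturbance <- numeric(N)
  abort_if(length(disturbance) < N, "disturbance shorter than the window")
  if (!is.null(seed)) set.seed(seed)

  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  dshift <- if (cfg$horizon_shift) d else 0L
  wext <- c(reference[seq_len(N)],
            rep(reference[N], dshift + cfg$P))        # last-value hold

  # padded state vectors: index k (0-based) lives at k + pad + 1
  pad <- d + n
  y_true <- numeric(N + n);  y_meas <- numeric(N + n)
  u_app <- numeric(N + pad)
  cost <- numeric(N)

  S <- forced_matrix(dmodel, cfg)
  a <- dmodel$den_z; b <- dmodel$num_z
  L <- cfg$P + dshift + 1L    # predictions t .. t+dshift+P from data through t-1

  for (k in seq_len(N)) {                             # k-th sample, t = k - 1
    iy <- n + k; iu <- pad + k
    # One sample of computation latency: the optimization occupies a sizeable
    # fraction of the sampling period, so u(t) is computed from measurements
    # up to t-1 (this timing also stabilizes the benchmark tuning, see the
    # methods vignette). The plant is advanced after the controller acts.
    u_prev <- u_app[iu - 1L]
    hist_y <- y_meas[iy - seq_len(n)]
    hist_u <- u_app[iu - seq_len(pad)]
    free <- simulate_response(dmodel, u = rep(u_prev, L), n_samples = L,
                              init = list(y = hist_y, u = hist_u))
    free <- tail(free, cfg$P)
    wseg <- wext[k + dshift + seq_len(cfg$P)]
    lo <- cfg$u_min - u_prev; hi <- cfg$u_max - u_prev
    objective <- make_move_objective(u_prev, free, S, wseg, cfg)
    res <- optimizer(objective, cbind(rep(lo, cfg$M), rep(hi, cfg$M)),
                     seeds = matrix(0, 1L, cfg$M))
    rec <- reconstruct_u(u_prev, res$par, L, cfg)
    u_app[iu] <- rec$u[1]
    cost[k] <- res$value

    # plant advance: true output from its own past and the applied inputs
    y_true[iy] <- sum(b * u_app[iu - d - (seq_along(b) - 1L)]) -
      sum(a[-1] * y_true[iy - seq_len(n)])
    y_meas[iy] <- y_true[iy] + disturbance[k]
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
  structure(hist, Ts = dmodel$Ts, cost = cost,
            u_min = cfg$u_min, u_max = cfg$u_max,
            class = c("closed_loop_history", "data.frame"))
}

#' Optimizer factories for the MPC move search
#'
#' Each factory returns a \code{function(objective, bounds, seeds)} suitable
#' for [mpc_control_step()] / [run_closed_loop()]:
#' \itemize{
#'   \item \code{ga_optimizer()} — the real-coded GA of [ga_optimize()].
#'   \item \code{grid_optimizer()} — the deterministic exhaustive
#'     [grid_oracle()]; with a coarse grid this is the "plain MPC" baseline,
#'     with a fine grid the verification oracle.
#'   \item \code{pso_optimizer()} — global-best particle swarm, see
#'     [pso_optimize()].
#' }
#'
#' @param cfg a [ga_config()] or [pso_config()].
#' @param points_per_gene grid resolution for \code{grid_optimizer}.
#' @return an optimizer closure.
#' @export
ga_optimizer <- function(cfg = ga_config()) {
  function(objective, bounds, seeds = NULL) ga_optimize(objective, bounds, cfg, seeds)
}

#' @rdname ga_optimizer
#' @export
grid_optimizer <- function(points_per_gene = 15L) {
  function(objective, bounds, seeds = NULL) {
    res <- grid_oracle(objective, bounds, points_per_gene)
    if (!is.null(seeds)) {      # honour seeded candidates (zero move)
      for (i in seq_len(nrow(seeds))) {
        v <- objective(seeds[i, ])
        if (v < res$value) res <- list(par = seeds[i, ], value = v)
      }
    }
    res
  }
}

#' @rdname ga_optimizer
#' @export
pso_optimizer <- function(cfg = pso_config()) {
  function(objective, bounds, seeds = NULL) pso_optimize(objective, bounds, cfg, seeds)
}
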