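test_that("quadratic cost reproduces hand-evaluated values", {
  cfg <- mpc_config(P = 2, M = 2, mu = 1, lambda = 0.1)
  # errors (1, 2), moves (0.5, 0.5): 1 + 4 + 0.1 (0.25 + 0.25) = 5.05
  expect_equal(mpc_cost(c(1, 2), c(0, 0), c(0.5, 0.5), cfg), 5.05)
  expect_equal(mpc_cost(c(3, 3), c(3, 3), c(0, 0), cfg), 0)
  expect_error(mpc_cost(c(1, 2, 3), c(0, 0), c(0, 0), cfg), "length P")
  expect_error(mpc_cost(c(1, 2), c(0, 0), c(0, 0, 0), cfg), "length M")
})

test_that("large move weights suppress the optimal moves", {
  dp <- canonical_dmodel()
  h <- make_history(dp, rep(0.2, 80))
  wseg <- rep(1.5, 20)
  obj_for <- function(lambda) {
    cfg <- mpc_config(P = 20, M = 2, lambda = lambda)
    function(m) mpc_cost(mpc_predict(dp, h$y, h$u, m, cfg), wseg, m, cfg)
  }
  b <- rbind(c(-1, 1), c(-1, 1))
  m_small <- grid_oracle(obj_for(0.1), b, 41)$par
  m_large <- grid_oracle(obj_for(1e6), b, 41)$par
  expect_gt(sum(abs(m_small)), 0)
  expect_equal(m_large, c(0, 0))
})

test_that("prediction equals a whole-trajectory simulation oracle", {
  dp <- canonical_dmodel()
  cfg <- mpc_config(P = 20, M = 2)
  set.seed(21)
  for (i in 1:8) {
    u_past <- pmax(0.35, pmin(1.6, cumsum(rnorm(90, 0, 0.1)) + 0.8))
    h <- make_history(dp, u_past)
    moves <- runif(2, -0.15, 0.15)      # stays strictly inside the bounds
    pred <- mpc_predict(dp, h$y, h$u, moves, cfg)
    # oracle: simulate the concatenated input from rest
    u_prev <- tail(u_past, 1)
    u_fut <- u_prev + cumsum(c(moves, numeric(79)))
    y_all <- simulate_response(dp, c(u_past, u_fut))
    expect_equal(pred, tail(y_all[seq_len(90 + 81)], 20), tolerance = 1e-10)
  }
})

test_that("zero history and zero moves predict zero output", {
  dp <- canonical_dmodel()
  cfg <- mpc_config()
  expect_equal(mpc_predict(dp, numeric(3), numeric(63), c(0, 0), cfg),
               numeric(20))
  expect_error(mpc_predict(dp, numeric(2), numeric(63), c(0, 0), cfg),
               "past_y")
  expect_error(mpc_predict(dp, numeric(3), numeric(63), c(0, 0, 0), cfg),
               "length M")
})

test_that("without the horizon shift, short horizons are unreachable", {
  dp <- canonical_dmodel()
  cfg <- mpc_config(P = 20, M = 2, horizon_shift = FALSE)
  h <- make_history(dp, runif(80, 0, 1))
  p0 <- mpc_predict(dp, h$y, h$u, c(0, 0), cfg)
  p1 <- mpc_predict(dp, h$y, h$u, c(0.8, -0.4), cfg)
  expect_equal(p0, p1)        # P <= d: the moves cannot matter
  cfg_on <- mpc_config(P = 20, M = 2, horizon_shift = TRUE)
  expect_false(isTRUE(all.equal(
    mpc_predict(dp, h$y, h$u, c(0, 0), cfg_on),
    mpc_predict(dp, h$y, h$u, c(0.8, -0.4), cfg_on))))
})

test_that("a satisfied reference makes inaction optimal", {
  dp <- canonical_dmodel()
  cfg <- mpc_config()
  st <- mpc_control_step(dp, list(y = numeric(3), u = numeric(63)),
                         reference = numeric(20), cfg,
                         optimizer = grid_optimizer(41))
  expect_equal(st$u, 0)
  expect_equal(st$value, 0)
})

test_that("the optimized cost never exceeds the zero-move cost", {
  dp <- canonical_dmodel()
  cfg <- mpc_config()
  set.seed(31)
  for (i in 1:10) {
    h <- make_history(dp, pmin(2, pmax(0, cumsum(rnorm(80, 0, 0.15)) + 0.4)))
    wseg <- rep(runif(1, 0, 1.5), 20)
    zero_cost <- mpc_cost(mpc_predict(dp, h$y, h$u, c(0, 0), cfg),
                          wseg, c(0, 0), cfg)
    st <- mpc_control_step(dp, list(y = h$y, u = h$u), wseg, cfg,
                           optimizer = ga_optimizer(ga_config()))
    expect_lte(st$value, zero_cost + 1e-12)
    expect_gte(st$u, cfg$u_min)
    expect_lte(st$u, cfg$u_max)
  }
})

test_that("control step result matches an exhaustive grid search", {
  dp <- canonical_dmodel()
  cfg <- mpc_config()
  h <- make_history(dp, rep(0.1, 80))
  wseg <- rep(1, 20)
  st_grid <- mpc_control_step(dp, list(y = h$y, u = h$u), wseg, cfg,
                              optimizer = grid_optimizer(201))
  st_ga <- mpc_control_step(dp, list(y = h$y, u = h$u), wseg, cfg,
                            optimizer = ga_optimizer(ga_config(seed = 5)))
  # GA and the exhaustive search agree to within the grid resolution
  expect_lt(abs(st_ga$u - st_grid$u), 0.05)
  expect_lt(abs(st_ga$value - st_grid$value), 1e-4 * max(1, st_grid$value))
  expect_error(
    mpc_control_step(dp, list(y = h$y, u = h$u), wseg, cfg,
                     optimizer = function(o, b, seeds) list(par = 1, value = 0)),
    "wrong length")
})

test_that("closed loop at equilibrium stays at equilibrium", {
  dp <- discretize_zoh(toy_patient(), 1)
  h <- run_closed_loop(dp, reference = numeric(60), cfg = mpc_config(P = 10),
                       optimizer = grid_optimizer(21), seed = 1)
  expect_equal(h$u, numeric(60))
  expect_equal(h$y, numeric(60))
})

test_that("closed loop tracks a step on a delay-free plant with integral action", {
  dp <- discretize_zoh(first_order_lag(5), 1)     # no dead time
  cfg <- mpc_config(P = 10, M = 2, lambda = 0.1, u_min = 0, u_max = 4)
  w <- make_reference(80, amplitude = 1)
  h <- run_closed_loop(dp, w, cfg = cfg, optimizer = grid_optimizer(81),
                       seed = 1)
  expect_lt(max(abs(1 - h$y[40:80])), 1e-2)       # settles, no offset
  expect_true(all(h$u >= cfg$u_min & h$u <= cfg$u_max))
})

test_that("closed-loop runs are bit-identical under a fixed seed", {
  sc_args <- list(reference = make_reference(100, delay = 60))
  dp <- canonical_dmodel()
  h1 <- run_closed_loop(dp, sc_args$reference, cfg = mpc_config(),
                        optimizer = ga_optimizer(), seed = 99)
  h2 <- run_closed_loop(dp, sc_args$reference, cfg = mpc_config(),
                        optimizer = ga_optimizer(), seed = 99)
  expect_identical(h1, h2)
})

test_that("the display mapping renders normalized output as absolute MAP", {
  dp <- discretize_zoh(toy_patient(), 1)
  h <- run_closed_loop(dp, numeric(20), cfg = mpc_config(P = 5),
                       optimizer = grid_optimizer(11), seed = 1,
                       map_initial = 40, map_target = 80)
  expect_equal(h$map_mmHg, rep(40, 20))
})
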