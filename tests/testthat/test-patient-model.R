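test_that("continuous model construction validates its physiology", {
  expect_error(build_continuous_model(5, -1, 20, 30, 0, 60), "positive")
  expect_error(build_continuous_model(5, 50, 20, 30, 1.0, 60), "alpha")
  expect_error(build_continuous_model(5, 50, 20, 30, 0.2, -5), "theta")
  expect_error(build_continuous_model(0, 50, 20, 30, 0.2, 60), "nonzero")
})

test_that("denominator expansion matches an independent convolution oracle", {
  set.seed(42)
  for (i in 1:25) {
    K <- runif(1, 0.5, 10)
    Tc <- runif(3, 1, 100)
    alpha <- runif(1, 0, 0.9)
    theta <- sample(0:90, 1)
    m <- build_continuous_model(K, Tc[1], Tc[2], Tc[3], alpha, theta)
    inner <- poly_conv(c(1, Tc[3]), c(1, Tc[2]))
    inner[1] <- inner[1] - alpha
    den_ref <- poly_conv(inner, c(1, Tc[1]))
    expect_equal(m$den, den_ref / den_ref[1], tolerance = 1e-12)
    expect_equal(m$num, K * c(1, Tc[3]) / den_ref[1], tolerance = 1e-12)
    expect_equal(m$den[1], 1)           # unit constant term
    expect_equal(dc_gain(m), K / (1 - alpha), tolerance = 1e-12)
  }
})

test_that("alpha = 0 with T2 = T3 cancels a pole against the zero", {
  m <- build_continuous_model(K = 3, T1 = 40, T2 = 25, T3 = 25,
                              alpha = 0, theta = 0)
  p <- sort(Re(poles(m)))
  expect_equal(p, sort(-1 / c(40, 25, 25)), tolerance = 1e-9)
  # the numerator root coincides with one denominator root
  z <- Re(polyroot(m$num))
  expect_equal(min(abs(outer(z, p, "-"))), 0, tolerance = 1e-9)
})

test_that("unit-parameter model has unit DC gain", {
  m <- build_continuous_model(1, 1, 1, 1, 0, 0)
  expect_equal(dc_gain(m), 1)
})

test_that("canonical patient carries its fixed polynomial form", {
  g <- canonical_patient_model()
  expect_equal(dc_gain(g), 5)
  expect_equal(g$theta, 60)
  expect_length(g$num, 2)               # numerator degree 1
  expect_length(g$den, 4)               # denominator degree 3
  expect_true(all(Re(poles(g)) < 0))    # asymptotically stable
})

test_that("ZOH of the canonical patient reproduces the benchmark coefficients", {
  dp <- discretize_zoh(canonical_patient_model(), Ts = 1)
  expect_identical(dp$d, 60L)
  # printed to 4 significant figures: b2, b1, b0 then a2, a1, a0
  expect_equal(signif(dp$num_z[2], 4), 0.002403)
  expect_equal(signif(dp$num_z[3], 4), -1.543e-05)
  expect_equal(signif(dp$num_z[4], 4), -0.002233)
  expect_equal(signif(dp$den_z[2], 4), -2.854)
  expect_equal(signif(dp$den_z[3], 4), 2.712)
  expect_equal(signif(dp$den_z[4], 4), -0.8578)
  expect_equal(dp$num_z[1], 0)          # strictly proper: no feedthrough
  expect_true(all(Mod(poles(dp)) < 1))  # stable in the z-plane
  expect_equal(dc_gain(dp), dc_gain(canonical_patient_model()),
               tolerance = 1e-6)
})

test_that("ZOH of a first-order lag matches its closed form", {
  for (Tc in c(0.5, 3, 40)) {
    for (Ts in c(0.25, 1, 2)) {
      dp <- discretize_zoh(first_order_lag(Tc), Ts)
      p <- exp(-Ts / Tc)
      expect_equal(dp$den_z, c(1, -p), tolerance = 1e-10)
      expect_equal(dp$num_z, c(0, 1 - p), tolerance = 1e-10)
      expect_identical(dp$d, 0L)
    }
  }
})

test_that("ZOH of a static gain is the gain itself", {
  m <- mapmpc:::new_continuous_model(num = 3.5, den = 1, theta = 0)
  dp <- discretize_zoh(m, 1)
  expect_equal(dp$num_z, 3.5)
  expect_equal(dp$den_z, 1)
  expect_identical(dp$d, 0L)
  expect_equal(simulate_response(dp, c(1, 2, -1)), c(3.5, 7, -3.5))
})

test_that("fractional dead time is rounded with a warning", {
  m <- first_order_lag(10, theta = 2.5)
  expect_warning(dp <- discretize_zoh(m, 1), "rounding")
  expect_identical(dp$d, 2L)
})

test_that("discrete DC gain equals continuous DC gain across the family", {
  set.seed(7)
  for (i in 1:10) {
    m <- build_continuous_model(runif(1, 1, 8), runif(1, 5, 80),
                                runif(1, 5, 80), runif(1, 5, 80),
                                runif(1, 0, 0.8), 0)
    dp <- discretize_zoh(m, 1)
    expect_equal(dc_gain(dp), dc_gain(m), tolerance = 1e-6)
  }
})

test_that("simulation follows the delayed difference equation", {
  dp <- canonical_dmodel()
  # zero input, zero history: identically zero
  expect_equal(simulate_response(dp, numeric(100)), numeric(100))
  # unit step: dead-time samples exactly zero, final value the DC gain
  y <- step_response(dp, 2500)
  expect_equal(y[1:61], numeric(61))    # y(k) = 0 for k <= 60
  expect_equal(tail(y, 1), 5, tolerance = 1e-3)
  expect_error(step_response(dp, 50), "delay")
})

test_that("simulation agrees with an independent linear-filter routine", {
  dp <- canonical_dmodel()
  set.seed(11)
  u <- rnorm(400)
  y <- simulate_response(dp, u)
  y_ref <- as.numeric(signal::filter(dp$num_z, dp$den_z,
                                     c(numeric(dp$d), u)))[seq_len(400)]
  expect_equal(y, y_ref, tolerance = 1e-10)
})

test_that("simulation is linear and commutes with time shifts", {
  dp <- canonical_dmodel()
  set.seed(13)
  for (i in 1:5) {
    u1 <- rnorm(220); u2 <- rnorm(220)
    al <- runif(1, -2, 2); be <- runif(1, -2, 2)
    lhs <- simulate_response(dp, al * u1 + be * u2)
    rhs <- al * simulate_response(dp, u1) + be * simulate_response(dp, u2)
    expect_equal(lhs, rhs, tolerance = 1e-9)
    # delaying the input by m samples delays the output exactly
    m <- sample(1:20, 1)
    y <- simulate_response(dp, u1)
    y_shift <- simulate_response(dp, c(numeric(m), u1))
    expect_identical(y_shift[seq_len(m)], numeric(m))
    expect_equal(y_shift[m + seq_len(200)], y[seq_len(200)], tolerance = 1e-12)
  }
})

test_that("disturbance adds at the measured output and history seeds the state", {
  dp <- discretize_zoh(toy_patient(), 1)
  u <- rep(1, 40)
  dist <- sin(seq_len(40) / 3)
  expect_equal(simulate_response(dp, u, disturbance = dist),
               simulate_response(dp, u) + dist)
  # continuing a run via init history reproduces the uninterrupted run
  y_all <- simulate_response(dp, rep(1, 60))
  n <- length(dp$den_z) - 1L
  h <- list(y = rev(tail(y_all[1:30], n)),
            u = rev(rep(1, dp$d + n)))
  y_cont <- simulate_response(dp, rep(1, 30), init = h)
  expect_equal(y_cont, y_all[31:60], tolerance = 1e-12)
  expect_error(simulate_response(dp, rep(1, 10), n_samples = 20), "shorter")
})
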