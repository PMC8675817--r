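# Shared fixtures, all built in code.

# Pure first-order lag 1/(1 + T s), optionally delayed. Built directly in
# polynomial form (the three-time-constant constructor always yields third
# order).
first_order_lag <- function(T_const, theta = 0, K = 1) {
  mapmpc:::new_continuous_model(num = K, den = c(1, T_const), theta = theta)
}

# Small delayed patient for fast scenario-level tests.
toy_patient <- function() {
  build_continuous_model(K = 2, T1 = 8, T2 = 4, T3 = 3, alpha = 0.1, theta = 5)
}

canonical_dmodel <- function(Ts = 1) discretize_zoh(canonical_patient_model(), Ts)

# Independent ascending-polynomial product (convolution), kept deliberately
# separate from the package's own expansion path.
poly_conv <- function(p, q) {
  n <- length(p) + length(q) - 1L
  r <- numeric(n)
  for (i in seq_along(p)) for (j in seq_along(q)) {
    r[i + j - 1L] <- r[i + j - 1L] + p[i] * q[j]
  }
  r
}

# Consistent plant history for prediction tests: drive the plant from rest
# with a given input and return the most-recent-first histories.
make_history <- function(dmodel, u_past) {
  y_past <- simulate_response(dmodel, u_past)
  n <- length(dmodel$den_z) - 1L
  d <- dmodel$d
  list(y = rev(tail(y_past, n)),
       u = rev(tail(u_past, d + n)),
       y_full = y_past, u_full = u_past)
}
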