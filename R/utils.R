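#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm median uniroot setNames
#' @importFrom utils tail write.csv
NULL

# Validation helper: abort with the caller's message when `cond` is FALSE.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Strip trailing (near-)zero high-order coefficients of an ascending
# polynomial, keeping at least the constant term.
trim_poly <- function(p, tol = 0) {
  n <- length(p)
  while (n > 1L && abs(p[n]) <= tol) n <- n - 1L
  p[seq_len(n)]
}

# Polynomial multiplication of ascending coefficient vectors.
poly_mul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    r[i + seq_along(q) - 1L] <- r[i + seq_along(q) - 1L] + p[i] * q
  }
  r
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
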