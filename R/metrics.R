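#' Control performance indices
#'
#' Discrete-sum IAE, ISE and MSE of the tracking error
#' \code{e(k) = r(k) - y(k)} over a window of a closed-loop run:
#' \deqn{IAE = \sum |e(k)|\, T_s, \quad ISE = \sum e(k)^2\, T_s, \quad
#'       MSE = \frac{1}{N} \sum e(k)^2.}
#' With \code{Ts} in seconds these have units error-units·s,
#' error-units²·s and error-units² respectively, and
#' \code{MSE * N * Ts = ISE} holds identically.
#'
#' @param history a \code{closed_loop_history} (or any data frame with
#'   columns \code{r} and \code{y} and a \code{Ts} attribute).
#' @param window integer indices (1-based) of the samples to include;
#'   defaults to the full run.
#' @param Ts sampling time; defaults to the history's \code{Ts} attribute
#'   (or 1).
#' @return an object of class \code{metrics_report}: list with \code{IAE},
#'   \code{ISE}, \code{MSE}, \code{N}, \code{Ts}.
#' @examples
#' h <- data.frame(r = c(1, 1, 1), y = c(0, 2, -1))
#' compute_metrics(h)  # IAE 4, ISE 6, MSE 2
#' @export
compute_metrics <- function(history, window = NULL, Ts = NULL) {
  abort_if(!all(c("r", "y") %in% names(history)),
           "'history' must have columns 'r' and 'y'")
  if (is.null(Ts)) Ts <- attr(history, "Ts")
  if (is.null(Ts)) Ts <- 1
  n_all <- nrow(history)
  if (is.null(window)) window <- seq_len(n_all)
  abort_if(length(window) == 0L, "empty metrics window")
  abort_if(min(window) < 1L || max(window) > n_all,
           "window indices outside the history")
  e <- history$r[window] - history$y[window]
  N <- length(e)
  structure(list(IAE = sum(abs(e)) * Ts,
                 ISE = sum(e^2) * Ts,
                 MSE = sum(e^2) / N,
                 N = N, Ts = Ts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("IAE = %.4g   ISE = %.4g   MSE = %.4g   (N = %d, Ts = %g s)\n",
              x$IAE, x$ISE, x$MSE, x$N, x$Ts))
  invisible(x)
}
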