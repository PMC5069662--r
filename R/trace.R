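## Signal containers and discrete convolution primitives shared by the
## forward model and the deconvolution.

#' Uniformly sampled current trace
#'
#' @param t time grid, s, uniform, starting at 0.
#' @param current induced current i(t), A.
#' @param metadata named list of condition metadata (concentrations,
#'   flow rate, seed, units ...).
#' @return Object of class `signal_trace`.
#' @export
signal_trace <- function(t, current, metadata = list()) {
  stopifnot(length(t) == length(current), length(t) >= 2)
  if (any(!is.finite(current))) stop("non-finite current values")
  dtv <- diff(t)
  if (any(abs(dtv - dtv[1]) > 1e-6 * abs(dtv[1])))
    stop("signal_trace: time grid is not uniform")
  structure(list(t = t, current = current,
                 sampling_rate = 1 / dtv[1], metadata = metadata),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace: %d samples @ %.6g Hz, %.4g s, peak |i| = %.3g A>\n",
              length(x$t), x$sampling_rate, max(x$t), max(abs(x$current))))
  if (length(x$metadata)) {
    kv <- vapply(names(x$metadata), function(k)
      paste0(k, "=", format(x$metadata[[k]])), character(1))
    cat("  ", paste(kv, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Causal discrete convolution on a shared uniform grid, trapezoid rule:
# y_k = dt * sum_{j=0..k} w_j f_{k-j} g_j, with half weights at j = 0
# and j = k. FFT-based via stats::convolve.
conv_causal <- function(f, g, dt) {
  n <- length(f)
  stopifnot(length(g) == n)
  full <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  # trapezoid endpoint correction: halve the j = 0 and j = k terms
  y <- dt * (full - 0.5 * f * g[1] - 0.5 * g * f[1])
  y
}

# Cumulative integral (trapezoid) on a uniform grid.
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

# Centred-difference derivative on a uniform grid (one-sided at ends).
grad_uniform <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}
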