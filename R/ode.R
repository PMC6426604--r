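# Adaptive Dormand-Prince RK5(4) integrator with step-size control.
# Self-contained because no dedicated ODE solver is available at run time;
# the cascade is only mildly stiff at realistic rate constants, so an
# explicit embedded pair with a tight tolerance is adequate.

DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
           187 / 2100, 1 / 40)

#' Integrate an ODE system with an adaptive Runge-Kutta method
#'
#' Dormand-Prince 5(4) embedded pair with proportional step-size control and
#' first-same-as-last reuse. Solutions are produced exactly at the requested
#' output times by capping the step at each boundary.
#'
#' @param rhs Function `rhs(t, y)` returning `dy/dt` as a numeric vector.
#' @param y0 Initial state (named vector names are preserved).
#' @param times Strictly increasing output times; `times[1]` is the initial
#'   time.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param max_steps Safety cap on accepted + rejected steps.
#' @return A matrix with `length(times)` rows: column `time` then one column
#'   per state variable.
#' @export
ode_rk45 <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                     max_steps = 5e5) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n + 1,
                dimnames = list(NULL, c("time", names(y0) %||%
                                          paste0("y", seq_len(n)))))
  out[1, ] <- c(times[1], y0)
  t <- times[1]
  y <- as.numeric(y0)
  f1 <- rhs(t, y)
  h <- initial_step(rhs, t, y, f1, rtol, atol)
  next_i <- 2L
  steps <- 0L
  k <- matrix(0, nrow = 7, ncol = n)

  while (next_i <= length(times)) {
    if (steps >= max_steps) {
      stop(sprintf(
        "ode_rk45: step limit reached at t = %.6g (h = %.3g); %s", t, h,
        "system may be too stiff for the requested tolerance"))
    }
    steps <- steps + 1L
    h <- min(h, times[length(times)] - t)
    hit_output <- t + h >= times[next_i] - 1e-14 * max(1, abs(times[next_i]))
    if (hit_output) h <- times[next_i] - t

    k[1, ] <- f1
    for (s in 1:6) {
      yi <- y + h * drop(DP_A[[s]] %*% k[seq_len(s), , drop = FALSE])
      k[s + 1, ] <- rhs(t + h * c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)[s], yi)
    }
    y5 <- y + h * drop(DP_B5 %*% k)
    y4 <- y + h * drop(DP_B4 %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))

    if (err <= 1) {
      t <- t + h
      y <- y5
      f1 <- k[7, ]   # FSAL: last stage equals rhs at the new point
      while (next_i <= length(times) &&
             abs(t - times[next_i]) <= 1e-12 * max(1, abs(times[next_i]))) {
        out[next_i, ] <- c(times[next_i], y)
        next_i <- next_i + 1L
      }
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
    h <- h * fac
    if (h <= 0 || !is.finite(h)) {
      stop("ode_rk45: step size underflow; integration failed")
    }
  }
  out
}

# Conservative first step from the scale of y and its derivative.
initial_step <- function(rhs, t, y, f, rtol, atol) {
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2))
  d1 <- sqrt(mean((f / sc)^2))
  h0 <- if (d0 < 1e-5 || d1 < 1e-5) 1e-6 else 0.01 * d0 / d1
  y1 <- y + h0 * f
  f1 <- rhs(t + h0, y1)
  d2 <- sqrt(mean(((f1 - f) / sc)^2)) / h0
  h1 <- if (max(d1, d2) <= 1e-15) {
    max(1e-6, h0 * 1e-3)
  } else {
    (0.01 / max(d1, d2))^(1 / 5)
  }
  min(100 * h0, h1)
}
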