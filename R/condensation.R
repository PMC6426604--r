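#' Pseudo-first-order condensation scheme
#'
#' The spontaneous condensation of betalamic acid with l-DOPA to form
#' dopaxanthin is second order, `v = k [bet][DOPA]`. With l-DOPA held in
#' large excess the reaction is pseudo-first-order in betalamic acid with
#' apparent constant `k_app = k [DOPA]`, and the product accumulates as
#' `[dopax](t) = [bet]0 (1 - exp(-k_app t))` under the mass balance
#' `[bet]0 = [bet] + [dopax]`.
#'
#' @param k Second-order rate constant, 1/h/M (> 0).
#' @param dopa_M Fixed l-DOPA concentration, M (> 0).
#' @return A `condensation_scheme` list with `k`, `dopa_M` and the derived
#'   `k_app = k * dopa_M` (1/h).
#' @examples
#' condensation_scheme(k = 189, dopa_M = 3.5e-3)
#' @export
condensation_scheme <- function(k, dopa_M) {
  stopifnot(k > 0, dopa_M > 0)
  structure(list(k = k, dopa_M = dopa_M, k_app = k * dopa_M),
            class = "condensation_scheme")
}

#' @export
print.condensation_scheme <- function(x, ...) {
  cat(sprintf(
    "<condensation_scheme> k = %.4g /h/M at [DOPA] = %.4g M (k_app = %.4g /h)\n",
    x$k, x$dopa_M, x$k_app))
  if (!is.null(x$slope)) {
    cat(sprintf("  slope = %.4g over n = %d points\n", x$slope, x$n))
  }
  invisible(x)
}

#' Dopaxanthin accumulation under pseudo-first-order kinetics
#'
#' @param bet0_uM Initial betalamic acid concentration(s), uM (>= 0).
#' @param scheme A [condensation_scheme()].
#' @param t_h Time(s) in hours (>= 0).
#' @return Dopaxanthin concentration(s), uM:
#'   `bet0_uM * (1 - exp(-k_app * t_h))`. Residual betalamic acid is
#'   `bet0_uM` minus this value (mass balance).
#' @examples
#' sch <- condensation_scheme(189, 3.5e-3)
#' dopax_accumulation(100, sch, t_h = 12)
#' @export
dopax_accumulation <- function(bet0_uM, scheme, t_h) {
  stopifnot(inherits(scheme, "condensation_scheme"))
  if (any(bet0_uM < 0)) stop("negative initial concentration")
  if (any(t_h < 0)) stop("negative time")
  bet0_uM * (1 - exp(-scheme$k_app * t_h))
}

#' Estimate the condensation constant from fixed-time endpoints
#'
#' Given dopaxanthin formed after a fixed time `t_h` from a series of initial
#' betalamic acid concentrations, the accumulation law makes
#' `[dopax] = s [bet]0` with slope `s = 1 - exp(-k_app t)`. The slope is
#' estimated by least-squares regression through the origin (zero substrate
#' gives zero product) and inverted as `k_app = -log(1 - s) / t`; the
#' second-order constant is `k = k_app / [DOPA]`.
#'
#' @param bet0_uM Initial betalamic acid concentrations, uM; >= 3 distinct
#'   values.
#' @param dopax_uM Dopaxanthin measured at `t_h`, uM; same length.
#' @param t_h Fixed reaction time, h (> 0).
#' @param dopa_M l-DOPA concentration held constant, M.
#' @return A [condensation_scheme()] carrying the estimated `k`, plus the
#'   fitted `slope` and `n`.
#' @examples
#' sch <- condensation_scheme(189, 3.5e-3)
#' b0 <- c(25, 50, 75, 100)
#' estimate_k(b0, dopax_accumulation(b0, sch, 12), t_h = 12, dopa_M = 3.5e-3)
#' @export
estimate_k <- function(bet0_uM, dopax_uM, t_h, dopa_M) {
  stopifnot(length(bet0_uM) == length(dopax_uM), t_h > 0, dopa_M > 0)
  if (length(unique(bet0_uM)) < 3) stop("need >= 3 distinct bet0 values")
  s <- unname(stats::coef(stats::lm(dopax_uM ~ 0 + bet0_uM))[1])
  if (s >= 1) {
    stop("slope >= 1: dopaxanthin exceeds initial betalamic acid, ",
         "impossible under mass balance")
  }
  if (s <= 0) stop("slope <= 0: no reaction detected")
  k_app <- -log(1 - s) / t_h
  out <- condensation_scheme(k = k_app / dopa_M, dopa_M = dopa_M)
  out$slope <- s
  out$n <- length(bet0_uM)
  out
}

#' Estimate the condensation constant from a time course
#'
#' Nonlinear fit of the accumulation law
#' `[dopax](t) = bet0 (1 - exp(-k_app t))` to a dopaxanthin time course at
#' fixed initial betalamic acid; cross-checks [estimate_k()] on shared data.
#'
#' @param t_h Times, h; >= 5 points.
#' @param dopax_uM Dopaxanthin concentrations, uM.
#' @param bet0_uM Fixed initial betalamic acid concentration, uM.
#' @param dopa_M l-DOPA concentration held constant, M.
#' @return A [condensation_scheme()] with the fitted `k`, plus `k_app` and
#'   `n`.
#' @export
time_course_k <- function(t_h, dopax_uM, bet0_uM, dopa_M) {
  stopifnot(length(t_h) == length(dopax_uM), length(t_h) >= 5,
            bet0_uM > 0, dopa_M > 0)
  if (max(dopax_uM) <= 0) stop("no reaction: dopaxanthin never accumulates")
  # initial guess from the early-time linear regime d[dopax]/dt ~ k_app bet0
  pos <- which(t_h > 0 & dopax_uM > 0 & dopax_uM < bet0_uM)
  k0 <- if (length(pos)) {
    stats::median(-log(1 - dopax_uM[pos] / bet0_uM) / t_h[pos])
  } else {
    1 / max(t_h)
  }
  fit <- tryCatch(
    stats::nls(dopax_uM ~ bet0_uM * (1 - exp(-k_app * t_h)),
               data = data.frame(t_h, dopax_uM),
               start = list(k_app = k0), algorithm = "port",
               lower = c(k_app = k0 * 1e-6),
               control = stats::nls.control(maxiter = 200, tol = 1e-10)),
    error = function(e) NULL
  )
  k_app <- if (!is.null(fit)) {
    unname(stats::coef(fit)[["k_app"]])
  } else {
    obj <- function(lk) sum((dopax_uM - bet0_uM * (1 - exp(-exp(lk) * t_h)))^2)
    exp(stats::optimize(obj, log(k0) + c(-8, 8), tol = 1e-12)$minimum)
  }
  out <- condensation_scheme(k = k_app / dopa_M, dopa_M = dopa_M)
  out$n <- length(t_h)
  out
}
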