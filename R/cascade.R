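CASCADE_SPECIES <- c("DOPA", "seco45", "seco23", "betalamic", "muscaflavin",
                     "dopaxanthin")

#' Parameters of the enzymatic-chemical betalain cascade
#'
#' The full mechanism: the dioxygenase cleaves the l-DOPA ring extradiolically
#' at the 4,5 (fraction `phi45`) or 2,3 position; the open-ring seco-DOPA
#' intermediates cyclize spontaneously (first order) to betalamic acid and
#' muscaflavin respectively; betalamic acid condenses (second order) with
#' intact l-DOPA to give dopaxanthin, consuming one extra l-DOPA per pigment
#' molecule.
#'
#' Units follow assay conventions at the interface (Vmax in uM/min, Km/Ki and
#' DOPA0 in mM, cyclization in 1/h, condensation in 1/h/M) and are converted
#' once here; the simulator works internally in uM and hours.
#'
#' @param Vmax Limiting enzymatic rate, uM/min.
#' @param Km Michaelis constant for l-DOPA, mM.
#' @param Ki Substrate-inhibition constant, mM (`Inf` disables inhibition;
#'   l-DOPA itself shows none).
#' @param phi45 Fraction of enzymatic turnover through the 4,5-cleavage
#'   branch, in `[0, 1]`.
#' @param k_cyc45,k_cyc23 First-order cyclization constants of the two
#'   seco-DOPA pools, 1/h. Not measured quantities; the defaults are
#'   illustrative values that place the demo seco maxima near 5 h with the
#'   betalamic-acid maximum following a few hours later (with the published
#'   condensation constant the observed ~20 h betalamic maximum is not
#'   reachable while keeping the seco maxima at 5 h; see the vignette).
#' @param k_cond Second-order condensation constant, 1/h/M.
#' @param DOPA0 Initial l-DOPA, mM.
#' @param enzyme_scale Multiplicative factor on `Vmax` (1 = fully active;
#'   0 = enzyme absent), a coarse stand-in for inactivation or oxygen
#'   limitation.
#' @param enzyme_t_off End of the enzyme-active time window, h (`Inf` keeps
#'   the enzyme active throughout). While the enzyme works, betalamic acid
#'   tracks its quasi-steady value from below and cannot overshoot; the
#'   decline after a maximum requires the enzymatic step to stop while
#'   intact l-DOPA remains for the condensation to consume.
#' @return A `cascade_params` list; internal fields `Vmax_uM_h`, `Km_uM`,
#'   `Ki_uM`, `k_cond_uM` and `DOPA0_uM` hold the converted values.
#' @export
cascade_params <- function(Vmax = 5.26, Km = 1.36, Ki = Inf, phi45 = 0.5,
                           k_cyc45 = 0.15, k_cyc23 = 0.10, k_cond = 189,
                           DOPA0 = 2.5, enzyme_scale = 1,
                           enzyme_t_off = 5) {
  stopifnot(Vmax >= 0, Km > 0, Ki > 0, phi45 >= 0, phi45 <= 1,
            k_cyc45 >= 0, k_cyc23 >= 0, k_cond >= 0, DOPA0 >= 0,
            enzyme_scale >= 0, enzyme_t_off >= 0)
  structure(list(
    Vmax = Vmax, Km = Km, Ki = Ki, phi45 = phi45,
    k_cyc45 = k_cyc45, k_cyc23 = k_cyc23, k_cond = k_cond,
    DOPA0 = DOPA0, enzyme_scale = enzyme_scale, enzyme_t_off = enzyme_t_off,
    Vmax_uM_h = Vmax * 60 * enzyme_scale,
    Km_uM = Km * 1000,
    Ki_uM = Ki * 1000,
    k_cond_uM = k_cond * 1e-6,   # 1/h/M -> 1/h/uM
    DOPA0_uM = DOPA0 * 1000
  ), class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("<cascade_params>\n")
  cat(sprintf("  enzyme: Vmax %.4g uM/min, Km %.4g mM, Ki %s mM, phi45 %.2f\n",
              x$Vmax, x$Km, format(x$Ki), x$phi45))
  cat(sprintf("  chemistry: k_cyc45 %.4g /h, k_cyc23 %.4g /h, k_cond %.4g /h/M\n",
              x$k_cyc45, x$k_cyc23, x$k_cond))
  cat(sprintf("  initial l-DOPA %.4g mM, enzyme_scale %.2f\n",
              x$DOPA0, x$enzyme_scale))
  invisible(x)
}

#' Right-hand side of the cascade ODE system
#'
#' State order: l-DOPA, 4,5-seco-DOPA, 2,3-seco-DOPA, betalamic acid,
#' muscaflavin, dopaxanthin (all uM). The enzymatic rate is the
#' substrate-inhibition law on l-DOPA (plain Michaelis-Menten when
#' `Ki = Inf`); condensation removes one betalamic acid and one l-DOPA per
#' dopaxanthin, so the DOPA-equivalent sum (counting dopaxanthin twice) is
#' conserved identically.
#'
#' @param state Numeric vector of 6 non-negative concentrations, uM.
#' @param params A [cascade_params()].
#' @param t Time in hours (only consulted for the enzyme-active window).
#' @return Named vector of time derivatives, uM/h.
#' @export
cascade_rhs <- function(state, params, t = 0) {
  S <- state[[1]]
  v_enz <- if (S <= 0 || t > params$enzyme_t_off) 0 else {
    params$Vmax_uM_h * S / (params$Km_uM + S * (1 + S / params$Ki_uM))
  }
  v_cond <- params$k_cond_uM * state[[4]] * S
  c(
    DOPA = -v_enz - v_cond,
    seco45 = params$phi45 * v_enz - params$k_cyc45 * state[[2]],
    seco23 = (1 - params$phi45) * v_enz - params$k_cyc23 * state[[3]],
    betalamic = params$k_cyc45 * state[[2]] - v_cond,
    muscaflavin = params$k_cyc23 * state[[3]],
    dopaxanthin = v_cond
  )
}

#' Simulate the betalain cascade
#'
#' Numerically integrates [cascade_rhs()] from an all-l-DOPA initial state
#' (or a user-supplied one) over the requested time grid.
#'
#' @param params A [cascade_params()].
#' @param times Output times in hours, strictly increasing, starting at the
#'   initial time.
#' @param state0 Optional initial state (uM, length 6); defaults to
#'   `DOPA0` with every product at zero.
#' @param rtol,atol Integration tolerances passed to [ode_rk45()].
#' @return A `cascade_timecourse`: a data frame with column `time_h` and one
#'   column per species (uM).
#' @examples
#' tc <- simulate_cascade(cascade_params(), times = seq(0, 30, 0.5))
#' head(tc)
#' @export
simulate_cascade <- function(params, times = seq(0, 30, length.out = 121),
                             state0 = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "cascade_params"))
  if (is.null(state0)) {
    state0 <- c(params$DOPA0_uM, 0, 0, 0, 0, 0)
  }
  stopifnot(length(state0) == 6, all(state0 >= 0))
  names(state0) <- CASCADE_SPECIES
  sol <- if (is.finite(params$enzyme_t_off) &&
             params$enzyme_t_off > times[1] &&
             params$enzyme_t_off < times[length(times)]) {
    # integrate in two phases so the switch-off discontinuity never sits
    # inside an adaptive step
    split_ode(params, state0, times, rtol, atol)
  } else {
    ode_rk45(function(t, y) cascade_rhs(y, params, t), state0, times,
             rtol = rtol, atol = atol)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_h"
  class(out) <- c("cascade_timecourse", "data.frame")
  out
}

split_ode <- function(params, state0, times, rtol, atol) {
  t_off <- params$enzyme_t_off
  rhs <- function(t, y) cascade_rhs(y, params, t)
  pre <- unique(c(times[times <= t_off], t_off))
  post <- unique(c(t_off, times[times > t_off]))
  sol1 <- if (length(pre) >= 2) {
    ode_rk45(rhs, state0, pre, rtol = rtol, atol = atol)
  } else {
    matrix(c(t_off, state0), nrow = 1,
           dimnames = list(NULL, c("time", names(state0))))
  }
  y_off <- sol1[nrow(sol1), -1]
  sol2 <- ode_rk45(function(t, y) cascade_rhs(y, params, t = t_off + 1),
                   y_off, post, rtol = rtol, atol = atol)
  rbind(sol1[sol1[, "time"] %in% times, , drop = FALSE],
        sol2[sol2[, "time"] %in% times & sol2[, "time"] > t_off, ,
             drop = FALSE])
}

#' Total l-DOPA equivalents along a time course
#'
#' Every species carries one l-DOPA skeleton except dopaxanthin, which
#' carries two (the condensed betalamic acid plus the intact l-DOPA).
#' This sum is invariant along any exact trajectory.
#'
#' @param course A `cascade_timecourse`.
#' @return Numeric vector of l-DOPA equivalents (uM), one per time point.
#' @export
dopa_equivalents <- function(course) {
  course$DOPA + course$seco45 + course$seco23 + course$betalamic +
    course$muscaflavin + 2 * course$dopaxanthin
}

#' Lag, peak and monotonicity summary of a single curve
#'
#' The lag time is the intercept with the time axis of the tangent drawn at
#' the point of maximal rate (central finite differences), clipped at zero:
#' the standard graphical construction for sigmoidal accumulation curves.
#' The peak is the discrete maximum when it is interior to the series.
#'
#' @param times Time points, strictly increasing, length >= 5.
#' @param values Non-negative curve values at `times`.
#' @param tol Relative tolerance (on the curve maximum) below which
#'   fluctuations are ignored when classifying monotonicity.
#' @return A `curve_summary` list: `lag` (h), `t_peak` and `peak_value`
#'   (`NA` when the maximum sits on the boundary), `monotone`.
#' @export
lag_time <- function(times, values, tol = 1e-6) {
  stopifnot(length(times) == length(values), length(times) >= 5,
            all(diff(times) > 0))
  if (any(values < -tol * max(abs(values), 1))) {
    stop("negative curve values")
  }
  vmax <- max(values)
  if (vmax <= 0) stop("all-zero curve: lag undefined")
  n <- length(values)
  # central differences in the interior, one-sided at the ends
  slope <- c(
    (values[2] - values[1]) / (times[2] - times[1]),
    (values[3:n] - values[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)]),
    (values[n] - values[n - 1]) / (times[n] - times[n - 1])
  )
  i <- which.max(slope)
  lag <- if (slope[i] <= 0) NA_real_ else {
    max(0, times[i] - values[i] / slope[i])
  }
  ipk <- which.max(values)
  interior <- ipk > 1 && ipk < n
  drops <- diff(values) < -tol * vmax
  structure(list(
    lag = lag,
    t_peak = if (interior) times[ipk] else NA_real_,
    peak_value = if (interior) values[ipk] else NA_real_,
    monotone = !any(drops)
  ), class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("<curve_summary> lag %.3g h, peak %s, monotone %s\n",
              x$lag,
              if (is.na(x$t_peak)) "none (boundary)" else
                sprintf("%.3g uM at %.3g h", x$peak_value, x$t_peak),
              x$monotone))
  invisible(x)
}

#' Fit cascade parameters to an observed time course
#'
#' Least squares by repeated simulation: the named free parameters are
#' optimized on the log scale (all are positive rates except `phi45`, which
#' is logit-transformed) against every species column present in the
#' observed course. Intended for small identifiable subsets (<= 4 free
#' parameters).
#'
#' @param course A `cascade_timecourse` (possibly with a subset of species
#'   columns) containing the observations; column `time_h` required.
#' @param free Character vector naming the parameters to estimate, from
#'   `Vmax`, `Km`, `Ki`, `phi45`, `k_cyc45`, `k_cyc23`, `k_cond`.
#' @param init A [cascade_params()] providing fixed values and starting
#'   points for the free ones.
#' @param rtol Integration tolerance used inside the objective (looser than
#'   the final simulation for speed).
#' @return A list with `params` (a [cascade_params()] at the optimum),
#'   `rss`, `convergence` and `flat` (TRUE when the objective is so flat
#'   that the configuration is likely non-identifiable).
#' @export
fit_cascade <- function(course, free, init = cascade_params(), rtol = 1e-7) {
  stopifnot(inherits(init, "cascade_params"), length(free) >= 1,
            length(free) <= 4)
  allowed <- c("Vmax", "Km", "Ki", "phi45", "k_cyc45", "k_cyc23", "k_cond")
  if (!all(free %in% allowed)) {
    stop("free parameters must be among: ", paste(allowed, collapse = ", "))
  }
  species <- intersect(CASCADE_SPECIES, names(course))
  if (length(species) < 2) stop("course must contain >= 2 observed species")
  times <- course$time_h
  obs <- as.matrix(course[species])

  to_working <- function(vals) {
    ifelse(free == "phi45", stats::qlogis(vals), log(vals))
  }
  from_working <- function(w) {
    ifelse(free == "phi45", stats::plogis(w), exp(w))
  }
  rebuild <- function(vals) {
    args <- init[c("Vmax", "Km", "Ki", "phi45", "k_cyc45", "k_cyc23",
                   "k_cond", "DOPA0", "enzyme_scale", "enzyme_t_off")]
    args[free] <- as.list(vals)
    do.call(cascade_params, args)
  }
  objective <- function(w) {
    p <- rebuild(from_working(w))
    sim <- tryCatch(
      simulate_cascade(p, times = times, rtol = rtol, atol = 1e-9),
      error = function(e) NULL
    )
    if (is.null(sim)) return(1e12)
    sum((as.matrix(sim[species]) - obs)^2)
  }

  w0 <- to_working(unlist(init[free]))
  if (length(free) == 1) {
    opt1 <- stats::optimize(objective, w0 + c(-log(50), log(50)), tol = 1e-12)
    opt <- list(par = opt1$minimum, value = opt1$objective, convergence = 0)
  } else {
    opt <- stats::optim(w0, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
  }
  # flatness probe: relative objective change under a 5% parameter nudge
  nudge <- vapply(seq_along(w0), function(j) {
    w <- opt$par
    w[j] <- w[j] + log(1.05)
    objective(w)
  }, numeric(1))
  scale <- max(opt$value, mean(obs^2) * length(obs) * 1e-12, 1e-300)
  flat <- all((nudge - opt$value) / scale < 1e-6) && opt$value > 0

  list(
    params = rebuild(from_working(opt$par)),
    rss = opt$value,
    convergence = if (opt$convergence == 0) "converged" else "non-convergence",
    flat = flat
  )
}
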