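#' Construct a saturation curve
#'
#' A set of initial-rate measurements at increasing substrate concentrations,
#' the raw material for Michaelis-Menten or substrate-inhibition fitting.
#'
#' @param substrate_mM Substrate concentrations in mM; strictly positive and
#'   strictly increasing, length >= 4.
#' @param rate_uM_per_min Initial rates in uM/min; non-negative, same length.
#' @param substrate Label for the substrate assayed.
#' @return A `saturation_curve` (a data frame with the two numeric columns
#'   and a `substrate` attribute).
#' @export
saturation_curve <- function(substrate_mM, rate_uM_per_min,
                             substrate = "l-DOPA") {
  stopifnot(
    is.numeric(substrate_mM), is.numeric(rate_uM_per_min),
    length(substrate_mM) == length(rate_uM_per_min),
    length(substrate_mM) >= 4
  )
  if (any(substrate_mM <= 0) || any(diff(substrate_mM) <= 0)) {
    stop("substrate concentrations must be strictly positive and increasing")
  }
  if (any(rate_uM_per_min < 0)) stop("rates must be non-negative")
  structure(
    data.frame(substrate_mM = substrate_mM,
               rate_uM_per_min = rate_uM_per_min),
    substrate = substrate,
    class = c("saturation_curve", "data.frame")
  )
}

#' Michaelis-Menten rate law
#'
#' @param S Substrate concentration(s), mM; non-negative.
#' @param Km Michaelis constant, mM.
#' @param Vmax Limiting rate, uM/min.
#' @return Rate(s) in uM/min: `Vmax * S / (Km + S)`.
#' @examples
#' mm_rate(2.5, Km = 1.36, Vmax = 5.26)
#' @export
mm_rate <- function(S, Km, Vmax) {
  if (any(S < 0)) stop("negative substrate concentration")
  stopifnot(Km > 0, Vmax > 0)
  Vmax * S / (Km + S)
}

#' Substrate-inhibition rate law
#'
#' Rate equation for inhibition by excess of substrate in its canonical
#' uncompetitive form, `Vmax * S / (Km + S * (1 + S / Ki))`. As `Ki` tends to
#' infinity this reduces to [mm_rate()]; the rate is maximal at
#' `S = sqrt(Km * Ki)`.
#'
#' @inheritParams mm_rate
#' @param Ki Substrate-inhibition constant, mM; may be `Inf`.
#' @export
si_rate <- function(S, Km, Vmax, Ki) {
  if (any(S < 0)) stop("negative substrate concentration")
  stopifnot(Km > 0, Vmax > 0, Ki > 0)
  Vmax * S / (Km + S * (1 + S / Ki))
}

#' Fit a saturation curve
#'
#' Nonlinear least-squares estimation of the Michaelis-Menten (`"mm"`) or
#' substrate-inhibition (`"si"`) rate law. Starting values follow the usual
#' saturation-curve heuristics: `Vmax` from the largest observed rate, `Km`
#' from the interpolated half-saturating concentration, `Ki` from the largest
#' concentration assayed. A Nelder-Mead polish on log-parameters backs up
#' `nls()` whenever Gauss-Newton iteration fails (e.g. on noise-free data
#' with zero residuals).
#'
#' @param curve A [saturation_curve()] (or data frame with columns
#'   `substrate_mM`, `rate_uM_per_min`).
#' @param model `"mm"` (>= 4 points) or `"si"` (>= 5 points).
#' @param weighting `"none"` for ordinary least squares (the default,
#'   matching common practice for these assays) or `"relative"` for
#'   `1/rate^2` weights.
#' @return A `kinetic_params` object: a list with elements `Km`, `Vmax`,
#'   `Ki` (`Inf` for the MM model), standard errors `se`, residual sum of
#'   squares `rss`, `model`, `n`, and `convergence` diagnostics.
#' @examples
#' s <- seq(0.25, 7.6, length.out = 8)
#' fit_saturation(saturation_curve(s, mm_rate(s, 1.36, 5.26)))
#' @export
fit_saturation <- function(curve, model = c("mm", "si"),
                           weighting = c("none", "relative")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  S <- curve$substrate_mM
  v <- curve$rate_uM_per_min
  stopifnot(length(S) >= if (model == "si") 5 else 4)
  if (diff(range(v)) < .Machine$double.eps * max(abs(v), 1)) {
    stop("degenerate data: rates are constant")
  }
  w <- if (weighting == "relative") 1 / pmax(v, max(v) * 1e-3)^2 else rep(1, length(v))

  Vmax0 <- max(v)
  Km0 <- stats::approx(v, S, xout = Vmax0 / 2, ties = "ordered")$y
  if (is.na(Km0) || Km0 <= 0) Km0 <- stats::median(S)
  start <- if (model == "mm") {
    c(Km = Km0, Vmax = Vmax0)
  } else {
    c(Km = Km0, Vmax = Vmax0, Ki = max(S))
  }

  predict_rate <- function(p) {
    if (model == "mm") mm_rate(S, p[["Km"]], p[["Vmax"]])
    else si_rate(S, p[["Km"]], p[["Vmax"]], p[["Ki"]])
  }
  objective <- function(lp) {
    sum(w * (v - predict_rate(exp(lp)))^2)
  }

  fit <- tryCatch({
    formula <- if (model == "mm") {
      rate_uM_per_min ~ Vmax * substrate_mM / (Km + substrate_mM)
    } else {
      rate_uM_per_min ~ Vmax * substrate_mM /
        (Km + substrate_mM * (1 + substrate_mM / Ki))
    }
    stats::nls(formula, data = data.frame(S, v, substrate_mM = S,
                                          rate_uM_per_min = v),
               start = as.list(start), weights = w,
               algorithm = "port", lower = start * 1e-4,
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            warnOnly = FALSE))
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(est)))
    rss <- sum(w * stats::resid(fit)^2)
    conv <- "nls"
  } else {
    opt <- stats::optim(log(start), objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    # polish from the Nelder-Mead optimum; restart once for safety
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    est <- exp(opt$par)
    se <- se_from_hessian(objective, opt$par, est, length(v))
    rss <- opt$value
    conv <- if (opt$convergence == 0) "optim" else "non-convergence"
  }
  names(se) <- names(est)

  out <- list(
    Km = unname(est[["Km"]]),
    Vmax = unname(est[["Vmax"]]),
    Ki = if (model == "si") unname(est[["Ki"]]) else Inf,
    se = se,
    rss = unname(rss),
    model = model,
    weighting = weighting,
    n = length(v),
    convergence = conv,
    substrate = attr(curve, "substrate") %||% "substrate"
  )
  class(out) <- "kinetic_params"
  out
}

# First-order standard errors from the curvature of a log-parameterized
# least-squares objective: Var(theta) ~ 2 * sigma^2 * H^-1, mapped back
# through the exponential.
se_from_hessian <- function(objective, log_par, est, n) {
  k <- length(log_par)
  sigma2 <- objective(log_par) / max(n - k, 1)
  H <- tryCatch(stats::optimHess(log_par, objective), error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, k))
  cov_log <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov_log)) return(rep(NA_real_, k))
  sqrt(pmax(diag(cov_log), 0)) * est   # delta method for exp()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kinetic_params <- function(x, ...) {
  lab <- if (x$model == "mm") "Michaelis-Menten" else "substrate inhibition"
  cat("<kinetic_params> ", lab, " fit (", x$substrate, ", n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  Km   = %.4g mM (se %.3g)\n", x$Km, x$se[["Km"]]))
  cat(sprintf("  Vmax = %.4g uM/min (se %.3g)\n", x$Vmax, x$se[["Vmax"]]))
  if (is.finite(x$Ki)) {
    cat(sprintf("  Ki   = %.4g mM (se %.3g)\n", x$Ki, x$se[["Ki"]]))
  }
  if (!is.null(x$kcat)) {
    cat(sprintf("  kcat = %.4g /min, kcat/Km = %.4g /min/mM\n",
                x$kcat, x$specificity))
  }
  cat(sprintf("  RSS  = %.4g\n", x$rss))
  invisible(x)
}

#' Derive turnover and specificity constants
#'
#' Adds `kcat = Vmax / [E]` and the specificity constant `kcat / Km` to a
#' fitted parameter set, with first-order propagation of the fit standard
#' errors (the enzyme concentration is treated as exact).
#'
#' @param params A `kinetic_params` object from [fit_saturation()].
#' @param enzyme_conc_uM Active-site concentration in uM (> 0).
#' @return The input object with `kcat` (1/min), `specificity` (1/min/mM),
#'   `enzyme_conc_uM` and their standard errors added to `se`.
#' @export
derive_constants <- function(params, enzyme_conc_uM) {
  stopifnot(inherits(params, "kinetic_params"), enzyme_conc_uM > 0)
  if (is.null(params$Vmax) || is.null(params$Km)) {
    stop("Vmax and Km are required")
  }
  kcat <- params$Vmax / enzyme_conc_uM
  spec <- kcat / params$Km
  se_kcat <- params$se[["Vmax"]] / enzyme_conc_uM
  se_spec <- spec * sqrt((se_kcat / kcat)^2 +
                           (params$se[["Km"]] / params$Km)^2)
  params$kcat <- kcat
  params$specificity <- spec
  params$enzyme_conc_uM <- enzyme_conc_uM
  params$se <- c(params$se[setdiff(names(params$se), c("kcat", "specificity"))],
                 kcat = unname(se_kcat), specificity = unname(se_spec))
  params
}
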