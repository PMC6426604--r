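#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the published assay designs: a 12-point substrate grid
#' from 0.1 mM up to the 7.6 mM l-DOPA solubility limit, 5% multiplicative
#' noise (HPLC/plate-reader signals scale with concentration), endpoint
#' series at initial betalamic acid up to 100 uM read after 12 h, and
#' ~30 h cascade monitoring.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise (>= 0).
#' @param n_points Number of design points for grids built on the fly
#'   (>= 3).
#' @param substrate_grid_mM,bet0_grid_uM,time_grid_h Optional explicit
#'   strictly increasing design grids overriding the defaults.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = NULL, noise_cv = 0.05, n_points = 12,
                             substrate_grid_mM = NULL, bet0_grid_uM = NULL,
                             time_grid_h = NULL) {
  stopifnot(noise_cv >= 0, n_points >= 3)
  for (g in list(substrate_grid_mM, bet0_grid_uM, time_grid_h)) {
    if (!is.null(g) && any(diff(g) <= 0)) {
      stop("design grids must be strictly increasing")
    }
  }
  structure(list(seed = seed, noise_cv = noise_cv, n_points = n_points,
                 substrate_grid_mM = substrate_grid_mM,
                 bet0_grid_uM = bet0_grid_uM,
                 time_grid_h = time_grid_h),
            class = "generator_config")
}

# Multiplicative Gaussian noise, truncated so the factor stays >= 0.05
# (keeps concentrations non-negative under heavy draws).
noise_factor <- function(n, cv) {
  if (cv == 0) rep(1, n) else pmax(1 + stats::rnorm(n, 0, cv), 0.05)
}

apply_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
}

#' Generate a synthetic saturation curve
#'
#' Rates are the chosen rate law evaluated at the design grid times a
#' multiplicative Gaussian factor `1 + eps`, `eps ~ N(0, cv^2)` truncated at
#' -0.95.
#'
#' @param truth List (or `kinetic_params`) with `Km`, `Vmax` and optionally
#'   finite `Ki` (which switches the generator to the substrate-inhibition
#'   law).
#' @param cfg A [generator_config()].
#' @return A [saturation_curve()].
#' @examples
#' gen_saturation(list(Km = 1.36, Vmax = 5.26), generator_config(seed = 1))
#' @export
gen_saturation <- function(truth, cfg = generator_config()) {
  apply_seed(cfg)
  S <- cfg$substrate_grid_mM %||%
    seq(0.1, 7.6, length.out = cfg$n_points)
  Ki <- truth$Ki %||% Inf
  v <- if (is.finite(Ki)) {
    si_rate(S, truth$Km, truth$Vmax, Ki)
  } else {
    mm_rate(S, truth$Km, truth$Vmax)
  }
  saturation_curve(S, v * noise_factor(length(S), cfg$noise_cv))
}

#' Generate synthetic condensation data
#'
#' Either fixed-time endpoints over a grid of initial betalamic acid
#' concentrations (`type = "endpoints"`, read at `t_h`) or a dopaxanthin
#' time course at fixed `bet0_uM` (`type = "course"`), both from the
#' closed-form pseudo-first-order accumulation law plus multiplicative
#' noise.
#'
#' @param truth A [condensation_scheme()].
#' @param cfg A [generator_config()].
#' @param type `"endpoints"` or `"course"`.
#' @param t_h Endpoint read time, h (endpoints only).
#' @param bet0_uM Fixed initial betalamic acid, uM (course only).
#' @return A data frame: columns `bet0_uM`, `dopax_uM` with attributes `t_h`
#'   and `dopa_M` (endpoints), or `t_h`, `dopax_uM` with attributes
#'   `bet0_uM` and `dopa_M` (course).
#' @export
gen_condensation <- function(truth, cfg = generator_config(),
                             type = c("endpoints", "course"),
                             t_h = 12, bet0_uM = 100) {
  stopifnot(inherits(truth, "condensation_scheme"))
  type <- match.arg(type)
  apply_seed(cfg)
  if (type == "endpoints") {
    b0 <- cfg$bet0_grid_uM %||% c(25, 50, 75, 100)
    dopax <- dopax_accumulation(b0, truth, t_h) *
      noise_factor(length(b0), cfg$noise_cv)
    structure(data.frame(bet0_uM = b0, dopax_uM = dopax),
              t_h = t_h, dopa_M = truth$dopa_M)
  } else {
    tt <- cfg$time_grid_h %||% seq(0, 12, length.out = 25)
    dopax <- dopax_accumulation(bet0_uM, truth, tt) *
      noise_factor(length(tt), cfg$noise_cv)
    structure(data.frame(t_h = tt, dopax_uM = dopax),
              bet0_uM = bet0_uM, dopa_M = truth$dopa_M)
  }
}

#' Generate a synthetic cascade time course
#'
#' Integrates the deterministic cascade and perturbs every species reading
#' with independent multiplicative noise; optionally normalizes each species
#' to its own maximum, the presentation used for multi-wavelength HPLC
#' monitoring.
#'
#' @param truth A [cascade_params()].
#' @param cfg A [generator_config()].
#' @param normalize Scale each species column to max 1?
#' @return A `cascade_timecourse` data frame.
#' @export
gen_cascade <- function(truth, cfg = generator_config(), normalize = FALSE) {
  stopifnot(inherits(truth, "cascade_params"))
  apply_seed(cfg)
  tt <- cfg$time_grid_h %||% seq(0, 30, length.out = 121)
  course <- simulate_cascade(truth, times = tt)
  for (sp in CASCADE_SPECIES) {
    course[[sp]] <- course[[sp]] * noise_factor(nrow(course), cfg$noise_cv)
    if (normalize && max(course[[sp]]) > 0) {
      course[[sp]] <- course[[sp]] / max(course[[sp]])
    }
  }
  course
}
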