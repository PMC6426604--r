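test_that("cascade RHS has the stated structure and conserves DOPA units", {
  p <- cascade_params()
  expect_identical(unname(cascade_rhs(rep(0, 6), p)), rep(0, 6))
  p0 <- cascade_params(k_cond = 0)
  set.seed(21)
  for (i in 1:25) {
    state <- runif(6, 0, 2000)
    d <- cascade_rhs(state, p, t = 1)
    # weighted sum (dopaxanthin counts twice) is identically zero
    expect_equal(sum(d[1:5]) + 2 * d[[6]], 0, tolerance = 1e-12)
    expect_identical(cascade_rhs(state, p0, t = 1)[["dopaxanthin"]], 0)
  }
  # enzyme window: no enzymatic flux past t_off
  d_off <- cascade_rhs(c(1000, 0, 0, 0, 0, 0), p, t = p$enzyme_t_off + 1)
  expect_identical(d_off[["seco45"]], 0)
})

test_that("simulation is constant with the enzyme off and conserves mass", {
  tc <- simulate_cascade(cascade_params(Vmax = 0, DOPA0 = 2.5),
                         times = seq(0, 10, 1))
  expect_equal(tc$DOPA, rep(2500, 11))
  expect_true(all(as.matrix(tc[betakin:::CASCADE_SPECIES[-1]]) == 0))

  tc <- simulate_cascade(cascade_params(), times = seq(0, 30, 0.25))
  eq <- dopa_equivalents(tc)
  expect_lt(max(abs(eq - eq[1])) / eq[1], 1e-6)
  expect_true(all(as.matrix(tc[-1]) > -1e-6))
})

test_that("default simulation has the observed qualitative shape", {
  tc <- simulate_cascade(cascade_params(), times = seq(0, 30, 0.1))
  s45 <- lag_time(tc$time_h, tc$seco45)
  s23 <- lag_time(tc$time_h, tc$seco23)
  bet <- lag_time(tc$time_h, tc$betalamic)
  expect_lt(s45$t_peak, bet$t_peak)  # seco maxima precede betalamic maximum
  expect_lt(s23$t_peak, bet$t_peak)
  expect_true(is_unimodal(tc$betalamic))
  expect_true(is_unimodal(tc$seco45))
  expect_true(lag_time(tc$time_h, tc$muscaflavin)$monotone)
  expect_true(lag_time(tc$time_h, tc$dopaxanthin)$monotone)
  # betalamic acid genuinely declines after its maximum
  expect_lt(tc$betalamic[length(tc$betalamic)], 0.9 * bet$peak_value)
})

test_that("branching extremes switch off the corresponding products", {
  tt <- seq(0, 20, 0.5)
  tc1 <- simulate_cascade(cascade_params(phi45 = 1), times = tt)
  expect_true(all(tc1$muscaflavin < 1e-8))
  expect_true(all(tc1$seco23 < 1e-8))
  tc0 <- simulate_cascade(cascade_params(phi45 = 0), times = tt)
  expect_true(all(tc0$betalamic < 1e-8))
  expect_true(all(tc0$dopaxanthin < 1e-8))
})

test_that("fast 4,5-cyclization collapses onto the reduced 5-species model", {
  # independent reduced model: seco45 eliminated, enzymatic flux feeds
  # betalamic acid directly
  reduced_rhs <- function(p) function(t, y) {
    S <- y[1]
    v <- if (S <= 0 || t > p$enzyme_t_off) 0 else {
      p$Vmax_uM_h * S / (p$Km_uM + S)
    }
    vc <- p$k_cond_uM * y[3] * S
    c(-v - vc,
      (1 - p$phi45) * v - p$k_cyc23 * y[2],
      p$phi45 * v - vc,
      p$k_cyc23 * y[2],
      vc)
  }
  tt <- seq(0, 20, 0.5)
  err <- vapply(c(5, 20, 80), function(kc) {
    p <- cascade_params(k_cyc45 = kc)
    full <- simulate_cascade(p, times = tt)
    red <- ode_rk45(reduced_rhs(p), c(p$DOPA0_uM, 0, 0, 0, 0), tt,
                    rtol = 1e-8, atol = 1e-10)
    expect_lt(max(full$seco45[-1]) / max(full$betalamic), 5 / kc)
    max(abs(full$betalamic - red[, 4])) / max(full$betalamic)
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # error shrinks as k_cyc45 grows
  expect_lt(err[3], 0.02)
})

test_that("enzymatic step at trace substrate matches the linear-chain
           closed form", {
  # DOPA0 << Km, condensation off: DOPA -> seco45 -> betalamic is a linear
  # chain with k1 = Vmax/Km and k2 = k_cyc45; betalamic acid has the
  # two-exponential solution
  p <- cascade_params(Vmax = 5.26, Km = 1.36, DOPA0 = 1e-3, phi45 = 1,
                      k_cyc45 = 0.8, k_cond = 0, enzyme_t_off = Inf)
  k1 <- p$Vmax_uM_h / p$Km_uM
  k2 <- p$k_cyc45
  tt <- seq(0, 15, 0.25)
  tc <- simulate_cascade(p, times = tt)
  analytic <- p$DOPA0_uM *
    (1 + (k1 * exp(-k2 * tt) - k2 * exp(-k1 * tt)) / (k2 - k1))
  expect_lt(max(abs(tc$betalamic - analytic)) / p$DOPA0_uM, 1e-3)
})

test_that("lag construction behaves on known curves", {
  t <- seq(0, 10, 0.1)
  # saturating exponential: maximal rate at t = 0, so no lag
  s <- lag_time(t, 1 - exp(-0.8 * t))
  expect_equal(s$lag, 0)
  expect_true(s$monotone)
  # two-step chain A -> B -> C from pure A: C is sigmoidal with a lag
  k1 <- 1; k2 <- 0.5
  C <- 1 + (k1 * exp(-k2 * t) - k2 * exp(-k1 * t)) / (k2 - k1)
  sC <- lag_time(t, C)
  expect_gt(sC$lag, 0)
  expect_error(lag_time(t, rep(0, length(t))), "all-zero")
  expect_error(lag_time(t[1:4], rep(1, 4)))
})

test_that("lag ordering dopaxanthin > betalamic > 0 across a parameter
           sweep", {
  set.seed(42)
  tt <- seq(0, 30, length.out = 91)
  for (i in 1:30) {
    p <- cascade_params(
      Vmax = runif(1, 1, 8), Km = runif(1, 0.5, 4),
      phi45 = runif(1, 0.25, 0.85),
      k_cyc45 = runif(1, 0.08, 1.5), k_cyc23 = runif(1, 0.08, 1.5),
      k_cond = runif(1, 80, 400), DOPA0 = runif(1, 1, 5),
      # finite enzyme window: the regime where the lag ordering is a theorem
      enzyme_t_off = runif(1, 3, 15)
    )
    tc <- simulate_cascade(p, times = tt)
    lag_bet <- lag_time(tc$time_h, tc$betalamic)$lag
    lag_dpx <- lag_time(tc$time_h, tc$dopaxanthin)$lag
    expect_gt(lag_bet, 0)
    expect_gt(lag_dpx, lag_bet)
    eq <- dopa_equivalents(tc)
    expect_lt(max(abs(eq - eq[1])) / eq[1], 1e-6)
  }
})

test_that("fit_cascade recovers free parameters from noiseless data", {
  truth <- cascade_params(k_cyc45 = 0.2, k_cyc23 = 0.12)
  obs <- simulate_cascade(truth, times = seq(0, 20, length.out = 41))

  f1 <- fit_cascade(obs, free = "k_cyc45",
                    init = cascade_params(k_cyc45 = 0.5, k_cyc23 = 0.12))
  expect_equal(f1$params$k_cyc45, 0.2, tolerance = 1e-4)
  expect_false(f1$flat)

  f2 <- fit_cascade(obs, free = c("k_cyc45", "k_cyc23"),
                    init = cascade_params(k_cyc45 = 0.4, k_cyc23 = 0.3))
  expect_equal(f2$params$k_cyc45, 0.2, tolerance = 1e-2)
  expect_equal(f2$params$k_cyc23, 0.12, tolerance = 1e-2)
  expect_identical(f2$convergence, "converged")
})

test_that("fit_cascade flags a non-identifiable configuration as flat", {
  truth <- cascade_params(phi45 = 1, k_cond = 0)
  obs <- simulate_cascade(truth, times = seq(0, 10, length.out = 21))
  # k_cyc23 never influences any observed species when phi45 = 1
  f <- fit_cascade(obs[c("time_h", "DOPA", "muscaflavin")],
                   free = "k_cyc23", init = truth)
  expect_true(f$flat)
  expect_error(fit_cascade(obs, free = "nope", init = truth), "must be among")
  expect_error(fit_cascade(obs[c("time_h", "DOPA")], free = "k_cyc45",
                           init = truth), ">= 2 observed species")
})

test_that("noisy cascade fits recover cyclization rates within 15%", {
  # scaled-down replicate study (10 seeds) of the 100-replicate design
  truth <- cascade_params(k_cyc45 = 0.2, k_cyc23 = 0.12)
  cfg_t <- seq(0, 20, length.out = 31)
  rel_err <- vapply(1:10, function(i) {
    obs <- gen_cascade(truth, generator_config(seed = i, noise_cv = 0.05,
                                               time_grid_h = cfg_t))
    f <- fit_cascade(obs, free = c("k_cyc45", "k_cyc23"),
                     init = cascade_params(k_cyc45 = 0.35, k_cyc23 = 0.2))
    max(abs(f$params$k_cyc45 - 0.2) / 0.2,
        abs(f$params$k_cyc23 - 0.12) / 0.12)
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.15)
})
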