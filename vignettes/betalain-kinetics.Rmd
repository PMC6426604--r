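---
title: "Models and methods: enzymatic-chemical kinetics of betalain formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: enzymatic-chemical kinetics of betalain formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betakin)
```

# The system

Betalain biosynthesis starts from l-DOPA. A 4,5-extradiol dioxygenase (DODA)
opens the catechol ring; the open-ring 4,5-seco-DOPA then cyclizes
spontaneously to betalamic acid, the structural and bioactive unit of all
betalains. A competing 2,3-extradiol cleavage gives 2,3-seco-DOPA and, after
cyclization, the isomer muscaflavin, which is terminal in this system.
Betalamic acid finally condenses — chemically, without any enzyme — with an
intact l-DOPA molecule to give the yellow pigment dopaxanthin. The bacterial
enzyme this package was built around (from *Gluconacetobacter
diazotrophicus*) made all of these steps observable in one pot, which is
exactly the structure the package models: one enzymatic step feeding a chain
of spontaneous reactions.

`betakin` treats the system at four levels, each usable on its own:

1. initial-rate enzyme kinetics (saturation curves);
2. the isolated condensation reaction under pseudo-first-order conditions;
3. the full cascade as a six-species ODE system;
4. the mass-spectrometric arithmetic used to identify the metabolites and
   the enzyme itself.

# Enzyme kinetics

## Models

For l-DOPA the enzyme follows plain Michaelis–Menten kinetics,

$$v = \frac{V_\max S}{K_m + S},$$

while catechol-type substrates show inhibition by excess substrate. The
substrate-inhibition law is fixed to the canonical uncompetitive form

$$v = \frac{V_\max S}{K_m + S\left(1 + S/K_i\right)},$$

which reduces to Michaelis–Menten as $K_i \to \infty$ and has its optimum at
$S^* = \sqrt{K_m K_i}$. Other parameterizations of excess-substrate
inhibition exist; this one was chosen because it is the textbook default,
and it is isolated behind `si_rate()` so a different form could be swapped
in without touching the fitting code.

## Fitting

`fit_saturation()` minimizes unweighted least squares, matching how such
assays are usually fit in practice; a `weighting = "relative"` option
(weights $1/v^2$) is available when the error is proportional to the signal.
Starting values are the standard heuristics: $V_{\max,0}$ is the largest
observed rate, $K_{m,0}$ the interpolated half-saturating concentration, and
$K_{i,0}$ the largest assayed concentration. Gauss–Newton iteration
(`nls`, port algorithm, positivity bounds) does the work; if it fails — the
typical case being noise-free data with an exactly-zero residual — a
Nelder–Mead polish on log-parameters takes over, with standard errors from
the curvature of the objective. Noiseless model-generated data are recovered
to better than $10^{-6}$ relative error either way, and an exhaustive
grid-search oracle in the test suite confirms the optimizer lands in the
right basin on small instances.

`derive_constants()` adds $k_\mathrm{cat} = V_\max/[E]$ and the specificity
constant $k_\mathrm{cat}/K_m$, propagating fit uncertainties to first order
and treating the enzyme concentration as exact. The active-site
concentration is deliberately an argument, never a default: it is an assay
property, not a model constant. (With the reference values
$V_\max = 5.26$ µM·min⁻¹ and $k_\mathrm{cat} = 0.50$ min⁻¹ one back-computes
$[E] \approx 10.5$ µM, which the examples use for illustration only.)

## Units

Substrate concentrations are mM, rates µM·min⁻¹ throughout the kinetics
module. Conversions happen at I/O boundaries, never inside a model — the
historic failure mode of kinetic software being silent unit drift.

# The condensation reaction

With two reactants and 1:1 stoichiometry the condensation is second order,
$v = k[\mathrm{bet}][\mathrm{DOPA}]$, with mass balance
$[\mathrm{bet}]_0 = [\mathrm{bet}] + [\mathrm{dopax}]$. Holding l-DOPA in
large excess (mM against ≤ 100 µM betalamic acid) makes it
pseudo-first-order with $k_\mathrm{app} = k[\mathrm{DOPA}]$ and

$$[\mathrm{dopax}](t) = [\mathrm{bet}]_0\,(1 - e^{-k_\mathrm{app} t}).$$

Two independent estimators are provided:

* **Endpoint slope** (`estimate_k()`): dopaxanthin measured at one fixed
  time $t$ over a series of $[\mathrm{bet}]_0$ values is proportional to
  $[\mathrm{bet}]_0$ with slope $s = 1 - e^{-k_\mathrm{app} t}$. The slope
  is estimated by regression through the origin (zero substrate must give
  zero product; an intercept would be a dimensional artifact) and inverted
  as $k_\mathrm{app} = -\ln(1 - s)/t$. A form $\ln(s)/t$ is sometimes
  written for this inversion; it is negative for $s < 1$ and does not invert
  the accumulation law, so the package uses the mathematically consistent
  expression. The estimator refuses slopes outside $(0, 1)$: $s \ge 1$
  violates mass balance and indicates a data problem, $s \le 0$ means no
  reaction.
* **Time-course fit** (`time_course_k()`): nonlinear fit of the
  accumulation law to a dopaxanthin time course at fixed
  $[\mathrm{bet}]_0$.

On shared noise-free data the two agree to well under 0.1%, which the test
suite uses as a cross-estimator oracle. l-DOPA depletion is ignored here by
design (the pseudo-first-order regime requires the excess); the cascade
module lifts that restriction. The condensation constant is pH-dependent;
the package treats $k$ as a per-pH constant and fits no functional pH model,
because none is established.

# The cascade model

## State and rate equations

Six species, all in µM, time in hours:
l-DOPA ($S$), 4,5-seco-DOPA ($s_{45}$), 2,3-seco-DOPA ($s_{23}$), betalamic
acid ($b$), muscaflavin ($m$), dopaxanthin ($x$).

$$
\begin{aligned}
\dot S &= -v_\mathrm{enz} - k_\mathrm{cond} b S \\
\dot s_{45} &= \varphi\, v_\mathrm{enz} - k_{45} s_{45} \\
\dot s_{23} &= (1-\varphi)\, v_\mathrm{enz} - k_{23} s_{23} \\
\dot b &= k_{45} s_{45} - k_\mathrm{cond} b S \\
\dot m &= k_{23} s_{23} \\
\dot x &= k_\mathrm{cond} b S
\end{aligned}
$$

with $v_\mathrm{enz}$ the substrate-inhibition rate law on $S$ (plain
Michaelis–Menten when $K_i = \infty$, the l-DOPA default). Cyclization is
lumped into single first-order steps — the intramolecular mechanism has
several elementary steps, but only the overall disappearance of the seco
pools is observable. The two cyclization routes get independent constants
$k_{45}$ and $k_{23}$, since nothing forces the isomers to share a rate.
Each dopaxanthin consumes one betalamic acid *and one intact l-DOPA*, so the
DOPA-equivalent sum $S + s_{45} + s_{23} + b + m + 2x$ is conserved exactly
by the vector field; every simulation is checked against this invariant to
$< 10^{-6}$ relative (observed: $\sim 10^{-15}$).

## The enzyme-active window

`cascade_params(enzyme_t_off = ...)` ends the enzymatic step at a fixed
time, a deliberately coarse representation of enzyme inactivation and
oxygen exhaustion in a closed vessel. It matters structurally, not just
cosmetically: while the enzyme runs, betalamic acid approaches its
quasi-steady value from below and **cannot** overshoot — one can check from
$\dot b$ that the quasi-steady level
$\varphi V / (k_\mathrm{cond}(K_m + S))$ only grows as $S$ falls. A
betalamic-acid maximum followed by a decline therefore requires the
enzymatic phase to end while intact l-DOPA remains for the condensation to
consume. That is also how the real system behaves: pigment keeps forming
after the enzyme-catalyzed reaction is over.

## Defaults and what they mean

| parameter | default | unit | basis |
|---|---|---|---|
| `Vmax` | 5.26 | µM·min⁻¹ | reference l-DOPA characterization |
| `Km` | 1.36 | mM | reference l-DOPA characterization |
| `Ki` | `Inf` | mM | no substrate inhibition for l-DOPA |
| `phi45` | 0.5 | — | both seco isomers are detected; no measured ratio exists, so the branching is split evenly and left configurable |
| `k_cyc45` | 0.15 | h⁻¹ | illustrative; see below |
| `k_cyc23` | 0.10 | h⁻¹ | illustrative; see below |
| `k_cond` | 189 | h⁻¹·M⁻¹ | measured condensation constant |
| `DOPA0` | 2.5 | mM | typical assay concentration |
| `enzyme_t_off` | 5 | h | demo window; see below |

The cyclization constants are **not measured quantities** — treat the
defaults as a demonstration configuration, not fitted truth. They were
chosen once so that the default simulation reproduces the observed ordering
of events: seco-DOPA maxima near 5 h preceding a unimodal betalamic-acid
curve, monotone muscaflavin and dopaxanthin, and ordered lags. One observed
feature is *not* reproducible under these constraints: with
$k_\mathrm{cond} = 189$ h⁻¹·M⁻¹ fixed, the betalamic maximum lands ~3 h
after the enzyme window closes (≈ 8 h in the demo), because the
peak-to-peak spacing is bounded by $k_\mathrm{cond} \times$ the leftover
l-DOPA. A betalamic maximum as late as 20 h with seco maxima at 5 h would
need a much slower condensation or slower cyclization than the other
observations allow. The package reports the structural properties
(ordering, unimodality, conservation) as its tested claims and treats
absolute peak/lag times as configuration-dependent.

## Numerical integration

No ODE solver package is assumed at run time, so the package carries its own
adaptive Dormand–Prince 5(4) integrator (`ode_rk45()`): embedded error
estimate, proportional step control with factors clamped to [0.2, 5],
first-same-as-last reuse, outputs hit exactly by step capping. Tolerances
default to `rtol = 1e-8`, `atol = 1e-10` µM. The cascade is only mildly
stiff at realistic constants; the test suite pushes $k_{45}$ to 80 h⁻¹
(time-scale separation of ~400×) and checks convergence onto an
independently integrated reduced model. When `enzyme_t_off` is finite the
integration is split at the switch-off time so the discontinuity never sits
inside an adaptive step.

## Lag and peak summaries

`lag_time()` operationalizes the lag as the intercept with the time axis of
the tangent at the point of maximal slope (central finite differences),
clipped at zero — the standard graphical construction for sigmoidal curves.
Peaks are reported only when the discrete maximum is interior to the series;
a maximum on the boundary means "no peak observed in this window", not "no
peak". Monotonicity tolerates fluctuations below a relative tolerance
(default $10^{-6}$) so that integrator-level wiggle does not flip the flag.

A caution discovered during property testing: the intuitive ordering
"dopaxanthin lags more than betalamic acid" is a theorem only in the regime
where the enzymatic phase terminates while l-DOPA remains. With a
perpetually active enzyme and fast condensation
($k_\mathrm{cond}[\mathrm{DOPA}] \gg k_{45}$), betalamic acid becomes a fast
quasi-steady intermediate whose tangent-lag can land *later* than
dopaxanthin's (e.g. $k_\mathrm{cond} = 292$ h⁻¹·M⁻¹, DOPA₀ = 3.4 mM,
$k_{45} = 0.12$ h⁻¹ gives lags of 9.7 h vs 4.9 h). The property-based tests
therefore assert the ordering across random parameter sweeps with finite
enzyme windows — the experimentally relevant regime — and assert the
regime-independent properties (conservation, monotone terminal products,
betalamic unimodality) everywhere.

## Whole-model fitting

`fit_cascade()` estimates a named subset (≤ 4) of parameters by repeated
simulation, on log scale (logit for the branching fraction), against all
species columns present in the observed course. Noise-free synthetic data
return the generating parameters to < 1%. A flatness probe (5% nudges at
the optimum) flags non-identifiable configurations — e.g. freeing
$k_{23}$ when $\varphi = 1$ — instead of returning an arbitrary number.

# Mass arithmetic

Monoisotopic atomic masses are fixed constants (C 12 exactly,
H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069; proton
1.00727646): with these, theoretical metabolite [M+H]⁺ values reproduce to
4 decimal places (dopaxanthin C₁₈H₁₈N₂O₈ → 391.1136, betalamic
acid/muscaflavin C₉H₉NO₅ → 212.0553, the seco-DOPAs C₉H₁₁NO₆ → 230.0659),
and tryptic-peptide [M+H]⁺ values to 2 decimals. Reported ppm differences
are computed as $(m_\mathrm{exp} - m_\mathrm{theo})/m_\mathrm{theo} \times
10^6$, signed; published tables sometimes carry ppm values computed from
more decimal places than they print, so small discrepancies against printed
ppm columns are expected and not forced.

In-silico digestion uses the Keil rule (cleave after K/R, suppressed before
P), returns fragments with up to a chosen number of missed cleavages, and
guarantees that the zero-missed-cleavage fragments concatenate back to the
input. Carbamidomethyl-Cys (+57.02146 Da) is on by default, matching
standard iodoacetamide alkylation; it is a no-op for Cys-free peptides.
N-terminal methionine is retained (no Met-excision logic). Out of scope by
design: isotope envelopes, charge states above 1, MS² fragment annotation,
intact-protein mass deconvolution.

# Purification arithmetic and quantification

`derive_table()` computes total protein (volume × concentration), total
activity (activity × volume), purification fold (specific activity over the
first row) and yield (total activity over the first row). A supplied
specific-activity column takes precedence over the derived ratio, because
assay-volume conventions often make the printed specific activity
non-derivable from the other printed columns; ratios (fold, yield) are
unaffected by that convention. Rounded presentation values (fold to 1
decimal, yield to integer) are returned alongside exact ones.
`beer_lambert_conc()` converts absorbance to µM with a default
ε = 24,000 M⁻¹·cm⁻¹ at 424 nm, the standard coefficient for betalamic acid.

# Synthetic data: what a green test establishes

All generators are pure functions of (truth, config): the same seed gives
bit-identical output. Noise is multiplicative Gaussian,
$y \cdot (1 + \varepsilon)$ with $\varepsilon \sim N(0, \mathrm{CV}^2)$
truncated at −0.95, because chromatographic and plate-reader signals scale
with concentration; there is no additive noise floor and no heteroscedastic
mixture. Default designs mirror the real assays: 12 substrate
concentrations from 0.1 mM to the 7.6 mM l-DOPA solubility limit, endpoint
series at $[\mathrm{bet}]_0 \in \{25, 50, 75, 100\}$ µM read at 12 h with
3.5 mM l-DOPA, ~30 h cascade monitoring, CV 5%.

What the generators do **not** emulate: baseline drift, peak-integration
bias, detector saturation, correlated errors across species measured from
the same injection, pH excursions, enzyme-batch variability. A green
round-trip test therefore establishes that the estimators invert the stated
models under the stated noise — it does not certify behaviour on real
chromatographic data with structured artifacts.

# Known limitations

* Cyclization rate constants are free parameters; absolute cascade timing
  is configuration, not prediction.
* The enzyme window is a step function; real inactivation is gradual.
* The condensation model covers dopaxanthin only — no other amine/amino
  acid condensations, no pigment degradation.
* The lag construction depends on the sampling grid through its finite
  differences; very coarse grids bias lags upward.
* `fit_cascade()` with noisy data and ≥ 3 free parameters inherits the
  usual pathologies of small nonlinear inverse problems; inspect `rss` and
  the `flat` flag.
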