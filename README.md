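# betakin

Quantitative analysis of betalain formation by a bacterial DOPA
4,5-extradiol dioxygenase (DODA) and the spontaneous chemistry downstream of
it. Betalains — the yellow betaxanthins and violet betacyanins of
Caryophyllales plants — are all built on betalamic acid, which forms when a
dioxygenase opens the aromatic ring of l-DOPA and the resulting 4,5-seco-DOPA
cyclizes on its own. The discovery of this activity in a bacterium makes the
early pathway experimentally tractable end to end: enzyme kinetics, the
open-ring intermediates, the cyclization products (betalamic acid and its
2,3-cleavage isomer muscaflavin) and the final condensation of betalamic acid
with intact l-DOPA into the pigment dopaxanthin.

`betakin` is aimed at enzymologists and systems biologists working with this
(or any comparable) enzymatic–chemical cascade. It provides:

* **Saturation-curve fitting** — Michaelis–Menten
  `v = V_max S / (K_m + S)` and substrate inhibition
  `v = V_max S / (K_m + S(1 + S/K_i))`, with standard errors, turnover
  number `k_cat = V_max/[E]` and specificity constant `k_cat/K_m`
  (`fit_saturation()`, `derive_constants()`).
* **Pseudo-first-order condensation analysis** — with l-DOPA in excess the
  second-order condensation `v = k[bet][DOPA]` reduces to
  `k_app = k[DOPA]`, and dopaxanthin accumulates as
  `[dopax](t) = [bet]_0 (1 − e^{−k_app t})`. Both the endpoint-slope
  estimator (`estimate_k()`) and a time-course fit (`time_course_k()`)
  invert this law.
* **A six-species cascade ODE model** — l-DOPA → 4,5-/2,3-seco-DOPA →
  betalamic acid / muscaflavin → dopaxanthin, with an enzyme-active time
  window, DOPA-equivalent conservation, lag/peak summaries and whole-model
  fitting (`simulate_cascade()`, `lag_time()`, `fit_cascade()`).
* **Exact-mass identification arithmetic** — monoisotopic masses, [M+H]⁺
  m/z, ppm errors, in-silico tryptic digestion and peptide-mass-fingerprint
  matching (`protonated_mz()`, `peptide_mh()`, `tryptic_digest()`,
  `pmf_match()`).
* **Purification-table bookkeeping and Beer–Lambert quantification**
  (`derive_table()`, `beer_lambert_conc()`).
* **Seeded synthetic-data generators** for every estimator
  (`gen_saturation()`, `gen_condensation()`, `gen_cascade()`), so the whole
  pipeline is testable without any external data.

## Worked example

```r
library(betakin)

## 1. Enzyme kinetics: simulate a 12-point l-DOPA saturation assay
##    (0.1-7.6 mM, 5% noise) and fit it
curve <- gen_saturation(list(Km = 1.36, Vmax = 5.26),
                        generator_config(seed = 2026))
fit <- derive_constants(fit_saturation(curve, "mm"), enzyme_conc_uM = 10.52)
fit
#> <kinetic_params> Michaelis-Menten fit (l-DOPA, n = 12)
#>   Km   = 1.366 mM (se 0.143)
#>   Vmax = 5.087 uM/min (se 0.144)
#>   kcat = 0.4836 /min, kcat/Km = 0.354 /min/mM
#>   RSS  = 0.1835
```

The generating truth was `K_m = 1.36` mM and `V_max = 5.26` µM·min⁻¹; one
noisy assay recovers 1.366 mM and 5.09 µM·min⁻¹, and with 10.52 µM active
sites the turnover number comes out at 0.48 min⁻¹.

```r
## 2. Condensation: endpoint series at four initial betalamic acid
##    concentrations, read after 2 h at 3.5 mM l-DOPA
sch <- condensation_scheme(k = 189, dopa_M = 3.5e-3)
b0 <- c(25, 50, 75, 100)
estimate_k(b0, dopax_accumulation(b0, sch, t_h = 2), t_h = 2, dopa_M = 3.5e-3)
#> <condensation_scheme> k = 189 /h/M at [DOPA] = 0.0035 M (k_app = 0.6615 /h)
#>   slope = 0.7337 over n = 4 points
```

The slope of dopaxanthin vs `[bet]_0` (0.734) inverts to
`k_app = −ln(1 − s)/t = 0.6615` h⁻¹, i.e. `k = 189` h⁻¹·M⁻¹ at 3.5 mM
l-DOPA — an exact round trip on noise-free data.

```r
## 3. Cascade: simulate the full mechanism and summarize the curves
tc <- simulate_cascade(cascade_params(), times = seq(0, 30, 0.25))
lag_time(tc$time_h, tc$betalamic)
#> <curve_summary> lag 1.43 h, peak 115 uM at 8 h, monotone FALSE
lag_time(tc$time_h, tc$dopaxanthin)
#> <curve_summary> lag 3.32 h, peak none (boundary), monotone TRUE
```

Betalamic acid appears after a lag (its seco-DOPA precursor must build up
first), peaks, and declines as it condenses with leftover l-DOPA;
dopaxanthin lags further and accumulates monotonically.

```r
## 4. Identification arithmetic
protonated_mz("C18H18N2O8")   # dopaxanthin [M+H]+  -> 391.1136
peptide_mh("DGIWLGQPR")       # tryptic peptide     -> 1041.55
ppm_error(391.1141, 391.1136) # TOF accuracy check  -> 1.28 ppm
```

## Command line

An executable wrapper is installed at `inst/cli/betakin`
(`system.file("cli", "betakin", package = "betakin")`):

```sh
betakin mass formula C18H18N2O8
betakin generate saturation --seed 1 --out sat.csv
betakin fit-mm sat.csv --enzyme-conc-uM 10.52
betakin simulate --t-end 30 --n 121 --out course.csv
betakin lag course.csv --species dopaxanthin
```

## Documentation

The methods vignette (`vignettes/betalain-kinetics.Rmd`) describes the
models, their assumptions, every tunable parameter, the synthetic-data
generators and the package's numerical and design choices in detail.
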