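Package: betakin
Title: Enzymatic and Chemical Kinetics of Bacterial Betalain Biosynthesis
Version: 0.1.0
Authors@R:
    person("Murcia", "Pigments Lab", email = "pigments@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of betalain formation by a
    bacterial DOPA 4,5-extradiol dioxygenase: saturation-curve fitting
    (Michaelis-Menten and substrate inhibition) with derived turnover and
    specificity constants, pseudo-first-order estimation of the rate constant
    for the spontaneous condensation of betalamic acid with l-DOPA, an ODE
    model of the full enzymatic-chemical cascade (l-DOPA to seco-DOPA
    intermediates to betalamic acid or muscaflavin to dopaxanthin) with lag
    and peak summaries, exact monoisotopic mass arithmetic for metabolite and
    tryptic-peptide identification, purification-table bookkeeping, and
    seeded synthetic-data generators that close the loop on every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
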