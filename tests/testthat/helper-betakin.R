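# Shared fixtures, all built in code.

# Published peptide-fingerprint table: tryptic fragments and [M+H]+ (Da).
PMF_TABLE <- data.frame(
  peptide = c("MTPVPEPIRQIGTIGSYHAHVYFDGPDGR", "QIGTIGSYHAHVYFDGPDGR",
              "DGIWLGQPRALLGSR", "DGIWLGQPR", "MTPVPEPIR", "AAIADR", "DHLR"),
  mh = c(3210.58, 2190.04, 1638.91, 1041.55, 1039.56, 616.34, 540.29)
)

# Metabolite formulas and theoretical [M+H]+ (Da).
METABOLITE_TABLE <- data.frame(
  compound = c("dopaxanthin", "betalamic acid / muscaflavin", "seco-DOPAs"),
  formula = c("C18H18N2O8", "C9H9NO5", "C9H11NO6"),
  mz = c(391.1136, 212.0553, 230.0659)
)

# Published two-step purification table.
PURIFICATION_TABLE <- data.frame(
  step = c("Crude extract", "Ni2+ chromatography"),
  volume_ml = c(6.0, 7.0),
  protein_mg_per_ml = c(15.9, 4.5),
  activity = c(1.578, 0.823),
  specific_activity = c(0.595, 1.087)
)

# Published enzyme truth for l-DOPA (mM, uM/min) and condensation constant.
KM_TRUE <- 1.36
VMAX_TRUE <- 5.26
K_COND_TRUE <- 189      # 1/h/M
DOPA_COND_M <- 3.5e-3   # fixed l-DOPA in the condensation assays

# Single local maximum (a monotone rise, a monotone fall, or a rise followed
# by a fall), ignoring fluctuations below a relative tolerance.
is_unimodal <- function(values, tol = 1e-6) {
  d <- diff(values)
  sig <- sign(d)[abs(d) > tol * max(abs(values), 1)]
  if (!length(sig)) return(TRUE)
  changes <- sum(diff(sig) != 0)
  changes == 0 || (changes == 1 && sig[1] > 0)
}
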