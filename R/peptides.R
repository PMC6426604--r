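# Monoisotopic residue masses (Da) for the 20 standard amino acids,
# i.e. the mass each residue contributes inside a peptide chain.
RESIDUE_MASS <- c(
  G = 57.02146372,  A = 71.03711379,  S = 87.03202841,  P = 97.05276385,
  V = 99.06841392,  T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

WATER_MASS <- 2 * MONOISOTOPIC_MASS[["H"]] + MONOISOTOPIC_MASS[["O"]]

# Carbamidomethylation of cysteine by iodoacetamide, the fixed modification
# introduced during reduction/alkylation prior to tryptic digestion.
CARBAMIDOMETHYL <- c(C = 57.02146)

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) stop("empty peptide sequence")
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(residues, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("invalid residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  residues
}

#' Monoisotopic [M+H]+ mass of a peptide
#'
#' Sum of the monoisotopic residue masses plus one water (peptide termini)
#' plus one proton, with any fixed modifications added per matching residue.
#' Carbamidomethylated cysteine (+57.02146 Da) is on by default, matching
#' iodoacetamide alkylation before digestion.
#'
#' @param sequence Peptide as a one-letter amino-acid string.
#' @param fixed_mods Named numeric vector of mass shifts (Da) applied to every
#'   occurrence of the named residue; `NULL` disables all modifications.
#' @param digits Decimals for the returned value; peptide fingerprint tables
#'   print 2.
#' @return The singly protonated monoisotopic m/z in Da.
#' @examples
#' peptide_mh("DGIWLGQPR") # 1041.55
#' @export
peptide_mh <- function(sequence, fixed_mods = CARBAMIDOMETHYL, digits = 2) {
  residues <- check_sequence(sequence)
  mass <- sum(RESIDUE_MASS[residues]) + WATER_MASS + PROTON_MASS
  if (length(fixed_mods)) {
    for (res in names(fixed_mods)) {
      mass <- mass + fixed_mods[[res]] * sum(residues == res)
    }
  }
  round(mass, digits)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminally of lysine and arginine except when the next residue
#' is proline (Keil rule), and enumerates every fragment containing at most
#' `missed_cleavages` internal uncleaved sites.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   (>= 0).
#' @return A data frame with columns `peptide`, `start`, `end`, `missed`,
#'   ordered by `missed` then `start`. The rows with `missed == 0` partition
#'   the input sequence.
#' @examples
#' tryptic_digest("DGIWLGQPRALLGSR")
#' tryptic_digest("AKRG", missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0) {
  residues <- check_sequence(sequence)
  stopifnot(length(missed_cleavages) == 1L, missed_cleavages >= 0)
  n <- length(residues)
  # cut after position i when residue i is K/R and i+1 is not P
  cuts <- which(residues %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  cuts <- cuts[residues[cuts + 1L] != "P"]
  bounds <- c(0L, cuts, n)    # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  pieces <- substring(paste(residues, collapse = ""), starts, ends)
  out <- list()
  for (m in 0:missed_cleavages) {
    i <- seq_len(length(pieces) - m)
    if (!length(i)) break
    out[[m + 1L]] <- data.frame(
      peptide = vapply(i, function(j) paste(pieces[j:(j + m)], collapse = ""),
                       character(1)),
      start = starts[i],
      end = ends[i + m],
      missed = m
    )
  }
  do.call(rbind, out)
}

#' Match observed masses against an in-silico digest
#'
#' Pairs every observed [M+H]+ mass with the closest theoretical tryptic
#' peptide within a ppm tolerance, the assignment step behind a peptide mass
#' fingerprint, and reports the resulting sequence coverage.
#'
#' @param observed Numeric vector of observed [M+H]+ masses (Da); non-empty.
#' @param protein Protein sequence to digest in silico.
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @param missed_cleavages Passed to [tryptic_digest()].
#' @param fixed_mods Passed to [peptide_mh()].
#' @return A data frame with one row per observed mass: `observed_mz`,
#'   `peptide`, `start`, `end`, `missed`, `theoretical_mz`, `delta_ppm`,
#'   `matched`. Unmatched masses have `NA` peptide fields. The fraction of
#'   protein residues covered by matched peptides is in
#'   `attr(, "coverage")`.
#' @export
pmf_match <- function(observed, protein, tol_ppm = 50,
                      missed_cleavages = 1, fixed_mods = CARBAMIDOMETHYL) {
  if (!length(observed)) stop("empty observed mass list")
  stopifnot(is.numeric(observed), all(observed > 0), tol_ppm > 0)
  digest <- tryptic_digest(protein, missed_cleavages)
  digest$theoretical_mz <- vapply(
    digest$peptide, peptide_mh, numeric(1),
    fixed_mods = fixed_mods, digits = 6
  )
  rows <- lapply(observed, function(mz) {
    dppm <- ppm_error(mz, digest$theoretical_mz)
    j <- which.min(abs(dppm))
    if (abs(dppm[j]) <= tol_ppm) {
      data.frame(observed_mz = mz, peptide = digest$peptide[j],
                 start = digest$start[j], end = digest$end[j],
                 missed = digest$missed[j],
                 theoretical_mz = digest$theoretical_mz[j],
                 delta_ppm = dppm[j], matched = TRUE)
    } else {
      data.frame(observed_mz = mz, peptide = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 missed = NA_integer_, theoretical_mz = NA_real_,
                 delta_ppm = NA_real_, matched = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  covered <- rep(FALSE, nchar(protein))
  for (i in which(out$matched)) {
    covered[out$start[i]:out$end[i]] <- TRUE
  }
  attr(out, "coverage") <- mean(covered)
  out
}
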