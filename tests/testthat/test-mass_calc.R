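test_that("formula parsing populates counts and round-trips to Hill order", {
  expect_equal(unclass(parse_formula("C9H9NO5")),
               c(C = 9L, H = 9L, N = 1L, O = 5L), ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("C")), c(C = 1L), ignore_attr = TRUE)
  # round trip and Hill normalization of scrambled input
  for (f in c("C18H18N2O8", "H2O", "C9H11NO6", "O5C9NH9")) {
    canon <- format(parse_formula(f))
    expect_identical(format(parse_formula(canon)), canon)
    expect_equal(monoisotopic_mass(canon), monoisotopic_mass(f))
  }
  expect_identical(format(parse_formula("O5C9NH9")), "C9H9NO5")
  expect_error(parse_formula("C9X2"), "unknown element")
  expect_error(parse_formula("c9h9"), "malformed")
  expect_error(parse_formula(""), "empty")
})

test_that("monoisotopic and protonated masses reproduce the metabolite table", {
  expect_identical(monoisotopic_mass("C"), 12)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4 / 18)
  expect_equal(monoisotopic_mass("C18H18N2O8"), 390.1063,
               tolerance = 5e-4 / 390)
  for (i in seq_len(nrow(METABOLITE_TABLE))) {
    expect_equal(protonated_mz(METABOLITE_TABLE$formula[i]),
                 METABOLITE_TABLE$mz[i], tolerance = 1e-9)
  }
})

test_that("protonation adds exactly one proton mass for any formula", {
  for (f in c("C18H18N2O8", "C9H9NO5", "H2O", "CH4N2O", "C2H6S")) {
    expect_equal(protonated_mz(f, digits = 10) - monoisotopic_mass(f),
                 PROTON_MASS, tolerance = 1e-10)
  }
})

test_that("ppm error follows the defining formula and is signed", {
  expect_equal(ppm_error(391.1141, 391.1136), 1.28, tolerance = 0.02 / 1.28)
  expect_equal(ppm_error(230.0665, 230.0659), 2.61, tolerance = 0.02 / 2.61)
  expect_identical(ppm_error(212.0562, 212.0562), 0)
  # antisymmetric to first order at small errors
  expect_equal(ppm_error(391.1141, 391.1136),
               -ppm_error(391.1136, 391.1141), tolerance = 1e-5)
  expect_error(ppm_error(212.05, 0), "positive")
})

test_that("tryptic digestion applies the Keil rule and partitions the input", {
  expect_identical(tryptic_digest("DGIWLGQPRALLGSR")$peptide,
                   c("DGIWLGQPR", "ALLGSR"))
  expect_identical(tryptic_digest("AKPR")$peptide, "AKPR")
  expect_identical(tryptic_digest("AKRG", 1)$peptide,
                   c("AK", "R", "G", "AKR", "RG"))
  expect_error(tryptic_digest("AKZ"), "invalid residue")
  # 0-missed-cleavage fragments concatenate back to the protein
  set.seed(7)
  for (rep in 1:20) {
    protein <- paste(sample(names(betakin:::RESIDUE_MASS),
                            sample(10:60, 1), replace = TRUE), collapse = "")
    dg <- tryptic_digest(protein, missed_cleavages = 2)
    base <- dg[dg$missed == 0, ]
    expect_identical(paste(base$peptide, collapse = ""), protein)
    expect_identical(base$start, c(1L, utils::head(base$end, -1) + 1L))
    # every m-missed peptide is the concatenation of m+1 consecutive bases
    for (m in 1:2) {
      got <- dg$peptide[dg$missed == m]
      want <- if (nrow(base) > m) {
        vapply(seq_len(nrow(base) - m), function(j) {
          paste(base$peptide[j:(j + m)], collapse = "")
        }, character(1))
      } else character(0)
      expect_identical(got, want)
    }
  }
})

test_that("peptide [M+H]+ reproduces the fingerprint table to 0.01 Da", {
  for (i in seq_len(nrow(PMF_TABLE))) {
    expect_equal(peptide_mh(PMF_TABLE$peptide[i]), PMF_TABLE$mh[i],
                 tolerance = 0.011 / PMF_TABLE$mh[i])
  }
  expect_equal(peptide_mh("G"), 76.04, tolerance = 1e-4)
  expect_error(peptide_mh("GXX"), "invalid residue")
  # carbamidomethyl on by default, only affects Cys
  expect_equal(peptide_mh("ACDK", digits = 6) -
                 peptide_mh("ACDK", fixed_mods = NULL, digits = 6),
               57.02146, tolerance = 1e-8)
  expect_identical(peptide_mh("ADGK"), peptide_mh("ADGK", fixed_mods = NULL))
})

test_that("protein mass is recoverable from its 0-missed digest", {
  protein <- "MTPVPEPIRQIGTIGSYHAHVYFDGPDGRAAIADRDHLR"
  dg <- tryptic_digest(protein)
  # sum of neutral peptide masses minus the extra waters = protein mass
  neutral <- vapply(dg$peptide, function(p) {
    peptide_mh(p, fixed_mods = NULL, digits = 10) - betakin::PROTON_MASS
  }, numeric(1))
  protein_mass <- peptide_mh(protein, fixed_mods = NULL, digits = 10) -
    betakin::PROTON_MASS
  expect_equal(sum(neutral) - (nrow(dg) - 1) * betakin:::WATER_MASS,
               protein_mass, tolerance = 1e-9)
})

test_that("pmf_match assigns within tolerance and reports coverage", {
  protein <- "MTPVPEPIRQIGTIGSYHAHVYFDGPDGRDGIWLGQPRALLGSRAAIADR"
  hit <- pmf_match(1041.55, protein, tol_ppm = 50, missed_cleavages = 0)
  expect_true(hit$matched)
  expect_identical(hit$peptide, "DGIWLGQPR")
  expect_lt(abs(hit$delta_ppm), 50)
  miss <- pmf_match(1041.55, "GGGG", tol_ppm = 50)
  expect_false(miss$matched)
  expect_identical(attr(miss, "coverage"), 0)
  # several masses at once, coverage is the union of matched spans
  both <- pmf_match(c(1041.55, 616.34, 5000), protein, tol_ppm = 50)
  expect_identical(both$matched, c(TRUE, TRUE, FALSE))
  expect_equal(attr(both, "coverage"), (9 + 6) / nchar(protein))
  expect_error(pmf_match(numeric(0), protein), "empty")
})
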