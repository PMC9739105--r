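test_that("residue masses match standard table values and reject unknowns", {
  expect_equal(residue_mass("G", "mono"), 57.02146, tolerance = 1e-7)
  expect_equal(residue_mass("H", "mono") - residue_mass("L", "mono"),
               23.9748, tolerance = 1e-3)
  expect_error(residue_mass("X"), "unknown amino-acid code 'X'")
  expect_error(residue_mass("GG"), "single")
})

test_that("monoisotopic never exceeds average, residues and constants alike", {
  for (aa in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
    expect_lt(residue_mass(aa, "mono"), residue_mass(aa, "average"))
  k <- mass_constants()
  expect_true(all(unlist(k) > 0))
  expect_lte(k$water_mono, k$water_avg)
  expect_lte(k$hydrogen_mono, k$hydrogen_avg)
})

test_that("peptide masses: single residue, additivity, disulfide accounting", {
  expect_equal(peptide_mass(peptide("G"), "mono"), 75.03203,
               tolerance = 1e-6)
  set.seed(101)
  for (i in 1:5) {
    a <- random_sequence(sample(3:20, 1))
    b <- random_sequence(sample(3:20, 1))
    for (mode in c("mono", "average")) {
      expect_equal(peptide_mass(peptide(paste0(a, b)), mode),
                   peptide_mass(peptide(a), mode) +
                     peptide_mass(peptide(b), mode) -
                     mass_constants()[[paste0("water_",
                                              sub("average", "avg", mode))]],
                   tolerance = 1e-9)
    }
  }
})

test_that("each disulfide removes exactly two hydrogens", {
  seq6c <- "ACCGCCKRCCW"  # six cysteines
  h <- mass_constants()
  for (mode in c("mono", "average")) {
    hm <- if (mode == "mono") h$hydrogen_mono else h$hydrogen_avg
    masses <- vapply(0:3, function(k)
      peptide_mass(peptide(seq6c, n_disulfides = k), mode), numeric(1))
    expect_equal(diff(masses), rep(-2 * hm, 3), tolerance = 1e-10)
  }
  # reduced minus oxidized (3 S-S) is 6 hydrogens
  expect_equal(
    peptide_mass(myotoxin3_peptide("45H", oxidized = FALSE), "average") -
      peptide_mass(myotoxin3_peptide("45H"), "average"),
    6 * h$hydrogen_avg, tolerance = 1e-10)
})

test_that("peptide construction validates alphabet and cysteine budget", {
  expect_error(peptide(""), "non-empty")
  expect_error(peptide("AXZ"), "unknown amino-acid code")
  expect_error(peptide("ACA", n_disulfides = 1), "cysteines")
  expect_error(peptide("ACCA", n_disulfides = -1), "non-negative")
  expect_silent(peptide("ACCA", n_disulfides = 1))
})

test_that("isoform mass differences reproduce the His/Leu 24 Da signature", {
  d45 <- mass_difference(myotoxin3_peptide("45H"), myotoxin3_peptide("45L"),
                         "average")
  d43 <- mass_difference(myotoxin3_peptide("43H"), myotoxin3_peptide("43L"),
                         "average")
  expect_equal(d45, 23.98, tolerance = 1e-2)
  expect_equal(d45, d43, tolerance = 1e-10)
  expect_equal(round(d45), 24)
  expect_equal(mass_difference(peptide("AKA"), peptide("ARA"), "mono"),
               -28.006, tolerance = 1e-3)
  expect_equal(mass_difference(peptide("AA"), peptide("AA")), 0)
})

test_that("substitution inference brute-forces all residue pairs", {
  hits <- infer_substitution(24.0, tolerance = 0.1)
  expect_true(any(hits$heavier == "H" & hits$lighter == "L"))
  iso <- infer_substitution(0, tolerance = 0.001)
  expect_setequal(unique(c(iso$heavier, iso$lighter)), c("L", "I"))
  rk <- infer_substitution(28.006, tolerance = 0.01)
  expect_true(any(rk$heavier == "R" & rk$lighter == "K"))
  expect_error(infer_substitution(24, tolerance = 0), "> 0")

  # independently coded second pass over all 380 ordered pairs
  for (delta in c(0, 16, 23.975, 28.006)) {
    tol <- 0.02
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    expected <- list()
    for (x in aa) for (y in aa) {
      if (x == y) next
      d <- residue_mass(x, "mono") - residue_mass(y, "mono")
      if (abs(d - abs(delta)) <= tol)
        expected[[length(expected) + 1L]] <- c(x, y)
    }
    got <- infer_substitution(delta, tol)
    expect_equal(nrow(got), length(expected))
    expect_setequal(paste(got$heavier, got$lighter),
                    vapply(expected, paste, character(1), collapse = " "))
    # sorted by mismatch
    expect_true(!is.unsorted(got$mismatch_da))
  }
})
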