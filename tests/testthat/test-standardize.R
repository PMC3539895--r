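# The five FICTS operators and their composition.

inchiOf <- function(smiles) smilesToStdInchi(smiles)$inchi

test_that("fragment stripping keeps the largest fragment, stated tie-break", {
  expect_identical(inchiOf(stripFragments(SMILES$sodium_acetate)),
                   INCHI$acetate)               # 4 heavy atoms beat Na's 1
  expect_identical(inchiOf(stripFragments("c1ccccc1")),
                   inchiOf("c1ccccc1"))          # identity on one fragment
  # equal heavy-atom counts: keep the lexicographically smaller InChI
  # (ethanol C2H6O < ethylamine C2H7N)
  expect_identical(inchiOf(stripFragments("CCN.CCO")), INCHI$ethanol)
  expect_identical(inchiOf(stripFragments("CCO.CCN")), INCHI$ethanol)
})

test_that("isotope clearing removes the /i layer", {
  expect_identical(inchiOf(SMILES$ethanol_d3), INCHI$ethanol_d3)
  expect_identical(inchiOf(clearIsotopes(SMILES$ethanol_d3)), INCHI$ethanol)
  expect_identical(inchiOf(clearIsotopes(SMILES$ethanol)), INCHI$ethanol)
})

test_that("charge neutralisation is proton-transfer only", {
  expect_identical(inchiOf(neutralizeCharges(SMILES$acetate)),
                   INCHI$acetic_acid)
  expect_identical(inchiOf(neutralizeCharges(SMILES$glycine_zwitterion)),
                   INCHI$glycine)
  # quaternary ammonium has no removable proton: retained as-is
  expect_identical(inchiOf(neutralizeCharges(SMILES$tma)), inchiOf(SMILES$tma))
})

test_that("tautomer canonicalisation collapses tautomer pairs", {
  expect_identical(inchiOf(canonicalTautomer(SMILES$hydroxypyridine)),
                   inchiOf(canonicalTautomer(SMILES$pyridone)))
  expect_identical(inchiOf(canonicalTautomer(SMILES$pyridone)),
                   INCHI$pyridone)
  # keto-enol pair with distinct Standard InChIs collapses too
  expect_false(inchiOf(SMILES$acac_keto) == inchiOf(SMILES$acac_enol))
  expect_identical(inchiOf(canonicalTautomer(SMILES$acac_keto)),
                   inchiOf(canonicalTautomer(SMILES$acac_enol)))
  # no mobile hydrogens: unchanged
  expect_identical(inchiOf(canonicalTautomer(SMILES$neopentane)),
                   inchiOf(SMILES$neopentane))
})

test_that("stereo stripping collapses enantiomers and E/Z pairs", {
  expect_identical(inchiOf(stripStereo(SMILES$l_alanine)),
                   INCHI$alanine_flat)
  expect_identical(inchiOf(stripStereo(SMILES$d_alanine)),
                   INCHI$alanine_flat)
  expect_identical(inchiOf(stripStereo(SMILES$e_butene)), INCHI$butene_flat)
  expect_identical(inchiOf(stripStereo(SMILES$z_butene)), INCHI$butene_flat)
  expect_identical(inchiOf(stripStereo(SMILES$benzene)),
                   inchiOf(SMILES$benzene))
})

test_that("each operator is idempotent on a library sample", {
  smi <- baseLibrary()$smiles[seq(1, 170, by = 11)]
  for (op in list(stripFragments, clearIsotopes, neutralizeCharges,
                  canonicalTautomer, stripStereo)) {
    once <- op(smi)
    expect_false(anyNA(once))
    expect_identical(op(once), once)
  }
})

test_that("applyFicts composes operators in order F,I,C,T,S on InChI input", {
  # baseline is the identity
  base <- applyFicts(INCHI$l_alanine, "FICTS")
  expect_true(base$ok)
  expect_identical(base$inchi, INCHI$l_alanine)
  # stereo-insensitive variant equals the structure-level stereo strip
  glc <- smilesToStdInchi(SMILES$d_glucose)$inchi
  expect_identical(applyFicts(glc, "FICTu")$inchi, INCHI$glucose_flat)
  expect_identical(applyFicts(glc, "FICTu")$inchi,
                   inchiOf(stripStereo(SMILES$d_glucose)))
  # sodium L-lactate under the all-insensitive variant: one neutral,
  # stereo-free, canonical-tautomer lactic acid -- equal to composing the
  # five single operators by hand
  lact <- smilesToStdInchi(SMILES$sodium_l_lactate)$inchi
  composed <- stripStereo(canonicalTautomer(neutralizeCharges(
    clearIsotopes(stripFragments(SMILES$sodium_l_lactate)))))
  expect_identical(applyFicts(lact, "uuuuu")$inchi, INCHI$lactic_flat)
  expect_identical(applyFicts(lact, "uuuuu")$inchi, inchiOf(composed))
  # unparseable input propagates a classified failure, no error
  bad <- applyFicts("InChI=banana", "uuuuu")
  expect_false(bad$ok)
  expect_identical(bad$failure_class, "parse_error")
})

test_that("standardized InChIs never carry the removed layers", {
  smi <- baseLibrary()$smiles[seq(2, 170, by = 17)]
  inchis <- smilesToStdInchi(smi)$inchi
  stereo_u <- applyFicts(inchis, "FICTu")
  expect_true(all(stereo_u$ok))
  expect_false(any(grepl("/[tmsb]", stereo_u$inchi)))
  iso <- smilesToStdInchi(c(SMILES$ethanol_d3, "[13CH3]CO"))$inchi
  iso_u <- applyFicts(iso, "FuCTS")
  expect_false(any(grepl("/i", iso_u$inchi, fixed = TRUE)))
})

test_that("equal InChIs under one variant stay equal under supersets", {
  # equivalence merging is monotone: standardisation is a function, so
  # once two structures collapse they cannot separate again
  pairs <- list(c(SMILES$l_alanine, SMILES$d_alanine),
                c(SMILES$acac_keto, SMILES$acac_enol),
                c(SMILES$sodium_acetate, SMILES$acetate))
  heal_variant <- c("FICTu", "FICuS", "uIuTS")
  supersets <- c("uuCTu", "uICuu", "uuuuu")
  for (k in seq_along(pairs)) {
    i2 <- smilesToStdInchi(pairs[[k]])$inchi
    base <- applyFicts(i2, heal_variant[k])
    expect_identical(base$inchi[1], base$inchi[2])
    more <- applyFicts(i2, supersets[k])
    expect_identical(more$inchi[1], more$inchi[2])
  }
})
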