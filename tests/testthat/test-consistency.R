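# Within-database audit semantics.

test_that("an identity database scores 100% in every cell", {
  smi <- baseLibrary()$smiles[1:6]
  ich <- smilesToStdInchi(smi)$inchi
  db <- makeSnapshot(smi, source = "ident", smiles_channel = smi,
                     inchi_channel = ich)
  rep <- auditWithin(db, c("FICTS", "FICTu"),
                     resolver = makeLookupResolver(
                       data.frame(name = character(), smiles = character())))
  cl <- cells(rep)
  live <- cl[cl$channel %in% c("smiles", "inchi"), ]
  expect_true(all(live$agreement_pct == 100))
  expect_true(all(live$n_compared == 6L))
  # absent iupac channel: no denominators, agreement undefined
  expect_true(all(is.na(cl$agreement_pct[cl$channel == "iupac"])))
})

test_that("stereo-flipped SMILES depress the baseline and heal under FICTu", {
  # 10 records; records 3 and 7 carry the enantiomer in the SMILES channel
  lib <- baseLibrary()
  chiral <- c("l-alanine", "l-leucine", "l-valine", "l-serine",
              "l-threonine", "l-methionine", "l-proline", "naproxen",
              "l-phenylalanine", "l-tryptophan")
  smi <- lib$smiles[match(chiral, lib$name)]
  flip <- function(s) {
    # invert every tetrahedral tag: the enantiomer
    tmp <- gsub("[C@@H]", "\x02", s, fixed = TRUE)
    tmp <- gsub("[C@H]", "[C@@H]", tmp, fixed = TRUE)
    gsub("\x02", "[C@H]", tmp, fixed = TRUE)
  }
  channel <- smi
  channel[c(3, 7)] <- flip(smi[c(3, 7)])
  db <- makeSnapshot(smi, source = "flip", smiles_channel = channel)
  rep <- auditWithin(db, c("FICTS", "FICTu"))
  cl <- cells(rep)
  pick <- function(v) cl[cl$channel == "smiles" & cl$variant == v, ]
  expect_identical(pick("FICTS")$n_compared, 10L)
  expect_identical(pick("FICTS")$n_matched, 8L)
  expect_equal(pick("FICTS")$agreement_pct, 80)
  expect_identical(pick("FICTu")$n_matched, 10L)
  expect_equal(pick("FICTu")$agreement_pct, 100)
})

test_that("records failing conversion are excluded but still counted as attempted", {
  smi <- c(SMILES$ethanol, SMILES$benzene)
  db <- databaseSnapshot("qa", data.frame(
    record_id = c("Q1", "Q2", "Q3"),
    mol_block = c(molBlockFromSmiles(smi), queryAtomMolBlock()),
    smiles = c("CCO", "c1ccccc1", "CCC"),
    inchi = NA_character_, iupac_name = NA_character_,
    stringsAsFactors = FALSE))
  rep <- auditWithin(db, "FICTS")
  cv <- conversionStats(rep)
  expect_identical(cv$attempted[cv$channel == "mol"], 3L)
  expect_identical(cv$succeeded[cv$channel == "mol"], 2L)
  cl <- cells(rep)
  expect_identical(cl$n_compared[cl$channel == "smiles" &
                                   cl$variant == "FICTS"], 2L)
  vd <- verdicts(rep)
  q3 <- vd[vd$record_id == "Q3" & vd$channel == "smiles", ]
  expect_identical(q3$status, "excluded")
  expect_identical(q3$reason, "mol_conversion_failed:query_atom")
})

test_that("the brute-force counting oracle handles the stated cases", {
  expect_identical(bruteForceAgreement(c("a", "a", NA), c("a", "b", "a")),
                   c(n_compared = 2L, n_matched = 1L))
  expect_identical(bruteForceAgreement(character(), character()),
                   c(n_compared = 0L, n_matched = 0L))
  set.seed(42)
  a <- sample(c(letters[1:3], NA), 1000, replace = TRUE)
  b <- sample(c(letters[1:3], NA), 1000, replace = TRUE)
  both <- !is.na(a) & !is.na(b)
  expect_identical(unname(bruteForceAgreement(a, b)),
                   c(sum(both), sum(a[both] == b[both])))
})

test_that("audit aggregation equals the brute-force oracle per cell", {
  st <- defaultStudy()
  rep <- auditWithin(dbA(st), c("FICTS", "FICTu"),
                     resolver = nameResolver(st))
  r <- records(dbA(st))
  mol_i <- molToStdInchi(r$mol_block)$inchi
  for (v in c("FICTS", "FICTu")) {
    mol_s <- applyFicts(mol_i, v)$inchi
    for (ch in c("smiles", "inchi")) {
      raw <- if (ch == "smiles") smilesToStdInchi(r$smiles)
             else inchiToStdInchi(r$inchi)
      ch_s <- applyFicts(raw$inchi, v)$inchi
      oracle <- bruteForceAgreement(mol_s, ch_s)
      cl <- cells(rep)
      cell <- cl[cl$channel == ch & cl$variant == v, ]
      expect_identical(cell$n_compared, unname(oracle["n_compared"]))
      expect_identical(cell$n_matched, unname(oracle["n_matched"]))
    }
  }
})

test_that("corrupting one channel leaves the other channels' cells unchanged", {
  st <- defaultStudy()
  db <- dbA(st)
  r <- records(db)
  r$smiles <- "C1CC"  # destroy the whole SMILES channel
  db2 <- databaseSnapshot("synthA", r, xrefs = xrefs(db))
  res <- nameResolver(st)
  c1 <- cells(auditWithin(db, c("FICTS", "FICTu"), resolver = res))
  c2 <- cells(auditWithin(db2, c("FICTS", "FICTu"), resolver = res))
  keep <- c1$channel != "smiles"
  expect_identical(c1[keep, ], c2[keep, ])
  expect_identical(c2$n_compared[c2$channel == "smiles"], rep(0L, 2))
})

test_that("denominators follow the exclusion law", {
  st <- defaultStudy()
  rep <- auditWithin(dbA(st), c("FICTS", "uuuuu"),
                     resolver = nameResolver(st))
  cv <- conversionStats(rep)
  cl <- cells(rep)
  vd <- verdicts(rep)
  for (v in unique(cl$variant)) for (ch in unique(cl$channel)) {
    sub <- vd[vd$channel == ch & vd$variant == v, ]
    # every record appears exactly once per channel and variant
    expect_identical(nrow(sub), length(dbA(st)))
    expect_identical(anyDuplicated(sub$record_id), 0L)
    n_comp <- cl$n_compared[cl$channel == ch & cl$variant == v]
    attempted <- cv$attempted[cv$channel == ch]
    conv_fail <- sum(grepl("conversion_failed", sub$reason))
    std_fail <- sum(grepl("standardisation_failed", sub$reason))
    expect_identical(n_comp, attempted - conv_fail - std_fail)
  }
})

test_that("mismatch diagnostics name the first differing InChI layer", {
  expect_identical(firstDiffLayer(INCHI$l_alanine, INCHI$d_alanine), "m")
  expect_identical(firstDiffLayer(INCHI$ethanol, INCHI$ethanol_d3), "i")
  expect_identical(firstDiffLayer(INCHI$ethanol, INCHI$ethanol),
                   NA_character_)
  expect_identical(firstDiffLayer(INCHI$acetic_acid, INCHI$acetate), "p")
  db <- makeSnapshot(SMILES$l_alanine, source = "diag",
                     smiles_channel = SMILES$d_alanine)
  rep <- auditWithin(db, "FICTS", diagnose = TRUE)
  vd <- verdicts(rep)
  expect_identical(vd$first_diff_layer[vd$channel == "smiles" &
                                         vd$variant == "FICTS"], "m")
})
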