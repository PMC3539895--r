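# SDF ingestion and channel-to-Standard-InChI conversion.

test_that("readSDF keeps entries with MOL blocks, drops and counts the rest", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeFixtureSDF(list(
    list(mol_block = molBlock(SMILES$ethanol),
         tags = list(ID = "R1", SMILES = "CCO")),
    list(mol_block = "",  # blank connection table: no structure
         tags = list(ID = "R2")),
    list(mol_block = molBlock(SMILES$benzene),
         tags = list(ID = "R3", XREFS = "ChEBI:1234 ChEBI:99"))), path)
  db <- readSDF(path, sourceName = "toy")
  expect_s4_class(db, "DatabaseSnapshot")
  expect_identical(length(db), 2L)
  expect_identical(records(db)$record_id, c("R1", "R3"))
  expect_identical(loadLog(db)$n_dropped_no_molblock, 1L)
  expect_identical(loadLog(db)$n_entries, 3L)
  # MOL block round-trips verbatim
  expect_identical(records(db)$mol_block[1], molBlock(SMILES$ethanol))
  # one record may carry several xrefs to the same target source
  xr <- xrefs(db)
  expect_identical(xr$record_id, c("R3", "R3"))
  expect_identical(xr$target_source, c("ChEBI", "ChEBI"))
  expect_identical(xr$target_id, c("1234", "99"))
})

test_that("an empty SDF yields an empty snapshot without error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(), path)
  db <- readSDF(path, sourceName = "empty")
  expect_identical(length(db), 0L)
  expect_identical(loadLog(db)$n_entries, 0L)
})

test_that("snapshots survive an SDF write/read round trip", {
  db <- makeSnapshot(c(SMILES$l_alanine, SMILES$sodium_acetate),
                     source = "rt", smiles_channel = c("C[C@H](N)C(=O)O", NA),
                     names_channel = c("l-alanine", NA))
  path <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(db, path)
  back <- readSDF(path, sourceName = "rt")
  expect_identical(records(back)$mol_block, records(db)$mol_block)
  expect_identical(records(back)$smiles, records(db)$smiles)
  expect_identical(records(back)$iupac_name, records(db)$iupac_name)
})

test_that("sidecar channel tables fill channels, first value winning", {
  db <- makeSnapshot(c(SMILES$ethanol, SMILES$benzene), source = "sc",
                     ids = c("S1", "S2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\tchannel\tvalue",
               "S1\tsmiles\tCCO", "S1\tsmiles\tOCC",
               "S2\tiupac_name\tbenzene", "S9\tsmiles\tCC"), path)
  db2 <- readChannelTable(db, path)
  expect_identical(records(db2)$smiles, c("CCO", NA))
  expect_identical(records(db2)$iupac_name, c(NA, "benzene"))
})

test_that("MOL conversion matches the reference InChI and classifies failures", {
  res <- molToStdInchi(c(molBlock(SMILES$ethanol), queryAtomMolBlock(),
                         "not a mol block", NA))
  expect_identical(res$inchi[1], INCHI$ethanol)
  expect_true(startsWith(res$inchi[1], "InChI=1S/"))
  expect_identical(res$failure_class[2], "query_atom")
  expect_identical(res$failure_class[3], "parse_error")
  expect_identical(res$failure_class[4], "empty_structure")
  # exactly one of inchi / failure_class per row
  expect_true(all(xor(is.na(res$inchi), is.na(res$failure_class))))
  # V3000 connection tables are out of scope and rejected
  v3 <- sub("V2000", "V3000", molBlock(SMILES$ethanol))
  expect_identical(molToStdInchi(v3)$failure_class, "parse_error")
})

test_that("ethanol InChI agrees with the independent OpenBabel oracle", {
  skip_if(Sys.which("obabel") == "", "obabel not on PATH")
  ob <- suppressWarnings(system2("obabel", c("-:CCO", "-oinchi"),
                                 stdout = TRUE, stderr = FALSE))
  ob <- trimws(ob[startsWith(ob, "InChI=")][1])
  expect_identical(smilesToStdInchi("CCO")$inchi, ob)
})

test_that("SMILES flavours collapse to one InChI; invalid SMILES classified", {
  res <- smilesToStdInchi(c("CCO", "OCC", "C1CC"))
  expect_identical(res$inchi[1], INCHI$ethanol)
  expect_identical(res$inchi[1], res$inchi[2])
  expect_identical(res$failure_class[3], "parse_error")
})

test_that("InChI channel normalisation is a fixed point on Standard InChI", {
  res <- inchiToStdInchi(c(INCHI$ethanol,
                           "InChI=1/C2H6O/c1-2-3/h3H,2H2,1H3",  # non-standard
                           "InChI=banana", "banana"))
  expect_identical(res$inchi[1], INCHI$ethanol)   # identity
  expect_identical(res$inchi[2], INCHI$ethanol)   # normalised
  expect_identical(res$failure_class[3], "parse_error")
  expect_identical(res$failure_class[4], "parse_error")
})

test_that("name resolution is a pluggable lookup with classified failures", {
  res <- nameToStdInchi(c("ethanol", "unobtainium"))
  expect_identical(res$inchi[1], INCHI$ethanol)
  expect_identical(res$failure_class[2], "name_unresolvable")
  # stereo carried through the resolver: chiral fixture keeps its /t layer
  chiral <- nameToStdInchi("d-alanine")
  expect_identical(chiral$inchi, INCHI$d_alanine)
  expect_match(chiral$inchi, "/t", fixed = TRUE)
  # crashing resolver: failure class 'other', no error escapes
  boom <- function(names) stop("resolver exploded")
  expect_warning(res2 <- nameToStdInchi("ethanol", boom), "resolver")
  expect_identical(res2$failure_class, "other")
})

test_that("converters are deterministic and channel-coherent", {
  mols <- utils::head(baseLibrary(), 8)
  mb <- molBlockFromSmiles(mols$smiles)
  via_mol <- molToStdInchi(mb)
  via_mol2 <- molToStdInchi(mb)
  expect_identical(via_mol, via_mol2)
  via_smiles <- smilesToStdInchi(mols$smiles)
  expect_true(all(via_mol$ok) && all(via_smiles$ok))
  # mol and smiles routes for the same structures give identical InChI
  expect_identical(via_mol$inchi, via_smiles$inchi)
  # and normalising those InChIs is idempotent
  expect_identical(inchiToStdInchi(via_smiles$inchi)$inchi, via_smiles$inchi)
})
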