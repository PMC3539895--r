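# Shared fixtures. Expected InChI values were computed with the reference
# IUPAC InChI implementation ahead of time and are frozen here; the
# ethanol value is additionally cross-checked against OpenBabel at test
# time where the obabel binary is available.

INCHI <- list(
  ethanol       = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
  ethanol_d3    = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3/i1D3",
  acetic_acid   = "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)",
  acetate       = "InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)/p-1",
  glycine       = "InChI=1S/C2H5NO2/c3-1-2(4)5/h1,3H2,(H,4,5)",
  l_alanine     = "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m0/s1",
  d_alanine     = "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m1/s1",
  alanine_flat  = "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)",
  pyridone      = "InChI=1S/C5H5NO/c7-5-3-1-2-4-6-5/h1-4H,(H,6,7)",
  glucose_flat  = "InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2",
  butene_flat   = "InChI=1S/C4H8/c1-3-4-2/h3-4H,1-2H3",
  lactic_flat   = "InChI=1S/C3H6O3/c1-2(4)3(5)6/h2,4H,1H3,(H,5,6)"
)

SMILES <- list(
  ethanol = "CCO", benzene = "c1ccccc1",
  l_alanine = "C[C@H](N)C(=O)O", d_alanine = "C[C@@H](N)C(=O)O",
  sodium_acetate = "CC(=O)[O-].[Na+]", acetate = "CC(=O)[O-]",
  glycine_zwitterion = "C(C(=O)[O-])[NH3+]",
  tma = "C[N+](C)(C)C",
  hydroxypyridine = "Oc1ccccn1", pyridone = "O=c1cccc[nH]1",
  acac_keto = "CC(=O)CC(C)=O", acac_enol = "CC(O)=CC(C)=O",
  neopentane = "CC(C)(C)C",
  e_butene = "C/C=C/C", z_butene = "C/C=C\\C",
  d_glucose = "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",
  sodium_l_lactate = "C[C@H](O)C(=O)[O-].[Na+]",
  ethanol_d3 = "[2H]C([2H])([2H])CO"
)

# session cache so expensive fixtures (MOL blocks, generated studies) are
# built once across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

molBlock <- function(smiles) {
  key <- paste0("mb:", smiles)
  cached(key, molBlockFromSmiles(smiles))
}

# write an SDF file from (mol_block, tag list) entries; entries with
# mol_block = "" get a blank 0-atom connection table
writeFixtureSDF <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    if (nzchar(e$mol_block)) writeLines(e$mol_block, con)
    else writeLines(c("", "", "",
                      "  0  0  0  0  0  0  0  0  0  0999 V2000",
                      "M  END"), con)
    for (tag in names(e$tags))
      writeLines(c(paste0(">  <", tag, ">"), e$tags[[tag]], ""), con)
    writeLines("$$$$", con)
  }
  path
}

# a small snapshot built in code: n records of one molecule per row
makeSnapshot <- function(smiles, source = "test", smiles_channel = NULL,
                         inchi_channel = NULL, names_channel = NULL,
                         ids = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- sprintf("%s%03d", toupper(substr(source, 1, 1)), seq_len(n))
  databaseSnapshot(source, data.frame(
    record_id = ids, mol_block = molBlockFromSmiles(smiles),
    smiles = if (is.null(smiles_channel)) NA_character_ else smiles_channel,
    inchi = if (is.null(inchi_channel)) NA_character_ else inchi_channel,
    iupac_name = if (is.null(names_channel)) NA_character_ else names_channel,
    stringsAsFactors = FALSE))
}

defaultStudy <- function() {
  cached("study_default",
         generateSyntheticPair(injectionSpec(nRecords = 40, seed = 11)))
}

# MOL block containing a "*" query atom (wildcard attachment point)
queryAtomMolBlock <- function() {
  cached("mb:query", molBlockFromSmiles("*CC"))
}
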