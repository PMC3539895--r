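# Self-verifying synthetic database generator. Each record's MOL block is
# the reference truth; affected identifier channels carry a corruption of
# a known class whose contract (which single FICTS u-rule heals it, and
# that no other single u-rule does) is verified at generation time by the
# chemistry helper against the same standardisation operators the audit
# uses. A base molecule lacking the feature a class needs (e.g. no
# defined stereocentre for a stereo flip) is resampled, never silently
# emitted clean while labelled corrupted.

#' The packaged base molecule library
#'
#' A curated library of drug-like small molecules (drugs, metabolites,
#' amino acids, natural products) as canonical SMILES, covering defined
#' stereocentres, ionisable groups, tautomer-capable motifs and
#' salt-formable acids and bases. The synthetic generator draws its
#' records from this library.
#'
#' @return data.frame with columns \code{name} and \code{smiles}.
#' @export
baseLibrary <- function() {
  utils::read.delim(baseLibraryPath(), stringsAsFactors = FALSE)
}

baseLibraryPath <- function() {
  system.file("extdata", "base_library.tsv", package = "molconsist",
              mustWork = TRUE)
}

#' Construct a synthetic corruption specification
#'
#' Defaults emulate the error structure observed in public small-molecule
#' databases: stereochemistry discrepancies dominant, tautomer
#' discrepancies second, salt/charge/isotope discrepancies minor, plus a
#' small admixture of outright wrong compounds and unconvertible strings.
#'
#' @param nRecords records per snapshot.
#' @param rates named per-record-channel class probabilities; unnamed
#'   classes default to 0. See [InjectionSpec-class].
#' @param channels identifier channels eligible for corruption.
#' @param pBadEdge,pMulti,multiMax cross-reference error structure, see
#'   [InjectionSpec-class].
#' @param seed integer seed; fully determines the generated study.
#' @return an [InjectionSpec-class].
#' @export
injectionSpec <- function(nRecords = 500,
                          rates = c(stereo = 0.10, tautomer = 0.05,
                                    fragment_salt = 0.02, charge = 0.02,
                                    isotope = 0.01, wrong_compound = 0.02,
                                    unconvertible = 0.01),
                          channels = c("smiles", "inchi", "iupac"),
                          pBadEdge = 0.10, pMulti = 0.10, multiMax = 5,
                          seed = 1L) {
  full <- stats::setNames(numeric(length(.INJECTION_CLASSES)),
                          .INJECTION_CLASSES)
  full[names(rates)] <- rates
  new("InjectionSpec", nRecords = as.integer(nRecords), rates = full,
      channels = channels, pBadEdge = pBadEdge, pMulti = pMulti,
      multiMax = as.integer(multiMax), seed = as.integer(seed))
}

#' Generate a pair of synthetic database snapshots with known errors
#'
#' Builds snapshot A (identifier channels corrupted per the spec's class
#' rates) and snapshot B (clean copies of the same structures), linked by
#' cross-reference edges of which a fraction are retargeted to
#' structurally different compounds and a fraction of compounds carry
#' multiple edges with exactly one correct. Every emitted corruption is
#' verified at generation time to satisfy its class contract; the same
#' seed yields byte-identical output.
#'
#' @param spec an [InjectionSpec-class].
#' @return a [SyntheticStudy-class].
#' @seealso [writeSyntheticStudy()] to materialise a.sdf / b.sdf /
#'   edges.tsv / truth.tsv.
#' @export
generateSyntheticPair <- function(spec = injectionSpec()) {
  stopifnot(is(spec, "InjectionSpec"))
  validObject(spec)
  lib <- baseLibrary()
  n <- spec@nRecords
  withSeed(spec@seed, {
    ids_a <- sprintf("A%05d", seq_len(n))
    ids_b <- sprintf("B%05d", seq_len(n))
    base_idx <- sample.int(nrow(lib), n, replace = TRUE)
    probs <- c(spec@rates, clean = 1 - sum(spec@rates))
    drawClass <- function(ch) {
      if (!(ch %in% spec@channels)) return(rep("clean", n))
      sample(names(probs), n, replace = TRUE, prob = probs)
    }
    cls <- data.frame(smiles = drawClass("smiles"),
                      inchi = drawClass("inchi"),
                      iupac = drawClass("iupac"), stringsAsFactors = FALSE)
    seeds <- sample.int(.Machine$integer.max - 1L, n)

    m <- runChemTool("mkrecord",
                     input = data.frame(id = ids_a, base = base_idx - 1L,
                                        cs = cls$smiles, ci = cls$inchi,
                                        cn = cls$iupac, seed = seeds),
                     args = c("--library", baseLibraryPath()), min_cols = 9L)
    if (any(m[, 2] != "1"))
      stop("synthetic generator could not satisfy a class contract for ",
           sum(m[, 2] != "1"), " record(s)")
    final_idx <- as.integer(m[, 3]) + 1L
    mol_blocks <- m[, 4]
    allu <- m[, 6]
    names_a <- paste0("name-", ids_a)
    rec_a <- data.frame(
      record_id = ids_a, mol_block = mol_blocks, smiles = m[, 7],
      inchi = m[, 8],
      iupac_name = names_a, stringsAsFactors = FALSE)
    # name lookup: corrupted-iupac records resolve to the corrupted
    # structure; unconvertible-iupac names are simply absent from the table
    name_rows <- cls$iupac != "unconvertible"
    nameTable <- data.frame(name = names_a[name_rows],
                            smiles = m[name_rows, 9],
                            stringsAsFactors = FALSE)
    rec_b <- data.frame(
      record_id = ids_b, mol_block = mol_blocks,
      smiles = lib$smiles[final_idx], inchi = m[, 5],
      iupac_name = lib$name[final_idx], stringsAsFactors = FALSE)
    nameTable <- rbind(nameTable,
                       data.frame(name = unique(lib$name[final_idx]),
                                  smiles = lib$smiles[
                                    match(unique(lib$name[final_idx]),
                                          lib$name)],
                                  stringsAsFactors = FALSE))

    # ---- cross-reference edges
    is_multi <- stats::runif(n) < spec@pMulti
    is_bad <- !is_multi & stats::runif(n) < spec@pBadEdge
    edge_from <- list(); edge_to <- list(); edge_good <- list()
    pickWrong <- function(i, k) {
      # target records holding a structurally different compound
      cand <- which(allu != allu[i])
      cand[sample.int(length(cand), min(k, length(cand)))]
    }
    for (i in seq_len(n)) {
      if (is_bad[i]) {
        to <- ids_b[pickWrong(i, 1L)]
        good <- FALSE
      } else if (is_multi[i]) {
        k <- sample(spec@multiMax - 1L, 1L)
        to <- c(ids_b[i], ids_b[pickWrong(i, k)])
        good <- c(TRUE, rep(FALSE, length(to) - 1L))
      } else {
        to <- ids_b[i]; good <- TRUE
      }
      edge_from[[i]] <- rep(ids_a[i], length(to))
      edge_to[[i]] <- to; edge_good[[i]] <- good
    }
    edges <- data.frame(from_source = "synthA",
                        from_id = unlist(edge_from), to_source = "synthB",
                        to_id = unlist(edge_to), stringsAsFactors = FALSE)
    truth <- new("GroundTruth",
                 channelLabels = data.frame(
                   record_id = rep(ids_a, 3L),
                   channel = rep(c("smiles", "inchi", "iupac"), each = n),
                   class = c(cls$smiles, cls$inchi, cls$iupac),
                   stringsAsFactors = FALSE),
                 edgeLabels = data.frame(from_id = unlist(edge_from),
                                         to_id = unlist(edge_to),
                                         good = unlist(edge_good),
                                         stringsAsFactors = FALSE))
    dbA <- databaseSnapshot("synthA", rec_a,
                            xrefs = data.frame(record_id = edges$from_id,
                                               target_source = "synthB",
                                               target_id = edges$to_id,
                                               stringsAsFactors = FALSE))
    dbB <- databaseSnapshot("synthB", rec_b)
    new("SyntheticStudy", dbA = dbA, dbB = dbB, edges = edges,
        truth = truth, nameTable = nameTable, spec = spec)
  })
}

#' @rdname SyntheticStudy-class
#' @export
setMethod("dbA", "SyntheticStudy", function(object) object@dbA)

#' @rdname SyntheticStudy-class
#' @export
setMethod("dbB", "SyntheticStudy", function(object) object@dbB)

#' @rdname SyntheticStudy-class
#' @export
setMethod("edges", "SyntheticStudy", function(object) object@edges)

#' @rdname SyntheticStudy-class
#' @export
setMethod("groundTruth", "SyntheticStudy", function(object) object@truth)

#' @rdname SyntheticStudy-class
#' @export
setMethod("nameTable", "SyntheticStudy", function(object) object@nameTable)

#' @rdname SyntheticStudy-class
#' @details `nameResolver` returns the fixture resolver backed by the
#'   study's name table, for use as the `resolver` argument of
#'   [auditWithin()].
#' @export
setMethod("nameResolver", "SyntheticStudy",
          function(object) makeLookupResolver(object@nameTable))

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy: ", length(object@dbA), " records per snapshot, ",
      nrow(object@edges), " cross-reference edges (seed ",
      object@spec@seed, ")\n", sep = "")
  tl <- object@truth@channelLabels
  tab <- table(tl$channel, tl$class)
  print(tab)
})

#' Write a synthetic study to disk
#'
#' Materialises \code{a.sdf}, \code{b.sdf}, \code{edges.tsv},
#' \code{truth.tsv} and \code{names.tsv} (the fixture name lookup) in a
#' directory. Deterministic: the same study writes byte-identical files.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSDF(dbA(study), file.path(dir, "a.sdf"))
  writeSDF(dbB(study), file.path(dir, "b.sdf"))
  writeTSV <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  writeTSV(edges(study), "edges.tsv")
  tr <- groundTruth(study)
  writeTSV(tr@channelLabels, "truth.tsv")
  writeTSV(tr@edgeLabels, "truth_edges.tsv")
  writeTSV(nameTable(study), "names.tsv")
  invisible(dir)
}
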