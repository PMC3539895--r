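#' @import methods
NULL

#' FICTS sensitivity flags
#'
#' The five FICTS standardisation switches: Fragment, Isotope, Charge,
#' Tautomer, Stereo. A \code{TRUE} slot marks that aspect as
#' \emph{insensitive} ("u" in the variant label): the corresponding
#' standardisation operator is applied before identifiers are compared.
#' The all-\code{FALSE} object is the fully sensitive baseline, labelled
#' \code{"FICTS"}; stereo-insensitive matching is \code{"FICTu"}.
#'
#' @slot fragment logical(1); strip all but the largest organic fragment.
#' @slot isotope logical(1); clear isotopic labels.
#' @slot charge logical(1); neutralise protonation-state charges.
#' @slot tautomer logical(1); replace by the canonical tautomer.
#' @slot stereo logical(1); remove stereochemistry.
#'
#' @seealso [fictsFlags()], [fictsLabel()], [parseFictsLabel()],
#'   [applyFicts()]
#' @export
setClass("FictsFlags", representation(
  fragment = "logical", isotope = "logical", charge = "logical",
  tautomer = "logical", stereo = "logical"))

setValidity("FictsFlags", function(object) {
  v <- c(object@fragment, object@isotope, object@charge,
         object@tautomer, object@stereo)
  if (length(v) != 5L || anyNA(v))
    return("all five flags must be non-NA scalar logicals")
  TRUE
})

#' A database snapshot of compound records
#'
#' One source database: per-record MOL blocks (verbatim MDL V2000 text, the
#' reference representation), the optional SMILES / InChI / IUPAC-name
#' identifier channels, and outgoing cross-references.
#'
#' @slot sourceName single string naming the database.
#' @slot records data.frame with columns \code{record_id},
#'   \code{mol_block}, \code{smiles}, \code{inchi}, \code{iupac_name}
#'   (channels \code{NA} when absent). Record ids are unique.
#' @slot xrefs data.frame with columns \code{record_id},
#'   \code{target_source}, \code{target_id}; a record may carry several
#'   edges to the same target source.
#' @slot loadLog list of ingestion counters (entries seen, records kept,
#'   entries dropped for lacking a MOL block, malformed entries skipped).
#'
#' @seealso [readSDF()], [databaseSnapshot()], [auditWithin()]
#' @export
setClass("DatabaseSnapshot", representation(
  sourceName = "character", records = "data.frame",
  xrefs = "data.frame", loadLog = "list"))

setValidity("DatabaseSnapshot", function(object) {
  msg <- character()
  req <- c("record_id", "mol_block", "smiles", "inchi", "iupac_name")
  if (length(object@sourceName) != 1L || is.na(object@sourceName))
    msg <- c(msg, "sourceName must be a single string")
  if (!all(req %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:",
                        paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$record_id))
      msg <- c(msg, "record_id values must be unique")
    if (nrow(object@records) &&
        any(is.na(object@records$mol_block) |
            !nzchar(object@records$mol_block)))
      msg <- c(msg, "every retained record must have a non-empty mol_block")
  }
  xr <- c("record_id", "target_source", "target_id")
  if (!all(xr %in% names(object@xrefs)))
    msg <- c(msg, paste("xrefs must have columns:", paste(xr, collapse = ", ")))
  else if (nrow(object@xrefs) &&
           !all(object@xrefs$record_id %in% object@records$record_id))
    msg <- c(msg, "xrefs refer to unknown record_ids")
  if (length(msg)) msg else TRUE
})

#' Within-database consistency report
#'
#' Result of [auditWithin()]: per-channel conversion statistics, the
#' channel-by-variant agreement table (the within-database consistency
#' matrix), per-variant standardisation-failure counts, and the per-record
#' verdict table with exclusion reasons.
#'
#' @slot sourceName audited database name.
#' @slot conversion data.frame: \code{channel}, \code{attempted},
#'   \code{succeeded}, \code{pct} (\code{NA} when \code{attempted == 0}).
#' @slot cells data.frame: \code{channel}, \code{variant},
#'   \code{n_compared}, \code{n_matched}, \code{agreement_pct}.
#' @slot verdicts data.frame: \code{record_id}, \code{channel},
#'   \code{variant}, \code{status} (match / mismatch / excluded),
#'   \code{reason}, and \code{first_diff_layer} for mismatches.
#' @slot stdFailures data.frame of standardisation-failure counts per
#'   variant (failures on either side of a comparison).
#' @slot variants character vector of FICTS variant labels audited.
#' @slot toolkit structure-toolkit version string, for provenance.
#' @export
setClass("ConsistencyReport", representation(
  sourceName = "character", conversion = "data.frame", cells = "data.frame",
  verdicts = "data.frame", stdFailures = "data.frame",
  variants = "character", toolkit = "character"))

#' Between-database cross-reference report
#'
#' Result of [auditCross()]: structural agreement of MOL-derived Standard
#' InChIs across cross-reference edges under one FICTS variant, with the
#' single-versus-multiple cross-reference breakdown and multiplicity
#' statistics. Direction matters: the report covers edges from
#' \code{fromSource} to \code{toSource} only and is never symmetrised.
#'
#' @slot fromSource,toSource database names.
#' @slot variant FICTS variant label used for both sides.
#' @slot nEdgesTotal edges supplied (after de-duplication).
#' @slot nEdgesCompared edges where both MOL conversions and
#'   standardisations succeeded and the target resolved.
#' @slot nMatched edges whose standardized InChIs agree.
#' @slot agreementPct 100 * nMatched / nEdgesCompared (\code{NA} if none).
#' @slot nMultiCompounds source compounds with >= 2 edges.
#' @slot multiMean,multiMedian mean / median edge count among those.
#' @slot singleXrefAgreementPct agreement over source compounds having
#'   exactly one edge (\code{NA} when the subset is empty).
#' @slot nSingleCompared,nSingleMatched counts behind that subset.
#' @slot exclusions data.frame of per-reason exclusion counts.
#' @slot edgeVerdicts data.frame with one row per edge: \code{from_id},
#'   \code{to_id}, \code{status}, \code{reason}.
#' @export
setClass("XrefReport", representation(
  fromSource = "character", toSource = "character", variant = "character",
  nEdgesTotal = "integer", nEdgesCompared = "integer", nMatched = "integer",
  agreementPct = "numeric", nMultiCompounds = "integer",
  multiMean = "numeric", multiMedian = "numeric",
  singleXrefAgreementPct = "numeric", nSingleCompared = "integer",
  nSingleMatched = "integer", exclusions = "data.frame",
  edgeVerdicts = "data.frame"))

#' Synthetic corruption specification
#'
#' Parameters of the synthetic paired-database generator: how many records,
#' the per-record-channel probability of each injected inconsistency class,
#' which identifier channels may be corrupted, and the cross-reference
#' error structure. The classes are mutually exclusive per record-channel,
#' so their rates must sum to at most one. The seed fully determines the
#' output.
#'
#' @slot nRecords number of records in each snapshot.
#' @slot rates named numeric vector of class probabilities over
#'   \code{stereo}, \code{tautomer}, \code{fragment_salt}, \code{charge},
#'   \code{isotope}, \code{wrong_compound}, \code{unconvertible}.
#' @slot channels subset of \code{c("smiles", "inchi", "iupac")} eligible
#'   for corruption.
#' @slot pBadEdge probability that a (single-edge) compound's
#'   cross-reference is retargeted to a structurally different compound.
#' @slot pMulti probability that a compound carries 2..multiMax edges, of
#'   which exactly one is correct.
#' @slot multiMax maximum edges per multi-reference compound.
#' @slot seed integer seed.
#' @seealso [injectionSpec()], [generateSyntheticPair()]
#' @export
setClass("InjectionSpec", representation(
  nRecords = "integer", rates = "numeric", channels = "character",
  pBadEdge = "numeric", pMulti = "numeric", multiMax = "integer",
  seed = "integer"))

.INJECTION_CLASSES <- c("stereo", "tautomer", "fragment_salt", "charge",
                        "isotope", "wrong_compound", "unconvertible")

setValidity("InjectionSpec", function(object) {
  msg <- character()
  if (object@nRecords < 1L) msg <- c(msg, "nRecords must be >= 1")
  if (!all(names(object@rates) %in% .INJECTION_CLASSES))
    msg <- c(msg, paste("rates names must be among:",
                        paste(.INJECTION_CLASSES, collapse = ", ")))
  if (any(object@rates < 0 | object@rates > 1))
    msg <- c(msg, "rates must be probabilities in [0, 1]")
  if (sum(object@rates) > 1 + 1e-12)
    msg <- c(msg, "classes are exclusive per record-channel: rates must sum to <= 1")
  if (!all(object@channels %in% c("smiles", "inchi", "iupac")))
    msg <- c(msg, "channels must be a subset of smiles, inchi, iupac")
  if (object@pBadEdge < 0 || object@pBadEdge > 1 ||
      object@pMulti < 0 || object@pMulti > 1)
    msg <- c(msg, "pBadEdge and pMulti must be in [0, 1]")
  if (object@multiMax < 2L) msg <- c(msg, "multiMax must be >= 2")
  if (is.na(object@seed)) msg <- c(msg, "seed must be a non-NA integer")
  if (length(msg)) msg else TRUE
})

#' Ground truth of an injected synthetic study
#'
#' Per record-channel injected-class labels and per-edge good/bad labels
#' emitted by [generateSyntheticPair()], for recovery testing.
#'
#' @slot channelLabels data.frame: \code{record_id}, \code{channel},
#'   \code{class} (\code{"clean"} or an injection class).
#' @slot edgeLabels data.frame: \code{from_id}, \code{to_id}, \code{good}
#'   (logical).
#' @export
setClass("GroundTruth", representation(
  channelLabels = "data.frame", edgeLabels = "data.frame"))

#' A generated pair of synthetic database snapshots
#'
#' Output of [generateSyntheticPair()]: two snapshots linked by
#' cross-reference edges, the ground-truth labels, the name-channel lookup
#' table, and the generating [InjectionSpec-class].
#'
#' @slot dbA,dbB the two [DatabaseSnapshot-class] objects; corruption is
#'   injected into dbA's identifier channels, dbB holds clean copies.
#' @slot edges data.frame of cross-reference edges (\code{from_source},
#'   \code{from_id}, \code{to_source}, \code{to_id}).
#' @slot truth [GroundTruth-class] labels.
#' @slot nameTable data.frame (\code{name}, \code{smiles}) backing the
#'   fixture name resolver for the IUPAC-name channel.
#' @slot spec the generating [InjectionSpec-class].
#' @export
setClass("SyntheticStudy", representation(
  dbA = "DatabaseSnapshot", dbB = "DatabaseSnapshot", edges = "data.frame",
  truth = "GroundTruth", nameTable = "data.frame", spec = "InjectionSpec"))
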