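# The five FICTS standardisation operators and their composition.
# Each operator works at structure level: the identifier is parsed, the
# structure edited, and the Standard InChI (or canonical SMILES for the
# single-operator helpers) regenerated. Composition order is fixed
# F -> I -> C -> T -> S: fragment stripping first so counterions cannot
# influence the charge and tautomer steps, stereo removal last because
# tautomer moves can create or destroy stereocentres.

applyOp <- function(op, smiles) {
  out <- rep(NA_character_, length(smiles))
  todo <- !is.na(smiles) & nzchar(smiles)
  if (any(todo)) {
    m <- runChemTool("op",
                     input = data.frame(id = which(todo), smiles = smiles[todo]),
                     args = c("--op", op), min_cols = 4L)
    ok <- m[, 2] == "1"
    out[todo][ok] <- m[ok, 4]
    if (any(!ok))
      warning(sum(!ok), " structure(s) failed operator ", op, ": ",
              paste(unique(m[!ok, 3]), collapse = ", "))
  }
  out
}

#' FICTS standardisation operators
#'
#' Single structure-level standardisation steps, each taking and returning
#' SMILES (canonical form; \code{NA} on failure, with a warning). All five
#' are idempotent and deterministic.
#'
#' \describe{
#'   \item{`stripFragments` (F)}{keep only the connected fragment with the
#'     most heavy atoms; ties broken by the lexicographically smaller
#'     Standard InChI. Single-fragment input is returned unchanged.}
#'   \item{`clearIsotopes` (I)}{remove every atom's isotope designation;
#'     the output's InChI carries no \code{/i} layer.}
#'   \item{`neutralizeCharges` (C)}{neutralise protonation-state charges
#'     by adding/removing protons (carboxylates, protonated amines,
#'     alkoxides, ...); permanent charges without a proton site
#'     (e.g. quaternary ammonium) are retained.}
#'   \item{`canonicalTautomer` (T)}{replace the structure by a
#'     deterministic canonical tautomer (RDKit's scoring-rule
#'     canonicaliser, version reported by [toolkitVersion()]); all
#'     enumerable tautomers of a molecule map to the same output. If the
#'     enumeration cap is hit the input is returned unchanged and the
#'     event is counted in reports.}
#'   \item{`stripStereo` (S)}{remove all tetrahedral and double-bond
#'     stereo; the output's InChI has no \code{/t}, \code{/m}, \code{/s}
#'     or \code{/b} layers.}
#' }
#'
#' @param smiles character vector of SMILES.
#' @return character vector of standardised canonical SMILES.
#' @examples \dontrun{
#' stripFragments("CC(=O)[O-].[Na+]")   # acetate fragment retained
#' neutralizeCharges("CC(=O)[O-]")      # acetic acid
#' canonicalTautomer("CC(O)=CC(C)=O")   # keto form of acetylacetone
#' }
#' @export
stripFragments <- function(smiles) applyOp("F", smiles)

#' @rdname stripFragments
#' @export
clearIsotopes <- function(smiles) applyOp("I", smiles)

#' @rdname stripFragments
#' @export
neutralizeCharges <- function(smiles) applyOp("C", smiles)

#' @rdname stripFragments
#' @export
canonicalTautomer <- function(smiles) applyOp("T", smiles)

#' @rdname stripFragments
#' @export
stripStereo <- function(smiles) applyOp("S", smiles)

#' Apply a FICTS variant to Standard InChI strings
#'
#' Parses each Standard InChI, applies the enabled operators in the fixed
#' order F, I, C, T, S, and regenerates the Standard InChI. The all-false
#' baseline (\code{"FICTS"}) is the identity. Idempotent for every flag
#' combination.
#'
#' @param inchi character vector of Standard InChI strings.
#' @param flags a [FictsFlags-class], a variant label such as
#'   \code{"FICTu"}, or anything [parseFictsLabel()] accepts.
#' @return data.frame with columns \code{input} (the provenance InChI),
#'   \code{variant}, \code{ok}, \code{inchi} (standardised; equals
#'   \code{input} under the baseline), \code{failure_class}, \code{note}
#'   (\code{"tautomer_cap"} when the tautomer enumeration cap was hit and
#'   the structure passed through unchanged).
#' @examples \dontrun{
#' applyFicts("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", "uuuuu")
#' }
#' @export
applyFicts <- function(inchi, flags = fictsFlags()) {
  label <- unname(normalizeVariants(flags))
  if (length(label) != 1L) stop("applyFicts takes a single variant")
  n <- length(inchi)
  out <- data.frame(input = unname(inchi), variant = label, ok = rep(FALSE, n),
                    inchi = NA_character_, failure_class = "empty_structure",
                    note = NA_character_, stringsAsFactors = FALSE)
  todo <- !is.na(inchi) & nzchar(inchi)
  if (any(todo)) {
    m <- runChemTool("pipeline",
                     input = data.frame(id = which(todo), kind = "inchi",
                                        value = inchi[todo]),
                     args = c("--variants", label), min_cols = 8L)
    conv_ok <- m[, 2] == "1"
    std_ok <- conv_ok & m[, 5] == "1"
    out$ok[todo] <- std_ok
    out$inchi[todo] <- ifelse(std_ok, m[, 7], NA_character_)
    out$failure_class[todo] <- ifelse(std_ok, NA_character_,
                                      ifelse(conv_ok, m[, 6], m[, 3]))
    out$note[todo] <- ifelse(nzchar(m[, 8]), m[, 8], NA_character_)
  }
  out
}

# split an InChI into named layers; layer "formula" then prefixed layers
inchiLayers <- function(inchi) {
  body <- sub("^InChI=1S?/", "", inchi)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  nm <- c("formula", substring(parts[-1], 1L, 1L))
  names(parts) <- nm
  parts
}

#' First differing InChI layer of a mismatching pair
#'
#' Read-only curation diagnostic: names the first layer (formula, c, h, q,
#' p, b, t, m, s, i, ...) at which two Standard InChIs disagree.
#'
#' @param a,b Standard InChI strings.
#' @return character vector of layer names (\code{NA} where equal or
#'   either side is \code{NA}).
#' @export
firstDiffLayer <- function(a, b) {
  mapply(function(x, y) {
    if (is.na(x) || is.na(y) || x == y) return(NA_character_)
    la <- inchiLayers(x); lb <- inchiLayers(y)
    keys <- union(names(la), names(lb))
    for (k in keys) {
      va <- la[k]; vb <- lb[k]
      if (is.na(va) || is.na(vb) || va != vb) return(k)
    }
    "none"
  }, a, b, USE.NAMES = FALSE)
}
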