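# SDF ingestion and identifier-channel conversion to Standard InChI.
# MOL blocks are kept byte-for-byte as read: the audit treats the MOL
# block as the reference representation and hands it verbatim to the
# InChI generator, so no re-serialisation is allowed to touch it.

.CHANNELS <- c("mol", "inchi", "smiles", "iupac")
.FAILURE_CLASSES <- c("query_atom", "parse_error", "name_unresolvable",
                      "empty_structure", "other")

#' Default SD-tag mapping
#'
#' Which SD data tags hold each identifier channel when reading an SDF.
#' Override any element in [readSDF()] for other tag dialects.
#'
#' @return named list with elements \code{record_id}, \code{smiles},
#'   \code{inchi}, \code{iupac_name}, \code{xrefs}.
#' @export
defaultTagMap <- function() {
  list(record_id = "ID", smiles = "SMILES", inchi = "INCHI",
       iupac_name = "IUPAC_NAME", xrefs = "XREFS")
}

#' Construct a database snapshot from parts
#'
#' @param sourceName database name.
#' @param records data.frame with \code{record_id} and \code{mol_block};
#'   missing channel columns are filled with \code{NA}.
#' @param xrefs optional data.frame (\code{record_id},
#'   \code{target_source}, \code{target_id}).
#' @param loadLog optional list of ingestion counters.
#' @return a [DatabaseSnapshot-class].
#' @export
databaseSnapshot <- function(sourceName, records,
                             xrefs = NULL, loadLog = list()) {
  for (col in c("smiles", "inchi", "iupac_name"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  records <- records[c("record_id", "mol_block", "smiles", "inchi",
                       "iupac_name")]
  rownames(records) <- NULL
  if (is.null(xrefs))
    xrefs <- data.frame(record_id = character(), target_source = character(),
                        target_id = character(), stringsAsFactors = FALSE)
  new("DatabaseSnapshot", sourceName = sourceName, records = records,
      xrefs = xrefs, loadLog = loadLog)
}

#' @rdname DatabaseSnapshot-class
#' @export
setMethod("sourceName", "DatabaseSnapshot", function(object) object@sourceName)

#' @rdname DatabaseSnapshot-class
#' @export
setMethod("records", "DatabaseSnapshot", function(object) object@records)

#' @rdname DatabaseSnapshot-class
#' @export
setMethod("xrefs", "DatabaseSnapshot", function(object) object@xrefs)

#' @rdname DatabaseSnapshot-class
#' @export
setMethod("loadLog", "DatabaseSnapshot", function(object) object@loadLog)

#' @rdname DatabaseSnapshot-class
#' @export
setMethod("length", "DatabaseSnapshot",
          function(x) nrow(x@records))

setMethod("show", "DatabaseSnapshot", function(object) {
  r <- object@records
  cat("DatabaseSnapshot '", object@sourceName, "': ", nrow(r),
      " records\n", sep = "")
  for (ch in c("smiles", "inchi", "iupac_name"))
    cat("  ", ch, ": ", sum(!is.na(r[[ch]])), " present\n", sep = "")
  cat("  xrefs: ", nrow(object@xrefs), " edges\n", sep = "")
})

# ----------------------------------------------------------------- SDF IO

#' Read a database snapshot from an SDF file
#'
#' Splits the file on \code{$$$$} delimiters, keeps each entry's MOL block
#' verbatim, and pulls identifier channels from the SD tags named in
#' \code{tagMap}. Entries without a usable MOL block (no atoms) are
#' dropped and counted; entries whose connection table cannot even be
#' delimited (no \code{M  END}) are skipped as malformed and counted. When
#' a channel tag carries several lines, the first is used. The xrefs tag
#' holds \code{SOURCE:ID} tokens split on \code{xrefSep}.
#'
#' @param path SDF file.
#' @param sourceName database name; defaults to the file stem.
#' @param tagMap SD-tag names per channel, see [defaultTagMap()].
#' @param xrefSep regular expression separating xref tokens
#'   (default: whitespace).
#' @return a [DatabaseSnapshot-class]; ingestion counters in
#'   [loadLog()].
#' @export
readSDF <- function(path, sourceName = NULL, tagMap = defaultTagMap(),
                    xrefSep = "[[:space:]]+") {
  if (!file.exists(path)) stop("cannot read SDF: ", path)
  if (is.null(sourceName))
    sourceName <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  ends <- which(lines == "$$$$")
  if (length(ends)) {
    starts <- c(1L, head(ends, -1L) + 1L)
  } else if (length(lines) && any(nzchar(trimws(lines)))) {
    starts <- 1L; ends <- length(lines) + 1L  # entry without terminator
  } else {
    starts <- integer(0); ends <- integer(0)
  }
  n_entries <- length(starts)
  recs <- vector("list", n_entries)
  xref_rows <- list()
  n_dropped <- 0L; n_malformed <- 0L
  for (k in seq_len(n_entries)) {
    entry <- lines[starts[k]:(ends[k] - 1L)]
    mend <- which(trimws(entry) == "M  END")
    if (!length(mend)) { n_malformed <- n_malformed + 1L; next }
    mol_block <- paste(entry[1:mend[1]], collapse = "\n")
    natoms <- suppressWarnings(
      as.integer(substr(entry[4], 1L, 3L)))
    if (is.na(natoms) || natoms < 1L) { n_dropped <- n_dropped + 1L; next }
    tags <- parseSDTags(entry[-(1:mend[1])])
    firstVal <- function(tag) {
      v <- tags[[tag]]
      if (is.null(v) || !length(v)) NA_character_ else v[1]
    }
    rid <- firstVal(tagMap$record_id)
    if (is.na(rid)) rid <- sprintf("%s_%06d", sourceName, k)
    recs[[k]] <- data.frame(
      record_id = rid, mol_block = mol_block,
      smiles = firstVal(tagMap$smiles), inchi = firstVal(tagMap$inchi),
      iupac_name = firstVal(tagMap$iupac_name), stringsAsFactors = FALSE)
    xv <- tags[[tagMap$xrefs]]
    if (!is.null(xv) && length(xv)) {
      tokens <- unlist(strsplit(paste(xv, collapse = " "), xrefSep))
      tokens <- tokens[nzchar(tokens)]
      good <- grepl(":", tokens, fixed = TRUE)
      if (any(good))
        xref_rows[[length(xref_rows) + 1L]] <- data.frame(
          record_id = rid,
          target_source = sub(":.*$", "", tokens[good]),
          target_id = sub("^[^:]*:", "", tokens[good]),
          stringsAsFactors = FALSE)
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(record_id = character(), mol_block = character(),
               smiles = character(), inchi = character(),
               iupac_name = character(), stringsAsFactors = FALSE)
  xr <- if (length(xref_rows)) do.call(rbind, xref_rows) else NULL
  log <- list(path = path, n_entries = n_entries,
              n_records = nrow(records),
              n_dropped_no_molblock = n_dropped, n_malformed = n_malformed)
  databaseSnapshot(sourceName, records, xrefs = xr, loadLog = log)
}

# SD data block -> named list of value-line vectors
parseSDTags <- function(lines) {
  hdr <- grep("^>\\s*<", lines)
  tags <- list()
  for (i in seq_along(hdr)) {
    tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", lines[hdr[i]])
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    vals <- lines[(hdr[i] + 1L):to]
    vals <- vals[nzchar(trimws(vals)) & vals != "$$$$"]
    tags[[tag]] <- vals
  }
  tags
}

#' Write a snapshot back to SDF
#'
#' MOL blocks are emitted verbatim; channels and xrefs become SD tags
#' under the given tag map.
#'
#' @inheritParams readSDF
#' @param db a [DatabaseSnapshot-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSDF <- function(db, path, tagMap = defaultTagMap()) {
  r <- records(db)
  xr <- xrefs(db)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(r))) {
    writeLines(r$mol_block[i], con)
    emit <- function(tag, value) {
      if (!is.na(value) && nzchar(value))
        writeLines(c(paste0(">  <", tag, ">"), value, ""), con)
    }
    emit(tagMap$record_id, r$record_id[i])
    emit(tagMap$smiles, r$smiles[i])
    emit(tagMap$inchi, r$inchi[i])
    emit(tagMap$iupac_name, r$iupac_name[i])
    ex <- xr[xr$record_id == r$record_id[i], , drop = FALSE]
    if (nrow(ex))
      emit(tagMap$xrefs,
           paste(paste0(ex$target_source, ":", ex$target_id),
                 collapse = " "))
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Attach identifier channels from a sidecar table
#'
#' Alternative to SD tags: a TSV with columns \code{record_id},
#' \code{channel} (\code{smiles}, \code{inchi} or \code{iupac_name}) and
#' \code{value}. The first value per record-channel wins.
#'
#' @param db a [DatabaseSnapshot-class].
#' @param path TSV file.
#' @return the snapshot with channels filled in.
#' @export
readChannelTable <- function(db, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("record_id", "channel", "value") %in% names(tab)))
  r <- records(db)
  for (ch in c("smiles", "inchi", "iupac_name")) {
    sub <- tab[tab$channel == ch & tab$record_id %in% r$record_id, ]
    sub <- sub[!duplicated(sub$record_id), ]
    if (nrow(sub))
      r[[ch]][match(sub$record_id, r$record_id)] <- sub$value
  }
  databaseSnapshot(sourceName(db), r, xrefs = xrefs(db), loadLog = loadLog(db))
}

# ------------------------------------------------- channel -> Std InChI

stdInchiResult <- function(input, ok, inchi, failure_class) {
  ok <- as.logical(ok)
  data.frame(input = input, ok = ok,
             inchi = ifelse(ok, inchi, NA_character_),
             failure_class = ifelse(ok, NA_character_, failure_class),
             stringsAsFactors = FALSE)
}

convertChannel <- function(kind, values) {
  n <- length(values)
  out <- stdInchiResult(values, rep(FALSE, n), rep(NA_character_, n),
                        rep("empty_structure", n))
  todo <- !is.na(values) & nzchar(values)
  if (any(todo)) {
    m <- runChemTool("pipeline",
                     input = data.frame(id = which(todo), kind = kind,
                                        value = values[todo]),
                     min_cols = 4L)
    out[todo, ] <- stdInchiResult(values[todo], m[, 2] == "1", m[, 4], m[, 3])
  }
  out
}

#' Convert identifier channels to Standard InChI
#'
#' Each converter is a deterministic, vectorised, total function: every
#' input yields either a Standard InChI (\code{"InChI=1S/..."}) or a
#' classified failure, never an error. Failure classes: \code{query_atom}
#' (wildcard "R"/"*" atoms, which block identifier generation),
#' \code{parse_error}, \code{name_unresolvable}, \code{empty_structure},
#' \code{other}.
#'
#' @param molBlocks,smiles,inchi,names character vectors of one channel's
#'   raw values (\code{NA} = absent).
#' @return data.frame with columns \code{input}, \code{ok}, \code{inchi}
#'   (\code{NA} unless \code{ok}), \code{failure_class} (\code{NA} when
#'   \code{ok}); exactly one of \code{inchi} / \code{failure_class} is
#'   filled per row.
#' @examples \dontrun{
#' smilesToStdInchi(c("CCO", "OCC"))  # both InChI=1S/C2H6O/c1-2-3/...
#' }
#' @export
molToStdInchi <- function(molBlocks) convertChannel("mol", molBlocks)

#' @rdname molToStdInchi
#' @export
smilesToStdInchi <- function(smiles) convertChannel("smiles", smiles)

#' @rdname molToStdInchi
#' @details \code{inchiToStdInchi} normalises both Standard and
#'   non-standard InChI inputs through the structure they encode; a
#'   Standard InChI round-trips to itself (fixed point).
#' @export
inchiToStdInchi <- function(inchi) convertChannel("inchi", inchi)

#' @rdname molToStdInchi
#' @param resolver a name resolver: \code{function(names)} returning a
#'   SMILES vector (\code{NA} where unresolved). See
#'   [makeLookupResolver()]. Full IUPAC-name parsing is out of scope;
#'   resolution is a pluggable interface.
#' @details \code{nameToStdInchi} maps unresolved names to
#'   \code{name_unresolvable}; a crashing resolver is caught, logged as a
#'   warning, and yields failure class \code{other} so the audit
#'   continues.
#' @export
nameToStdInchi <- function(names, resolver = defaultNameResolver()) {
  smiles <- tryCatch(resolver(names), error = function(e) {
    warning("name resolver failed: ", conditionMessage(e))
    structure(rep(NA_character_, length(names)), crashed = TRUE)
  })
  crashed <- isTRUE(attr(smiles, "crashed"))
  out <- convertChannel("smiles", as.character(smiles))
  out$input <- names
  unresolved <- is.na(smiles)
  out$ok[unresolved] <- FALSE
  out$inchi[unresolved] <- NA_character_
  out$failure_class[unresolved] <-
    if (crashed) "other" else "name_unresolvable"
  out$failure_class[unresolved & is.na(names)] <- "empty_structure"
  out
}

#' Fixture-backed name resolvers
#'
#' `makeLookupResolver` wraps a name-to-SMILES lookup table into the
#' resolver interface used by [nameToStdInchi()] and [auditWithin()].
#' `defaultNameResolver` serves the package's built-in fixture names (the
#' base molecule library plus a few classics such as \code{"ethanol"}).
#'
#' @param table data.frame with columns \code{name} and \code{smiles}, or
#'   a named character vector of SMILES.
#' @return function mapping a character vector of names to SMILES
#'   (\code{NA} where unknown).
#' @export
makeLookupResolver <- function(table) {
  if (is.data.frame(table)) {
    map <- table$smiles
    names(map) <- table$name
  } else map <- table
  function(names) unname(map[as.character(names)])
}

#' @rdname makeLookupResolver
#' @export
defaultNameResolver <- function() {
  lib <- baseLibrary()
  extra <- utils::read.delim(
    system.file("extdata", "name_lookup.tsv", package = "molconsist",
                mustWork = TRUE), stringsAsFactors = FALSE)
  makeLookupResolver(rbind(lib[c("name", "smiles")], extra))
}

#' Build MOL V2000 blocks from SMILES
#'
#' Convenience for constructing snapshots and fixtures in code: parses
#' each SMILES, computes 2D coordinates (stereo preserved as wedges) and
#' writes an MDL V2000 MOL block.
#'
#' @param smiles character vector.
#' @return character vector of MOL blocks (\code{NA} where the SMILES
#'   does not parse).
#' @export
molBlockFromSmiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  todo <- !is.na(smiles) & nzchar(smiles)
  if (any(todo)) {
    m <- runChemTool("genmol",
                     input = data.frame(id = which(todo),
                                        smiles = smiles[todo]),
                     min_cols = 4L)
    ok <- m[, 2] == "1"
    out[todo][ok] <- m[ok, 4]
  }
  out
}
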