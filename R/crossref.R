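# Between-database audit: MOL-derived Standard InChIs are compared across
# cross-reference edges. Each edge is investigated independently; edges
# whose target id is absent from the target snapshot, or where either
# MOL fails conversion/standardisation, are excluded from the denominator
# with a reason code. Direction matters and is never symmetrised.

#' Cross-reference edges from a snapshot or a TSV file
#'
#' `harvestEdges` turns a snapshot's embedded xrefs into an edge table;
#' `readEdges` reads one from TSV (columns \code{from_source},
#' \code{from_id}, \code{to_source}, \code{to_id}).
#'
#' @param db a [DatabaseSnapshot-class].
#' @return data.frame of edges.
#' @export
harvestEdges <- function(db) {
  xr <- xrefs(db)
  data.frame(from_source = rep(sourceName(db), nrow(xr)),
             from_id = xr$record_id, to_source = xr$target_source,
             to_id = xr$target_id, stringsAsFactors = FALSE)
}

#' @rdname harvestEdges
#' @param path TSV file of edges.
#' @export
readEdges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("from_source", "from_id", "to_source", "to_id") %in%
                  names(e)))
  e
}

#' Audit structural agreement across cross-references
#'
#' Compares the standardized MOL-derived Standard InChIs of the two
#' records joined by each cross-reference edge from \code{dbA} to
#' \code{dbB}, under one FICTS variant. A compound with several
#' cross-references contributes each edge independently; the
#' single-cross-reference subset (source compounds with exactly one edge)
#' is additionally reported, together with multiplicity statistics of the
#' multi-reference compounds. Duplicate edges (same from_id, to_id) are
#' collapsed to one claim before comparison.
#'
#' @param dbA,dbB source and target [DatabaseSnapshot-class] objects.
#' @param edges edge data.frame (see [harvestEdges()]); all edges must
#'   point from \code{dbA}'s source to \code{dbB}'s source. Defaults to
#'   the edges embedded in \code{dbA}.
#' @param flags one FICTS variant (label or [FictsFlags-class]).
#' @return an [XrefReport-class].
#' @export
auditCross <- function(dbA, dbB, edges = NULL, flags = fictsFlags()) {
  stopifnot(is(dbA, "DatabaseSnapshot"), is(dbB, "DatabaseSnapshot"))
  label <- unname(normalizeVariants(flags))
  if (length(label) != 1L) stop("auditCross takes a single variant")
  if (is.null(edges)) edges <- harvestEdges(dbA)
  edges <- edges[edges$to_source == sourceName(dbB), , drop = FALSE]
  if (nrow(edges) && !all(edges$from_source == sourceName(dbA)))
    stop("edges must point from '", sourceName(dbA), "'")
  edges <- edges[!duplicated(edges[c("from_id", "to_id")]), , drop = FALSE]
  n_total <- nrow(edges)

  ra <- records(dbA); rb <- records(dbB)
  resolved <- edges$from_id %in% ra$record_id & edges$to_id %in% rb$record_id

  # one batch: standardized MOL-derived InChIs for every referenced record
  need_a <- unique(edges$from_id[resolved])
  need_b <- unique(edges$to_id[resolved])
  req <- data.frame(
    id = c(paste0("A\r", need_a, recycle0 = TRUE),
           paste0("B\r", need_b, recycle0 = TRUE)),
    kind = rep("mol", length(need_a) + length(need_b)),
    value = c(ra$mol_block[match(need_a, ra$record_id)],
              rb$mol_block[match(need_b, rb$record_id)]),
    stringsAsFactors = FALSE)
  side <- list(A = list(), B = list())
  if (nrow(req)) {
    m <- runChemTool("pipeline", input = req, args = c("--variants", label), min_cols = 8L)
    for (k in seq_len(nrow(m))) {
      parts <- strsplit(m[k, 1], "\r", fixed = TRUE)[[1]]
      ok <- m[k, 2] == "1" && m[k, 5] == "1"
      side[[parts[1]]][[parts[2]]] <-
        list(ok = ok, inchi = if (ok) m[k, 7] else NA_character_,
             reason = if (ok) NA_character_
                      else if (m[k, 2] != "1")
                        paste0("conversion_failed:", m[k, 3])
                      else paste0("standardisation_failed:", m[k, 6]))
    }
  }

  status <- rep("excluded", n_total)
  reason <- rep(NA_character_, n_total)
  reason[!resolved] <- "unresolved_target"
  for (i in which(resolved)) {
    sa <- side$A[[edges$from_id[i]]]; sb <- side$B[[edges$to_id[i]]]
    if (!sa$ok) { reason[i] <- paste0("from_", sa$reason); next }
    if (!sb$ok) { reason[i] <- paste0("to_", sb$reason); next }
    status[i] <- if (sa$inchi == sb$inchi) "match" else "mismatch"
  }
  compared <- status != "excluded"
  matched <- status == "match"
  n_comp <- sum(compared); n_match <- sum(matched)

  # single- vs multi-cross-reference breakdown (per source compound)
  cnt <- table(edges$from_id)
  single_ids <- names(cnt)[cnt == 1L]
  sgl <- compared & edges$from_id %in% single_ids
  n_sc <- sum(sgl); n_sm <- sum(sgl & matched)
  ms <- multiplicityStats(edges)

  excl <- table(reason[!compared])
  exclusions <- data.frame(reason = names(excl),
                           n = as.integer(excl), stringsAsFactors = FALSE)
  if (n_comp == 0L)
    warning("no comparable cross-reference edges between '",
            sourceName(dbA), "' and '", sourceName(dbB), "'")
  new("XrefReport", fromSource = sourceName(dbA), toSource = sourceName(dbB),
      variant = label, nEdgesTotal = n_total, nEdgesCompared = n_comp,
      nMatched = n_match,
      agreementPct = if (n_comp) 100 * n_match / n_comp else NA_real_,
      nMultiCompounds = ms[["n_multi"]], multiMean = ms[["mean"]],
      multiMedian = ms[["median"]],
      singleXrefAgreementPct = if (n_sc) 100 * n_sm / n_sc else NA_real_,
      nSingleCompared = n_sc, nSingleMatched = n_sm,
      exclusions = exclusions,
      edgeVerdicts = data.frame(from_id = edges$from_id,
                                to_id = edges$to_id, status = status,
                                reason = reason, stringsAsFactors = FALSE))
}

#' Cross-reference multiplicity statistics
#'
#' Groups edges by source compound (and target source) and summarises
#' compounds carrying more than one cross-reference.
#'
#' @param edges edge data.frame (see [harvestEdges()]).
#' @return named list: \code{n_multi} (compounds with >= 2 edges),
#'   \code{mean} and \code{median} of their edge counts (\code{NA} when
#'   no compound is multi-referenced).
#' @examples
#' e <- data.frame(from_source = "A", from_id = c("a", "a", "b"),
#'                 to_source = "B", to_id = c("x", "y", "z"))
#' multiplicityStats(e)  # 1 compound, mean 2, median 2
#' @export
multiplicityStats <- function(edges) {
  if (!nrow(edges))
    return(list(n_multi = 0L, mean = NA_real_, median = NA_real_))
  cnt <- table(paste(edges$from_id, edges$to_source, sep = "\r"))
  multi <- as.integer(cnt[cnt >= 2L])
  if (!length(multi))
    return(list(n_multi = 0L, mean = NA_real_, median = NA_real_))
  list(n_multi = length(multi), mean = mean(multi),
       median = stats::median(multi))
}

setMethod("show", "XrefReport", function(object) {
  cat("XrefReport ", object@fromSource, " -> ", object@toSource,
      "  [", object@variant, "]\n", sep = "")
  cat(sprintf("  edges: %d total, %d compared, %d matched (%s%%)\n",
              object@nEdgesTotal, object@nEdgesCompared, object@nMatched,
              fmtPct(object@agreementPct)))
  cat(sprintf("  single-xref compounds: %d compared, %d matched (%s%%)\n",
              object@nSingleCompared, object@nSingleMatched,
              fmtPct(object@singleXrefAgreementPct)))
  cat(sprintf("  multi-xref compounds: %d (mean %s, median %s edges)\n",
              object@nMultiCompounds, fmtNum(object@multiMean),
              fmtNum(object@multiMedian)))
  if (nrow(object@exclusions)) {
    cat("  exclusions:\n")
    for (i in seq_len(nrow(object@exclusions)))
      cat("    ", object@exclusions$reason[i], ": ",
          object@exclusions$n[i], "\n", sep = "")
  }
})

fmtPct <- function(x) if (is.na(x)) "-" else sprintf("%.1f", x)
fmtNum <- function(x) if (is.na(x)) "-" else sprintf("%.1f", x)
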