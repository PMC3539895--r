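# Report writers and the end-to-end demo run. Tables mirror the shapes of
# published database-consistency studies (channels x variants for the
# within-database audit; directed source-pair rows for the cross audit);
# percentages are printed to one decimal but raw counts are always kept
# alongside so nothing is lost to rounding.

#' Write a within-database audit report to disk
#'
#' Writes \code{conversion.tsv}, \code{cells.tsv} (channel x variant
#' agreement table), \code{verdicts.tsv} (per-record outcomes with
#' exclusion reasons), \code{std_failures.tsv} and \code{report.json}.
#'
#' @param report a [ConsistencyReport-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, useful when several reports share a
#'   directory.
#' @return `dir`, invisibly.
#' @export
writeAuditTables <- function(report, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, f))
  tsv <- function(d, f)
    utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cv <- report@conversion
  cv$pct <- round(cv$pct, 1)
  tsv(cv, "conversion.tsv")
  tsv(reshapeCells(report@cells), "cells.tsv")
  tsv(report@cells, "cells_long.tsv")
  tsv(report@verdicts, "verdicts.tsv")
  tsv(report@stdFailures, "std_failures.tsv")
  jsonlite::write_json(
    list(source = report@sourceName, toolkit = report@toolkit,
         variants = report@variants, conversion = report@conversion,
         cells = report@cells,
         exclusion_counts = exclusionCounts(report)),
    p("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

exclusionCounts <- function(report) {
  v <- report@verdicts
  ex <- v[v$status == "excluded" & !is.na(v$reason), ]
  as.list(table(ex$reason))
}

#' @rdname writeAuditTables
#' @param xreport an [XrefReport-class].
#' @export
writeXrefTables <- function(xreport, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, f))
  summary <- data.frame(
    from_source = xreport@fromSource, to_source = xreport@toSource,
    variant = xreport@variant, n_edges_total = xreport@nEdgesTotal,
    n_edges_compared = xreport@nEdgesCompared,
    n_matched = xreport@nMatched,
    agreement_pct = round(xreport@agreementPct, 1),
    single_xref_agreement_pct = round(xreport@singleXrefAgreementPct, 1),
    n_single_compared = xreport@nSingleCompared,
    n_multi_compounds = xreport@nMultiCompounds,
    multi_mean = round(xreport@multiMean, 1),
    multi_median = xreport@multiMedian, stringsAsFactors = FALSE)
  utils::write.table(summary, p("crossref.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(xreport@edgeVerdicts, p("edge_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(as.list(summary), list(exclusions = xreport@exclusions)),
    p("crossref.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Run the full synthetic audit demonstration
#'
#' Generates a synthetic study, audits both snapshots within-database
#' under the requested variants, audits the cross-references at the
#' baseline and the stereo-insensitive variant, and writes every table
#' plus a \code{config.json} capturing the run parameters and toolkit
#' version. Deterministic given the spec's seed.
#'
#' @param dir output directory.
#' @param spec an [InjectionSpec-class].
#' @param variants FICTS variants for the within-database audits.
#' @return invisibly, a list with elements \code{study}, \code{withinA},
#'   \code{withinB}, \code{crossBaseline}, \code{crossStereoU}.
#' @export
runFullDemo <- function(dir, spec = injectionSpec(),
                        variants = c("FICTS", "uICTS", "FuCTS", "FIuTS",
                                     "FICuS", "FICTu")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generateSyntheticPair(spec)
  writeSyntheticStudy(study, file.path(dir, "data"))
  res <- nameResolver(study)
  wa <- auditWithin(dbA(study), variants, resolver = res)
  wb <- auditWithin(dbB(study), variants, resolver = res)
  writeAuditTables(wa, dir, prefix = "within_a_")
  writeAuditTables(wb, dir, prefix = "within_b_")
  xb <- auditCross(dbA(study), dbB(study), edges(study), "FICTS")
  xs <- auditCross(dbA(study), dbB(study), edges(study), "FICTu")
  writeXrefTables(xb, dir, prefix = "baseline_")
  writeXrefTables(xs, dir, prefix = "stereo_u_")
  jsonlite::write_json(
    list(command = "full-demo", n_records = spec@nRecords,
         rates = as.list(spec@rates), channels = spec@channels,
         p_bad_edge = spec@pBadEdge, p_multi = spec@pMulti,
         multi_max = spec@multiMax, seed = spec@seed,
         variants = variants, toolkit = toolkitVersion(),
         package = as.character(utils::packageVersion("molconsist"))),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(study = study, withinA = wa, withinB = wb,
                 crossBaseline = xb, crossStereoU = xs))
}
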