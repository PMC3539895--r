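# Within-database audit: the MOL block is the reference representation;
# each identifier channel is converted to Standard InChI and compared to
# the MOL-derived Standard InChI by exact string equality, per FICTS
# variant. A record whose MOL or channel fails conversion, or fails
# standardisation under a variant, is excluded from that cell's
# denominator with a reason code ("no comparison is done").

.AUDIT_CHANNELS <- c("inchi", "smiles", "iupac")

#' Audit identifier consistency within one database
#'
#' For every record, converts the MOL block and each present identifier
#' channel (InChI, SMILES, IUPAC name via the pluggable resolver) to a
#' Standard InChI, standardises both sides under each FICTS variant, and
#' compares by exact string equality. The fully sensitive baseline
#' (\code{"FICTS"}) is always included. Records carrying several values
#' in one channel contribute their first value only.
#'
#' @param db a [DatabaseSnapshot-class].
#' @param variants FICTS variants to audit: labels, [FictsFlags-class]
#'   objects, or a list of either.
#' @param resolver name resolver for the IUPAC channel, see
#'   [makeLookupResolver()].
#' @param diagnose if \code{TRUE}, annotate each baseline mismatch with
#'   the first differing InChI layer (curation aid).
#' @return a [ConsistencyReport-class].
#' @seealso [auditCross()] for the between-database audit,
#'   [bruteForceAgreement()] for the counting oracle used in tests.
#' @export
auditWithin <- function(db, variants = c("FICTS", "FICTu"),
                        resolver = defaultNameResolver(),
                        diagnose = FALSE) {
  stopifnot(is(db, "DatabaseSnapshot"))
  if (length(db) == 0L) stop("snapshot has no records")
  labels <- unique(c("FICTS", normalizeVariants(variants)))
  r <- records(db)
  n <- nrow(r)

  # ---- assemble one conversion+standardisation batch over all channels
  req <- data.frame(id = character(), kind = character(),
                    value = character(), stringsAsFactors = FALSE)
  add <- function(req, rows, channel, kind, value)
    rbind(req, data.frame(id = paste(channel, rows, sep = "\r"),
                          kind = kind, value = value,
                          stringsAsFactors = FALSE))
  req <- add(req, seq_len(n), "mol", "mol", r$mol_block)
  has <- list(mol = rep(TRUE, n))
  for (ch in c("inchi", "smiles")) {
    has[[ch]] <- !is.na(r[[ch]]) & nzchar(r[[ch]])
    if (any(has[[ch]]))
      req <- add(req, which(has[[ch]]), ch, ch, r[[ch]][has[[ch]]])
  }
  has$iupac <- !is.na(r$iupac_name) & nzchar(r$iupac_name)
  resolver_crashed <- FALSE
  resolved <- rep(NA_character_, n)
  if (any(has$iupac)) {
    resolved[has$iupac] <- tryCatch(
      as.character(resolver(r$iupac_name[has$iupac])),
      error = function(e) {
        resolver_crashed <<- TRUE
        warning("name resolver failed; IUPAC channel excluded as 'other': ",
                conditionMessage(e))
        rep(NA_character_, sum(has$iupac))
      })
    ok_names <- has$iupac & !is.na(resolved)
    if (any(ok_names))
      req <- add(req, which(ok_names), "iupac", "smiles", resolved[ok_names])
  }
  m <- runChemTool("pipeline", input = req,
                   args = c("--variants", paste(labels, collapse = ",")),
                   min_cols = 4L + 4L * length(labels))

  # per-channel matrices of conversion + standardised InChIs
  ids <- strsplit(m[, 1], "\r", fixed = TRUE)
  ch_of <- vapply(ids, `[`, character(1), 1L)
  row_of <- as.integer(vapply(ids, `[`, character(1), 2L))
  conv_ok <- matrix(NA, n, 4, dimnames = list(NULL, c("mol", .AUDIT_CHANNELS)))
  conv_fail <- matrix(NA_character_, n, 4,
                      dimnames = dimnames(conv_ok))
  std_ok <- array(NA, c(n, 4, length(labels)),
                  dimnames = list(NULL, c("mol", .AUDIT_CHANNELS), labels))
  std_inchi <- array(NA_character_, dim(std_ok), dimnames = dimnames(std_ok))
  std_fail <- array(NA_character_, dim(std_ok), dimnames = dimnames(std_ok))
  for (k in seq_len(nrow(m))) {
    ch <- ch_of[k]; i <- row_of[k]
    conv_ok[i, ch] <- m[k, 2] == "1"
    conv_fail[i, ch] <- if (m[k, 2] == "1") NA_character_ else m[k, 3]
    for (v in seq_along(labels)) {
      off <- 4L + (v - 1L) * 4L
      std_ok[i, ch, v] <- conv_ok[i, ch] && m[k, off + 1L] == "1"
      std_fail[i, ch, v] <- if (isTRUE(std_ok[i, ch, v])) NA_character_
                            else m[k, off + 2L]
      std_inchi[i, ch, v] <- if (isTRUE(std_ok[i, ch, v])) m[k, off + 3L]
                             else NA_character_
    }
  }
  # unresolved names count as conversion failures of the iupac channel
  unres <- has$iupac & is.na(resolved)
  conv_ok[unres, "iupac"] <- FALSE
  conv_fail[unres, "iupac"] <-
    if (resolver_crashed) "other" else "name_unresolvable"

  # ---- conversion statistics (denominator: records possessing a channel)
  conversion <- do.call(rbind, lapply(c("mol", .AUDIT_CHANNELS), function(ch) {
    attempted <- sum(has[[ch]])
    succeeded <- sum(conv_ok[has[[ch]], ch], na.rm = TRUE)
    data.frame(channel = ch, attempted = attempted, succeeded = succeeded,
               pct = if (attempted) 100 * succeeded / attempted else NA_real_,
               stringsAsFactors = FALSE)
  }))

  # ---- per-record verdicts and agreement cells
  verd <- list(); cell <- list(); sfail <- list()
  for (v in seq_along(labels)) {
    lab <- labels[v]
    for (ch in .AUDIT_CHANNELS) {
      status <- rep("excluded", n)
      reason <- rep(NA_character_, n)
      reason[!has[[ch]]] <- "channel_absent"
      cf <- !has[[ch]]  # handled
      bad_mol_conv <- !cf & !conv_ok[, "mol"]
      reason[bad_mol_conv] <-
        paste0("mol_conversion_failed:", conv_fail[bad_mol_conv, "mol"])
      bad_ch_conv <- !cf & !bad_mol_conv & !conv_ok[, ch]
      reason[bad_ch_conv] <-
        paste0("channel_conversion_failed:", conv_fail[bad_ch_conv, ch])
      live <- has[[ch]] & conv_ok[, "mol"] & conv_ok[, ch]
      bad_mol_std <- live & !std_ok[, "mol", v]
      reason[bad_mol_std] <-
        paste0("mol_standardisation_failed:", std_fail[bad_mol_std, "mol", v])
      bad_ch_std <- live & std_ok[, "mol", v] & !std_ok[, ch, v]
      reason[bad_ch_std] <-
        paste0("channel_standardisation_failed:", std_fail[bad_ch_std, ch, v])
      compared <- live & std_ok[, "mol", v] & std_ok[, ch, v]
      match <- compared & std_inchi[, "mol", v] == std_inchi[, ch, v]
      status[compared] <- ifelse(match[compared], "match", "mismatch")
      reason[compared] <- NA_character_
      vd <- data.frame(record_id = r$record_id, channel = ch, variant = lab,
                       status = status, reason = reason,
                       stringsAsFactors = FALSE)
      if (diagnose) {
        vd$first_diff_layer <- NA_character_
        mm <- status == "mismatch"
        if (any(mm))
          vd$first_diff_layer[mm] <-
            firstDiffLayer(std_inchi[mm, "mol", v], std_inchi[mm, ch, v])
      }
      verd[[length(verd) + 1L]] <- vd
      n_comp <- sum(compared); n_match <- sum(match)
      cell[[length(cell) + 1L]] <- data.frame(
        channel = ch, variant = lab, n_compared = n_comp,
        n_matched = n_match,
        agreement_pct = if (n_comp) 100 * n_match / n_comp else NA_real_,
        stringsAsFactors = FALSE)
      sfail[[length(sfail) + 1L]] <- data.frame(
        channel = ch, variant = lab,
        n_std_failed = sum(bad_mol_std) + sum(bad_ch_std),
        stringsAsFactors = FALSE)
    }
  }
  if (!any(unlist(lapply(has[.AUDIT_CHANNELS], any))))
    warning("no records carry any identifier channel; ",
            "report contains conversion stats only")
  new("ConsistencyReport", sourceName = sourceName(db),
      conversion = conversion, cells = do.call(rbind, cell),
      verdicts = do.call(rbind, verd), stdFailures = do.call(rbind, sfail),
      variants = labels, toolkit = toolkitVersion())
}

#' @rdname ConsistencyReport-class
#' @export
setMethod("conversionStats", "ConsistencyReport",
          function(object) object@conversion)

#' @rdname ConsistencyReport-class
#' @export
setMethod("cells", "ConsistencyReport", function(object) object@cells)

#' @rdname ConsistencyReport-class
#' @export
setMethod("verdicts", "ConsistencyReport", function(object) object@verdicts)

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport for '", object@sourceName, "' (",
      object@toolkit, ")\n", sep = "")
  cat("\nConversion to Standard InChI (%):\n")
  cv <- object@conversion
  cv$pct <- round(cv$pct, 1)
  print(cv, row.names = FALSE)
  cat("\nAgreement with the MOL-derived InChI (%):\n")
  wide <- reshapeCells(object@cells)
  print(wide, row.names = FALSE)
})

# cells long -> channels x variants table of pct (1 decimal, like the
# published consistency tables)
reshapeCells <- function(cells) {
  variants <- unique(cells$variant)
  chans <- unique(cells$channel)
  wide <- data.frame(channel = paste0("MOL-", toupper(chans)))
  for (v in variants)
    wide[[v]] <- round(cells$agreement_pct[match(
      paste(chans, v), paste(cells$channel, cells$variant))], 1)
  wide
}

#' Naive agreement-counting oracle
#'
#' Counts, with an explicit loop and no shared code with [auditWithin()],
#' how many pairs have both sides present and how many of those are
#' equal. Used as the independent aggregation oracle in the test suite.
#'
#' @param a,b character vectors of equal length (\code{NA} = absent side).
#' @return integer vector \code{c(n_compared, n_matched)}.
#' @examples
#' bruteForceAgreement(c("a", "a", NA), c("a", "b", "a"))  # 2 1
#' @export
bruteForceAgreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  n_compared <- 0L; n_matched <- 0L
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    n_compared <- n_compared + 1L
    if (a[i] == b[i]) n_matched <- n_matched + 1L
  }
  c(n_compared = n_compared, n_matched = n_matched)
}
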