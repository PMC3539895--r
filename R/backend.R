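# Batched bridge to the bundled RDKit helper (inst/python/chem_tool.py).
# Every structure-level operation in the package funnels through
# runChemTool(): requests are written as a backslash-escaped TSV, the
# helper is invoked once per batch, and its TSV reply is read back. The
# helper embeds the IUPAC InChI implementation via RDKit.

.molconsist_env <- new.env(parent = emptyenv())

pythonBinary <- function() {
  bin <- getOption("molconsist.python", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin))
    stop("no 'python' interpreter found; set options(molconsist.python=)")
  bin
}

chemToolScript <- function() {
  system.file("python", "chem_tool.py", package = "molconsist",
              mustWork = TRUE)
}

# escape \, tab, CR, LF so arbitrary text (MOL blocks) fits one TSV field
escapeField <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescapeField <- function(x) {
  # protect doubled backslashes before expanding the short escapes
  x <- gsub("\\\\", "\x01", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  gsub("\x01", "\\", x, fixed = TRUE)
}

#' @noRd
runChemTool <- function(mode, input = NULL, args = character(),
                        min_cols = 0L) {
  fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(fout), add = TRUE)
  cmd_args <- c(chemToolScript(), mode, "--out", fout, args)
  if (!is.null(input)) {
    fin <- tempfile(fileext = ".tsv")
    on.exit(unlink(fin), add = TRUE)
    lines <- apply(as.matrix(input), 1L, function(r)
      paste(escapeField(as.character(r)), collapse = "\t"))
    writeLines(lines, fin, useBytes = TRUE)
    cmd_args <- c(cmd_args, "--in", fin)
  }
  ferr <- tempfile(fileext = ".err")
  on.exit(unlink(ferr), add = TRUE)
  status <- system2(pythonBinary(), shQuote(cmd_args),
                    stdout = FALSE, stderr = ferr)
  if (!identical(status, 0L)) {
    err <- tryCatch(readLines(ferr, warn = FALSE), error = function(e) "")
    stop("chemistry helper failed (mode '", mode, "', status ", status, "):\n",
         paste(utils::tail(err, 12L), collapse = "\n"))
  }
  out <- readLines(fout, warn = FALSE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  ncol <- max(min_cols, if (length(parts)) max(lengths(parts)) else 0L)
  mat <- matrix("", nrow = length(parts), ncol = ncol)
  for (i in seq_along(parts)) {
    p <- unescapeField(parts[[i]])
    mat[i, seq_along(p)] <- p
  }
  mat
}

#' Version of the structure toolkit behind the audit
#'
#' Returns the version string of the chemistry toolkit (RDKit, which
#' embeds the IUPAC InChI code) used for all conversions and
#' standardisations. Recorded in every report for provenance.
#'
#' @return single string, e.g. \code{"rdkit 2024.09.2"}.
#' @export
toolkitVersion <- function() {
  if (is.null(.molconsist_env$toolkit)) {
    m <- runChemTool("version")
    .molconsist_env$toolkit <- paste(m[1, 1], m[1, 2])
  }
  .molconsist_env$toolkit
}

# run code under a seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
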