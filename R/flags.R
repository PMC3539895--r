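.FICTS_LETTERS <- c("F", "I", "C", "T", "S")

#' Construct FICTS sensitivity flags
#'
#' @param fragment,isotope,charge,tautomer,stereo logical switches; `TRUE`
#'   marks the aspect insensitive (standardised away, rendered "u" in the
#'   label).
#' @return a [FictsFlags-class] object.
#' @examples
#' fictsLabel(fictsFlags())               # "FICTS" -- fully sensitive
#' fictsLabel(fictsFlags(stereo = TRUE))  # "FICTu"
#' @export
fictsFlags <- function(fragment = FALSE, isotope = FALSE, charge = FALSE,
                       tautomer = FALSE, stereo = FALSE) {
  new("FictsFlags", fragment = fragment, isotope = isotope, charge = charge,
      tautomer = tautomer, stereo = stereo)
}

#' Render and parse FICTS variant labels
#'
#' A variant label writes the five letters F, I, C, T, S in order,
#' lower-casing a position to "u" when that aspect is insensitive:
#' \code{"FICTS"} is the fully sensitive baseline, \code{"FICTu"} is
#' stereo-insensitive, \code{"uuuuu"} is insensitive to everything.
#'
#' @param object a [FictsFlags-class] object.
#' @return `fictsLabel`: a single label string.
#' @aliases fictsLabel,FictsFlags-method
#' @export
setMethod("fictsLabel", "FictsFlags", function(object) {
  ins <- c(object@fragment, object@isotope, object@charge,
           object@tautomer, object@stereo)
  paste(ifelse(ins, "u", .FICTS_LETTERS), collapse = "")
})

#' @rdname fictsLabel
#' @param label a variant label string such as \code{"FICTu"}.
#' @return `parseFictsLabel`: the corresponding [FictsFlags-class] object.
#' @export
parseFictsLabel <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      nchar(label) != 5L)
    stop("a FICTS label is a 5-character string; valid letters per ",
         "position: F/u, I/u, C/u, T/u, S/u")
  chars <- strsplit(label, "")[[1]]
  ok <- chars == .FICTS_LETTERS | chars == "u"
  if (!all(ok))
    stop("invalid FICTS label '", label, "': position ", which(!ok)[1],
         " must be '", .FICTS_LETTERS[which(!ok)[1]], "' or 'u'")
  ins <- chars == "u"
  fictsFlags(fragment = ins[1], isotope = ins[2], charge = ins[3],
             tautomer = ins[4], stereo = ins[5])
}

#' All 32 FICTS variants
#'
#' @return named list of the 32 [FictsFlags-class] combinations, named by
#'   their labels (\code{"FICTS"} through \code{"uuuuu"}).
#' @export
allFictsVariants <- function() {
  grid <- expand.grid(stereo = c(FALSE, TRUE), tautomer = c(FALSE, TRUE),
                      charge = c(FALSE, TRUE), isotope = c(FALSE, TRUE),
                      fragment = c(FALSE, TRUE))
  out <- lapply(seq_len(nrow(grid)), function(i)
    fictsFlags(fragment = grid$fragment[i], isotope = grid$isotope[i],
               charge = grid$charge[i], tautomer = grid$tautomer[i],
               stereo = grid$stereo[i]))
  names(out) <- vapply(out, fictsLabel, character(1))
  out
}

# accept a label, a FictsFlags, or a list of either; return label vector
normalizeVariants <- function(variants) {
  if (is(variants, "FictsFlags")) variants <- list(variants)
  if (is.character(variants)) variants <- as.list(variants)
  vapply(variants, function(v) {
    if (is(v, "FictsFlags")) return(fictsLabel(v))
    fictsLabel(parseFictsLabel(v))  # validates
  }, character(1))
}

# set of insensitive letters, for subset comparisons in properties
insensitiveSet <- function(flags) {
  if (is.character(flags)) flags <- parseFictsLabel(flags)
  .FICTS_LETTERS[c(flags@fragment, flags@isotope, flags@charge,
                   flags@tautomer, flags@stereo)]
}

setMethod("show", "FictsFlags", function(object) {
  cat("FictsFlags:", fictsLabel(object), "\n")
})
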