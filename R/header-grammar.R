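## The ISA-Tab column-header grammar.
##
## A header is either a bare category label ("Source Name", "Protocol REF",
## "Unit", ...) or a qualified one ("Characteristics[Organism]",
## "Parameter Value[Daily photon flux]"). Matching is case-sensitive and
## exact after trimming outer whitespace; the vocabulary is closed so that
## dialect drift fails fast. "Protocol REF[X]" is accepted as documentation
## shorthand and normalised to a plain Protocol REF column whose expected
## cell value is X.

.trimws <- function(x) sub("^[ \t]+", "", sub("[ \t]+$", "", x))

#' Parse an ISA-Tab column header
#'
#' Splits a raw header string into its category and bracket qualifier. The
#' qualifier is taken verbatim between the brackets (inner whitespace
#' preserved, outer trimmed). Unknown categories, qualified headers of
#' non-qualifiable categories, unbalanced brackets and empty input are
#' errors.
#'
#' @param text a single raw header string.
#' @return a [FieldHeader-class] object.
#' @examples
#' parseHeader("Characteristics[Organism]")
#' parseHeader("Source Name")
#' parseHeader("Protocol REF[Rooting]")  # normalised shorthand
#' @export
parseHeader <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    text <- .trimws(text)
    if (!nzchar(text))
        stop("empty header")
    open <- gregexpr("[", text, fixed = TRUE)[[1L]]
    close <- gregexpr("]", text, fixed = TRUE)[[1L]]
    nopen <- sum(open > 0L)
    nclose <- sum(close > 0L)
    if (nopen == 0L && nclose == 0L) {
        key <- names(.CATEGORY_LABELS)[match(text, .CATEGORY_LABELS)]
        if (is.na(key))
            stop("unknown header category: '", text, "'")
        if (key %in% .QUALIFIED_CATEGORIES)
            stop("header category '", text, "' requires a [qualifier]")
        return(FieldHeader(key))
    }
    if (nopen != 1L || nclose != 1L || close[1L] != nchar(text) ||
        open[1L] >= close[1L])
        stop("malformed bracket syntax in header: '", text, "'")
    base <- .trimws(substr(text, 1L, open[1L] - 1L))
    qual <- .trimws(substr(text, open[1L] + 1L, close[1L] - 1L))
    key <- names(.CATEGORY_LABELS)[match(base, .CATEGORY_LABELS)]
    if (is.na(key))
        stop("unknown header category: '", base, "'")
    if (identical(key, "PROTOCOL_REF"))  # documentation shorthand
        return(FieldHeader("PROTOCOL_REF", expected = qual))
    if (!key %in% .QUALIFIED_CATEGORIES)
        stop("header category '", base, "' does not take a qualifier")
    if (!nzchar(qual))
        stop("empty qualifier in header: '", text, "'")
    FieldHeader(key, qualifier = qual)
}

#' Format a FieldHeader in canonical spelling
#'
#' The inverse of [parseHeader()]: qualified categories render as
#' `Category[qualifier]`, everything else as the bare label (a Protocol REF
#' column always renders as `Protocol REF` regardless of its expected cell
#' value).
#'
#' @param header a [FieldHeader-class] object.
#' @return character(1), the canonical header text.
#' @export
formatHeader <- function(header) {
    stopifnot(is(header, "FieldHeader"))
    validObject(header)
    label <- .CATEGORY_LABELS[[header@category]]
    if (nzchar(header@qualifier))
        paste0(label, "[", header@qualifier, "]")
    else
        label
}

#' @describeIn parseHeader vectorised convenience: parse several headers into
#'   a list of `FieldHeader` objects.
#' @param texts character vector of raw headers.
#' @export
parseHeaders <- function(texts) lapply(texts, parseHeader)

headerTexts <- function(headers)
    vapply(headers, formatHeader, character(1))

headerCategories <- function(headers)
    vapply(headers, slot, character(1), "category")

headerQualifiers <- function(headers)
    vapply(headers, slot, character(1), "qualifier")

setMethod("show", "FieldHeader", function(object) {
    cat("FieldHeader:", formatHeader(object))
    if (nzchar(object@expected))
        cat(" (expected value: ", object@expected, ")", sep = "")
    cat("\n")
})
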