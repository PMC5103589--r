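## Validation-issue plumbing shared by the reader and the validator.

.ISSUE_CODES <- c("MISSING_COLUMN", "EMPTY_ESSENTIAL_CELL",
                  "UNDECLARED_PROTOCOL", "BROKEN_SAMPLE_LINK",
                  "UNKNOWN_VARIABLE_ID", "ORPHAN_DATA_ROW",
                  "DUPLICATE_HEADER", "RAGGED_ROW", "MISSING_FILE",
                  "EXTRA_COLUMN", "EXTERNAL_FILE", "NAMING_CONVENTION",
                  "TRAILING_EMPTY", "TDF_CONFLICT", "OPAQUE_DATA_FILE",
                  "MISSING_GROUP_KEY", "DUPLICATE_VARIABLE_ID", "EMPTY_FILE",
                  "MALFORMED_HEADER")

#' Issue table helpers
#'
#' Validation findings are plain data.frames with a fixed column set so they
#' can be concatenated, sorted and serialised uniformly. `emptyIssues()`
#' returns the zero-row prototype; `issue()` builds one or more rows.
#'
#' @return a data.frame with columns `severity`, `code`, `file`, `row`,
#'   `column`, `message`.
#' @export
emptyIssues <- function() {
    data.frame(severity = character(0), code = character(0),
               file = character(0), row = character(0),
               column = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' @rdname emptyIssues
#' @param severity "error", "warning" or "info".
#' @param code a stable identifier from the documented code list.
#' @param file,row,column issue coordinates; rows are 1-based counting the
#'   header row as row 1, "-" when not applicable; columns are canonical
#'   header text (with an occurrence suffix for repeated headers), "-" when
#'   not applicable.
#' @param message human-readable description.
#' @export
issue <- function(severity, code, file = "-", row = "-", column = "-",
                  message = "") {
    stopifnot(all(severity %in% c("error", "warning", "info")),
              all(code %in% .ISSUE_CODES))
    data.frame(severity = severity, code = code, file = file,
               row = as.character(row), column = column, message = message,
               stringsAsFactors = FALSE)
}

bindIssues <- function(...) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
    if (!length(parts))
        return(emptyIssues())
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

## Deterministic ordering: by file, then numeric row ("-" last), then column.
sortIssues <- function(issues) {
    if (nrow(issues) == 0L)
        return(issues)
    rown <- suppressWarnings(as.numeric(issues$row))
    rown[is.na(rown)] <- Inf
    ord <- order(issues$file, rown, issues$column, issues$code,
                 issues$message)
    out <- issues[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' @describeIn ValidationReport-class extract the issue table.
#' @param object,x a `ValidationReport`.
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))

#' @rdname ValidationReport-class
#' @export
setMethod("issues", "ValidationReport", function(x) x@issues)

#' @rdname ValidationReport-class
#' @param severity restrict the count to one severity level.
#' @export
issueCount <- function(x, severity = NULL) {
    tab <- if (is(x, "ValidationReport")) x@issues else x
    if (!is.null(severity))
        tab <- tab[tab$severity %in% severity, , drop = FALSE]
    nrow(tab)
}

setMethod("show", "ValidationReport", function(object) {
    tab <- object@issues
    cat(sprintf("ValidationReport: %d error(s), %d warning(s), %d info\n",
                sum(tab$severity == "error"),
                sum(tab$severity == "warning"),
                sum(tab$severity == "info")))
    if (nrow(tab))
        print(utils::head(tab, 20L))
})

#' @describeIn ComplianceReport-class overall compliance score.
#' @param x a `ComplianceReport`.
#' @export
complianceScore <- function(x) {
    stopifnot(is(x, "ComplianceReport"))
    x@score
}

#' @describeIn ComplianceReport-class the per-attribute coverage table.
#' @export
complianceTable <- function(x) {
    stopifnot(is(x, "ComplianceReport"))
    x@table
}

setMethod("show", "ComplianceReport", function(object) {
    t <- object@table
    cat(sprintf("ComplianceReport (%s configuration): score %.3f\n",
                object@kind, object@score))
    for (sec in unique(t$section)) {
        s <- t[t$section == sec, , drop = FALSE]
        miss <- s$attribute[!s$present]
        cat(sprintf("  %-42s %d/%d%s\n", sec, sum(s$present), nrow(s),
                    if (length(miss))
                        paste0("  missing: ", paste(miss, collapse = ", "))
                    else ""))
    }
})
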