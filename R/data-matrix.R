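## Derived Data File matrices: the default plain tab-separated
## sample-by-variable dialect, rows keyed by a data-node column (Assay Name
## unless the extension rule is used) and columns keyed by Variable IDs.

.DATA_NODE_LABELS <- unname(.CATEGORY_LABELS[.DATA_NODE_CATEGORIES])

#' Read a Derived Data File matrix
#'
#' The first header cell names the data-node column giving row identity
#' (`Assay Name` by default; any other data node — `Source Name`,
#' `Sample Name`, `Extract Name` — is accepted under the extension rule);
#' the remaining header cells are Variable IDs. Empty cells and the literal
#' token `NA` are missing values. Ragged rows, duplicated row ids and an
#' empty header are errors.
#'
#' @param path path to the file.
#' @param expectedLinkNode if given, the first header cell must equal it.
#' @return a [DataMatrix-class].
#' @export
readDataMatrix <- function(path, expectedLinkNode = NULL) {
    fname <- basename(path)
    lines <- .readTabLines(path)
    lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
    if (length(lines) < 2L)
        stop("data matrix ", fname, " needs a header and at least one row")
    header <- .splitCells(lines[1L])
    if (!nzchar(header[1L]))
        stop("empty header in data matrix ", fname)
    linkNode <- header[1L]
    if (!is.null(expectedLinkNode) && linkNode != expectedLinkNode)
        stop("data matrix ", fname, " links on '", linkNode,
             "', expected '", expectedLinkNode, "'")
    vars <- header[-1L]
    rows <- lapply(lines[-1L], .splitCells)
    lens <- lengths(rows)
    if (any(lens != length(header)))
        stop("ragged row in data matrix ", fname, " (row ",
             which(lens != length(header))[1L] + 1L, ": expected ",
             length(header), " cells, found ",
             lens[lens != length(header)][1L], ")")
    grid <- do.call(rbind, rows)
    ids <- grid[, 1L]
    if (anyDuplicated(ids))
        stop("duplicated row id in data matrix ", fname, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    values <- grid[, -1L, drop = FALSE]
    dimnames(values) <- list(ids, vars)
    DataMatrix(fname, linkNode = linkNode, values = values)
}

#' @rdname readDataMatrix
#' @param matrix a [DataMatrix-class] to serialise.
#' @export
writeDataMatrix <- function(matrix, path) {
    validObject(matrix)
    v <- matrix@values
    lines <- c(.formatCells(c(matrix@linkNode, colnames(v))),
               vapply(seq_len(nrow(v)), function(i)
                   .formatCells(c(rownames(v)[i], v[i, ])), character(1)))
    .writeTextLines(lines, path)
}

#' @describeIn readDataMatrix logical matrix marking missing cells (empty or
#'   literal `NA`).
#' @export
missingMask <- function(matrix) {
    v <- matrix@values
    v == "" | v == "NA"
}

setMethod("show", "DataMatrix", function(object) {
    cat(sprintf("DataMatrix '%s': %d row(s) x %d variable(s), linked on '%s'\n",
                object@sourceFile, nrow(object@values),
                ncol(object@values), object@linkNode))
})

setMethod("dim", "DataMatrix", function(x) dim(x@values))
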