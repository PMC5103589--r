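## Reading and writing ISA-Tab datasets: tab-delimited Study/Assay tables,
## the sectioned key-value Investigation file, and the dataset directory
## layout. Serialisation is deterministic (UTF-8, "\n" line endings, stable
## ordering) so that two writes of the same dataset are byte-identical and
## read(write(d)) is structurally equal to d.

## --- TSV primitives --------------------------------------------------------

.stripCR <- function(lines) sub("\r$", "", lines)

.splitCells <- function(line) {
    ## a sentinel keeps trailing empty cells (strsplit would drop them)
    cells <- strsplit(paste0(line, "\037"), "\t", fixed = TRUE)[[1L]]
    cells[length(cells)] <- sub("\037$", "", cells[length(cells)])
    ## quoted cells: strip the wrapper, un-double inner quotes
    quoted <- nchar(cells) >= 2L & startsWith(cells, "\"") &
              endsWith(cells, "\"")
    cells[quoted] <- gsub("\"\"", "\"",
                          substr(cells[quoted], 2L,
                                 nchar(cells[quoted]) - 1L))
    cells
}

.formatCells <- function(cells) {
    if (any(grepl("[\t\n\r]", cells)))
        stop("cells may not contain tabs or newlines")
    needQuote <- grepl("\"", cells, fixed = TRUE)
    cells[needQuote] <- paste0("\"", gsub("\"", "\"\"", cells[needQuote]),
                               "\"")
    paste(cells, collapse = "\t")
}

.writeTextLines <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

.readTabLines <- function(path) {
    lines <- .stripCR(readLines(path, encoding = "UTF-8", warn = FALSE))
    ## drop a UTF-8 BOM if some other tool left one
    if (length(lines) && startsWith(lines[1L], "﻿"))
        lines[1L] <- sub("^﻿", "", lines[1L])
    lines
}

## --- Study / Assay tables --------------------------------------------------

## Returns list(table = StudyTable/AssayTable or NULL, issues = data.frame).
## Ragged data rows are padded/truncated to the header width and reported as
## RAGGED_ROW errors; trailing all-empty rows and columns are stripped with
## an info entry; header parse failures abort the table with an error issue.
.readTable <- function(path, what = c("study", "assay")) {
    what <- match.arg(what)
    fname <- basename(path)
    iss <- emptyIssues()
    lines <- .readTabLines(path)
    while (length(lines) && !nzchar(lines[length(lines)])) {
        lines <- lines[-length(lines)]
        iss <- bindIssues(iss, issue("info", "TRAILING_EMPTY", fname,
                                     message = "trailing empty row stripped"))
    }
    if (!length(lines))
        return(list(table = NULL,
                    issues = bindIssues(iss, issue("error", "EMPTY_FILE",
                                                   fname,
                                                   message = "empty table file"))))
    cellRows <- lapply(lines, .splitCells)
    headerCells <- cellRows[[1L]]
    while (length(headerCells) && !nzchar(headerCells[length(headerCells)])) {
        headerCells <- headerCells[-length(headerCells)]
        iss <- bindIssues(iss, issue("info", "TRAILING_EMPTY", fname, row = 1,
                                     message = "trailing empty column stripped"))
    }
    headers <- tryCatch(parseHeaders(headerCells), error = function(e) e)
    if (inherits(headers, "error"))
        return(list(table = NULL,
                    issues = bindIssues(iss,
                        issue("error", "MALFORMED_HEADER", fname, row = 1,
                              message = conditionMessage(headers)))))
    ncol <- length(headers)
    rows <- vector("list", length(cellRows) - 1L)
    for (i in seq_along(rows)) {
        cells <- cellRows[[i + 1L]]
        if (length(cells) != ncol) {
            iss <- bindIssues(iss, issue("error", "RAGGED_ROW", fname,
                row = i + 1L,
                column = as.character(min(length(cells) + 1L, ncol)),
                message = sprintf("expected %d cells, found %d", ncol,
                                  length(cells))))
            cells <- c(cells, character(ncol))[seq_len(ncol)]
        }
        rows[[i]] <- cells
    }
    ctor <- if (what == "study") StudyTable else AssayTable
    tab <- tryCatch(ctor(fname, headers, rows), error = function(e) e)
    if (inherits(tab, "error"))
        return(list(table = NULL,
                    issues = bindIssues(iss,
                        issue("error", "MALFORMED_HEADER", fname, row = 1,
                              message = conditionMessage(tab)))))
    list(table = tab, issues = iss)
}

.writeTable <- function(table, path) {
    validObject(table)
    lines <- .formatCells(headerTexts(table@headers))
    if (nrow(table@rows))
        lines <- c(lines, apply(table@rows, 1L, .formatCells))
    .writeTextLines(lines, path)
}

## --- Investigation file ----------------------------------------------------

.INV_SECTIONS <- c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION",
                   "INVESTIGATION PUBLICATIONS", "INVESTIGATION CONTACTS",
                   "STUDY", "STUDY DESIGN DESCRIPTORS", "STUDY PUBLICATIONS",
                   "STUDY FACTORS", "STUDY ASSAYS", "STUDY PROTOCOLS",
                   "STUDY CONTACTS")

.kvLine <- function(key, values) {
    .formatCells(c(key, as.character(values)))
}

.dfColumns <- function(df, keys, fields) {
    vapply(seq_along(keys), function(i)
        .kvLine(keys[i], df[[fields[i]]]), character(1))
}

writeInvestigation <- function(inv, path) {
    validObject(inv)
    lines <- c(
        "ONTOLOGY SOURCE REFERENCE",
        .dfColumns(inv@ontologySources,
                   c("Term Source Name", "Term Source File",
                     "Term Source Version", "Term Source Description"),
                   c("name", "file", "version", "description")),
        "INVESTIGATION",
        .kvLine("Investigation Identifier", inv@identifier),
        .kvLine("Investigation Title", inv@title),
        .kvLine("Investigation Description", inv@description),
        .kvLine("Investigation Submission Date", inv@submissionDate),
        .kvLine("Investigation Public Release Date", inv@publicReleaseDate),
        "INVESTIGATION PUBLICATIONS",
        .dfColumns(inv@publications,
                   c("Investigation PubMed ID",
                     "Investigation Publication DOI",
                     "Investigation Publication Author List",
                     "Investigation Publication Title",
                     "Investigation Publication Status"),
                   c("pubmedID", "doi", "authorList", "title", "status")),
        "INVESTIGATION CONTACTS",
        .dfColumns(inv@contacts,
                   c("Investigation Person Last Name",
                     "Investigation Person First Name",
                     "Investigation Person Email",
                     "Investigation Person Affiliation"),
                   c("lastName", "firstName", "email", "affiliation")))
    for (st in inv@studies) {
        lines <- c(lines,
            "STUDY",
            .kvLine("Study Identifier", st@identifier),
            .kvLine("Study Title", st@title),
            .kvLine("Study Description", st@description),
            .kvLine("Study Submission Date", st@submissionDate),
            .kvLine("Study Public Release Date", st@publicReleaseDate),
            .kvLine("Study File Name", st@fileName),
            "STUDY DESIGN DESCRIPTORS",
            .kvLine("Study Design Type", st@designDescriptors),
            "STUDY PUBLICATIONS",
            .kvLine("Study PubMed ID", character(0)),
            "STUDY FACTORS",
            .dfColumns(st@factors,
                       c("Study Factor Name", "Study Factor Type"),
                       c("name", "type")),
            "STUDY ASSAYS",
            .kvLine("Study Assay File Name", st@assayFiles),
            .kvLine("Study Assay Measurement Type",
                    rep("phenotyping", length(st@assayFiles))),
            "STUDY PROTOCOLS",
            .dfColumns(st@protocols,
                       c("Study Protocol Name", "Study Protocol Type",
                         "Study Protocol Description",
                         "Study Protocol Parameters Name"),
                       c("name", "type", "description", "parameters")),
            "STUDY CONTACTS",
            .dfColumns(st@contacts,
                       c("Study Person Last Name",
                         "Study Person First Name", "Study Person Email",
                         "Study Person Affiliation"),
                       c("lastName", "firstName", "email", "affiliation")))
    }
    .writeTextLines(lines, path)
}

.sectionValues <- function(block, key, default = character(0)) {
    hit <- which(vapply(block, function(x) x$key == key, logical(1)))
    if (!length(hit))
        return(default)
    block[[hit[1L]]]$values
}

.scalarValue <- function(block, key) {
    v <- .sectionValues(block, key)
    if (length(v)) v[1L] else ""
}

.sectionDF <- function(block, keys, fields) {
    cols <- lapply(keys, function(k) .sectionValues(block, k))
    n <- max(c(0L, lengths(cols)))
    cols <- lapply(cols, function(x) c(x, rep("", n - length(x))))
    setNames(as.data.frame(cols, stringsAsFactors = FALSE,
                           col.names = fields),
             fields)
}

readInvestigation <- function(path) {
    lines <- .readTabLines(path)
    lines <- lines[nzchar(lines)]
    ## split into (section, key-value) structure preserving STUDY repetition
    sections <- list()
    current <- NULL
    for (line in lines) {
        cells <- .splitCells(line)
        if (length(cells) == 1L && cells[1L] %in% .INV_SECTIONS) {
            if (!is.null(current))
                sections[[length(sections) + 1L]] <- current
            current <- list(name = cells[1L], entries = list())
        } else {
            if (is.null(current))
                stop("investigation content before any section label in ",
                     basename(path))
            current$entries[[length(current$entries) + 1L]] <-
                list(key = cells[1L],
                     values = if (length(cells) > 1L) cells[-1L]
                              else character(0))
        }
    }
    if (!is.null(current))
        sections[[length(sections) + 1L]] <- current
    secNames <- vapply(sections, `[[`, character(1), "name")
    entriesOf <- function(name) {
        i <- which(secNames == name)
        if (length(i)) sections[[i[1L]]]$entries else list()
    }
    invEntries <- entriesOf("INVESTIGATION")
    inv <- Investigation(
        identifier = .scalarValue(invEntries, "Investigation Identifier"),
        title = .scalarValue(invEntries, "Investigation Title"),
        description = .scalarValue(invEntries, "Investigation Description"),
        submissionDate = .scalarValue(invEntries,
                                      "Investigation Submission Date"),
        publicReleaseDate = .scalarValue(invEntries,
                                         "Investigation Public Release Date"),
        ontologySources = .sectionDF(entriesOf("ONTOLOGY SOURCE REFERENCE"),
            c("Term Source Name", "Term Source File", "Term Source Version",
              "Term Source Description"),
            c("name", "file", "version", "description")),
        publications = .sectionDF(entriesOf("INVESTIGATION PUBLICATIONS"),
            c("Investigation PubMed ID", "Investigation Publication DOI",
              "Investigation Publication Author List",
              "Investigation Publication Title",
              "Investigation Publication Status"),
            c("pubmedID", "doi", "authorList", "title", "status")),
        contacts = .sectionDF(entriesOf("INVESTIGATION CONTACTS"),
            c("Investigation Person Last Name",
              "Investigation Person First Name",
              "Investigation Person Email",
              "Investigation Person Affiliation"),
            c("lastName", "firstName", "email", "affiliation")))
    ## study blocks: a STUDY section opens a block running to the next STUDY
    studyStarts <- which(secNames == "STUDY")
    studies <- list()
    for (k in seq_along(studyStarts)) {
        from <- studyStarts[k]
        to <- if (k < length(studyStarts)) studyStarts[k + 1L] - 1L
              else length(sections)
        blockSections <- sections[from:to]
        blockNames <- vapply(blockSections, `[[`, character(1), "name")
        blockOf <- function(name) {
            i <- which(blockNames == name)
            if (length(i)) blockSections[[i[1L]]]$entries else list()
        }
        se <- blockOf("STUDY")
        studies[[k]] <- StudyRecord(
            fileName = .scalarValue(se, "Study File Name"),
            identifier = .scalarValue(se, "Study Identifier"),
            title = .scalarValue(se, "Study Title"),
            description = .scalarValue(se, "Study Description"),
            submissionDate = .scalarValue(se, "Study Submission Date"),
            publicReleaseDate = .scalarValue(se,
                                             "Study Public Release Date"),
            designDescriptors = .sectionValues(
                blockOf("STUDY DESIGN DESCRIPTORS"), "Study Design Type"),
            factors = .sectionDF(blockOf("STUDY FACTORS"),
                c("Study Factor Name", "Study Factor Type"),
                c("name", "type")),
            assayFiles = .sectionValues(blockOf("STUDY ASSAYS"),
                                        "Study Assay File Name"),
            protocols = .sectionDF(blockOf("STUDY PROTOCOLS"),
                c("Study Protocol Name", "Study Protocol Type",
                  "Study Protocol Description",
                  "Study Protocol Parameters Name"),
                c("name", "type", "description", "parameters")),
            contacts = .sectionDF(blockOf("STUDY CONTACTS"),
                c("Study Person Last Name", "Study Person First Name",
                  "Study Person Email", "Study Person Affiliation"),
                c("lastName", "firstName", "email", "affiliation")))
    }
    inv@studies <- studies
    validObject(inv)
    inv
}

## --- referenced-file discovery ---------------------------------------------

.columnCells <- function(table, category, qualifier = NULL) {
    cats <- headerCategories(table@headers)
    idx <- which(cats == category)
    if (!is.null(qualifier)) {
        quals <- headerQualifiers(table@headers)
        idx <- idx[quals[idx] == qualifier]
    }
    if (!length(idx) || nrow(table@rows) == 0L)
        return(character(0))
    as.character(table@rows[, idx, drop = TRUE])
}

.referencedFiles <- function(assay) {
    list(tdf = unique(.columnCells(assay, "PARAMETER_VALUE",
                                   "Trait Definition File")),
         derived = unique(.columnCells(assay, "DERIVED_DATA_FILE")),
         raw = unique(.columnCells(assay, "RAW_DATA_FILE")))
}

## --- dataset read / write --------------------------------------------------

#' Read an ISA-Tab dataset directory
#'
#' Loads the single `i_*.txt` Investigation file, every Study and Assay
#' file it names, and the Trait Definition Files and Derived Data Files
#' referenced from the assays. Referenced files absent from the directory
#' are recorded in `externalFiles`; every parse problem (ragged rows,
#' malformed headers, unreadable files) is collected into the dataset's
#' `parseIssues` table rather than silently dropped. Files that do not
#' follow the `i_*`/`s_*`/`a_*` naming convention are warned about.
#'
#' @param directory path to the dataset directory.
#' @return a [PhenoDataset-class].
#' @seealso [writeDataset()], [validateDataset()]
#' @export
readDataset <- function(directory) {
    if (!dir.exists(directory))
        stop("no such directory: ", directory)
    files <- list.files(directory)
    invFiles <- files[grepl("^i_.*\\.txt$", files)]
    if (length(invFiles) == 0L)
        stop("no investigation file (i_*.txt) in ", directory)
    if (length(invFiles) > 1L)
        stop("multiple investigation files in ", directory, ": ",
             paste(invFiles, collapse = ", "))
    iss <- emptyIssues()
    inv <- readInvestigation(file.path(directory, invFiles))
    studies <- list()
    assays <- list()
    for (st in inv@studies) {
        for (fn in c(st@fileName, st@assayFiles)) {
            isStudy <- fn == st@fileName
            prefix <- if (isStudy) "s_" else "a_"
            if (!startsWith(fn, prefix))
                iss <- bindIssues(iss, issue("warning", "NAMING_CONVENTION",
                    fn, message = sprintf(
                        "file name does not start with '%s'", prefix)))
            path <- file.path(directory, fn)
            if (!file.exists(path)) {
                iss <- bindIssues(iss, issue("error", "MISSING_FILE",
                    fn, message = sprintf(
                        "%s file named in the investigation is absent",
                        if (isStudy) "study" else "assay")))
                next
            }
            got <- .readTable(path, if (isStudy) "study" else "assay")
            iss <- bindIssues(iss, got$issues)
            if (!is.null(got$table)) {
                if (isStudy)
                    studies[[fn]] <- got$table
                else
                    assays[[fn]] <- got$table
            }
        }
    }
    tdfs <- list()
    matrices <- list()
    external <- character(0)
    for (assay in assays) {
        refs <- .referencedFiles(assay)
        for (fn in setdiff(refs$tdf[nzchar(refs$tdf)], names(tdfs))) {
            path <- file.path(directory, fn)
            if (!file.exists(path)) {
                external <- union(external, fn)
                next
            }
            got <- tryCatch(readTDF(path), error = function(e) e)
            if (inherits(got, "error"))
                iss <- bindIssues(iss, issue("error", "MALFORMED_HEADER",
                    fn, message = conditionMessage(got)))
            else
                tdfs[[fn]] <- got
        }
        for (fn in setdiff(refs$derived[nzchar(refs$derived)],
                           names(matrices))) {
            path <- file.path(directory, fn)
            if (!file.exists(path)) {
                external <- union(external, fn)
                next
            }
            got <- tryCatch(readDataMatrix(path), error = function(e) e)
            if (inherits(got, "error"))
                iss <- bindIssues(iss, issue("error", "MALFORMED_HEADER",
                    fn, message = conditionMessage(got)))
            else
                matrices[[fn]] <- got
        }
        external <- union(external,
            Filter(function(fn) nzchar(fn) &&
                       !file.exists(file.path(directory, fn)), refs$raw))
    }
    PhenoDataset(investigation = inv, studies = studies, assays = assays,
                 traitDefinitions = tdfs, dataFiles = matrices,
                 externalFiles = sort(external), rootDir = directory,
                 parseIssues = sortIssues(iss))
}

#' Write an ISA-Tab dataset directory
#'
#' Serialises a dataset to tab-delimited UTF-8 files with "\n" line endings.
#' The dataset invariants are verified before any file is written; file
#' names must follow the `i_*`/`s_*`/`a_*` convention. Two writes of the
#' same dataset are byte-identical, and `readDataset(writeDataset(d))` is
#' structurally equal to `d`.
#'
#' @param dataset a [PhenoDataset-class].
#' @param directory target directory (created if absent).
#' @param investigationFile name for the investigation file.
#' @return invisibly, a list describing the file layout (`investigation`,
#'   `studies`, `assays`, `traitDefinitions`, `dataFiles`).
#' @export
writeDataset <- function(dataset, directory,
                         investigationFile = "i_investigation.txt") {
    stopifnot(is(dataset, "PhenoDataset"))
    validObject(dataset@investigation)
    for (tab in c(dataset@studies, dataset@assays))
        validObject(tab)
    for (x in dataset@traitDefinitions)
        validObject(x)
    for (x in dataset@dataFiles)
        validObject(x)
    if (!startsWith(investigationFile, "i_"))
        stop("investigation file name must start with 'i_'")
    for (fn in names(dataset@studies))
        if (!startsWith(fn, "s_"))
            stop("study file name must start with 's_': ", fn)
    for (fn in names(dataset@assays))
        if (!startsWith(fn, "a_"))
            stop("assay file name must start with 'a_': ", fn)
    if (!dir.exists(directory))
        dir.create(directory, recursive = TRUE)
    writeInvestigation(dataset@investigation,
                       file.path(directory, investigationFile))
    for (fn in names(dataset@studies))
        .writeTable(dataset@studies[[fn]], file.path(directory, fn))
    for (fn in names(dataset@assays))
        .writeTable(dataset@assays[[fn]], file.path(directory, fn))
    for (fn in names(dataset@traitDefinitions))
        writeTDF(dataset@traitDefinitions[[fn]], file.path(directory, fn))
    for (fn in names(dataset@dataFiles))
        writeDataMatrix(dataset@dataFiles[[fn]], file.path(directory, fn))
    invisible(list(investigation = investigationFile,
                   studies = names(dataset@studies),
                   assays = names(dataset@assays),
                   traitDefinitions = names(dataset@traitDefinitions),
                   dataFiles = names(dataset@dataFiles)))
}

## --- structural equality ---------------------------------------------------

.sortByName <- function(x) if (length(x)) x[order(names(x))] else x

.canonicalTable <- function(t) {
    rows <- t@rows
    dimnames(rows) <- NULL
    list(file = t@sourceFile, headers = headerTexts(t@headers), rows = rows)
}

.canonicalDataset <- function(d) {
    inv <- d@investigation
    list(
        investigation = list(
            identifier = inv@identifier, title = inv@title,
            description = inv@description,
            submissionDate = inv@submissionDate,
            publicReleaseDate = inv@publicReleaseDate,
            ontologySources = inv@ontologySources,
            publications = inv@publications, contacts = inv@contacts,
            studies = lapply(inv@studies, function(s) list(
                fileName = s@fileName, identifier = s@identifier,
                title = s@title, description = s@description,
                submissionDate = s@submissionDate,
                publicReleaseDate = s@publicReleaseDate,
                designDescriptors = s@designDescriptors,
                factors = s@factors, assayFiles = s@assayFiles,
                protocols = s@protocols, contacts = s@contacts))),
        studies = lapply(.sortByName(d@studies), .canonicalTable),
        assays = lapply(.sortByName(d@assays), .canonicalTable),
        tdfs = lapply(.sortByName(d@traitDefinitions),
                      function(x) list(file = x@sourceFile, defs = x@defs)),
        dataFiles = lapply(.sortByName(d@dataFiles),
                           function(x) list(file = x@sourceFile,
                                            linkNode = x@linkNode,
                                            values = x@values)))
}

#' Structural equality of two datasets
#'
#' Compares header sequences, cell values, investigation records, trait
#' definitions and data matrices; ignores the root directory and read-time
#' issue tables.
#'
#' @param a,b [PhenoDataset-class] objects.
#' @return `TRUE` or a character vector of differences (as [all.equal()]).
#' @export
datasetEqual <- function(a, b) {
    all.equal(.canonicalDataset(a), .canonicalDataset(b))
}

setMethod("show", "PhenoDataset", function(object) {
    cat(sprintf(
        "PhenoDataset: %d stud%s, %d assay(s), %d trait definition file(s), %d data file(s)\n",
        length(object@studies),
        if (length(object@studies) == 1L) "y" else "ies",
        length(object@assays), length(object@traitDefinitions),
        length(object@dataFiles)))
    if (nzchar(object@rootDir))
        cat("  read from:", object@rootDir, "\n")
    if (length(object@externalFiles))
        cat("  external files:", length(object@externalFiles), "\n")
    if (nrow(object@parseIssues))
        cat("  parse issues:", nrow(object@parseIssues), "\n")
})
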