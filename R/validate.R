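## Structural validation against a configuration, cross-file link integrity,
## and MIAPPE compliance reporting. All findings are returned as coded
## issues, never raised; empty required cells are warnings (published
## datasets legitimately ship with them) while absent required columns are
## errors.

## Locate the protocol blocks of a table: each Protocol REF column opens a
## block that runs to the next Protocol REF column (or a closing data node);
## the block's name is its column's modal non-empty cell value.
.tableBlocks <- function(table) {
    cats <- headerCategories(table@headers)
    starts <- which(cats == "PROTOCOL_REF")
    blocks <- list()
    for (k in seq_along(starts)) {
        from <- starts[k]
        to <- if (k < length(starts)) starts[k + 1L] - 1L else length(cats)
        vals <- if (nrow(table@rows)) table@rows[, from] else character(0)
        vals <- vals[nzchar(vals)]
        name <- if (length(vals)) names(sort(table(vals),
                                             decreasing = TRUE))[1L] else ""
        blocks[[k]] <- list(refCol = from,
                            paramCols = which(cats == "PARAMETER_VALUE" &
                                              seq_along(cats) >= from &
                                              seq_along(cats) <= to),
                            name = name)
    }
    blocks
}

.columnLabel <- function(texts, i) {
    occ <- sum(texts[seq_len(i)] == texts[i])
    if (sum(texts == texts[i]) > 1L)
        sprintf("%s#%d", texts[i], occ)
    else
        texts[i]
}

.emptyCellWarnings <- function(table, col, fname) {
    if (nrow(table@rows) == 0L)
        return(emptyIssues())
    empty <- which(!nzchar(table@rows[, col]))
    if (!length(empty))
        return(emptyIssues())
    texts <- headerTexts(table@headers)
    issue("warning", "EMPTY_ESSENTIAL_CELL", fname, row = empty + 1L,
          column = .columnLabel(texts, col),
          message = "empty cell in a required column")
}

#' Validate one Study/Assay table against a configuration schema
#'
#' Reports `MISSING_COLUMN` errors for required planned headers that are
#' absent (a missing protocol block yields one error for its Protocol REF
#' column and one per required parameter), `DUPLICATE_HEADER` errors for
#' repeated property columns, `EMPTY_ESSENTIAL_CELL` warnings for empty
#' cells in required planned columns, `UNDECLARED_PROTOCOL` warnings for
#' Protocol REF cell values not declared in the investigation (when
#' `declaredProtocols` is supplied), and `EXTRA_COLUMN` info entries for
#' well-formed columns outside the plan.
#'
#' @param table a [StudyTable-class] or [AssayTable-class].
#' @param config the matching [StudyConfig-class] or [AssayConfig-class].
#' @param declaredProtocols protocol names declared in the investigation for
#'   this study, or `NULL` to skip the declaration check.
#' @return a data.frame of issues (see [emptyIssues()]).
#' @export
validateTable <- function(table, config, declaredProtocols = NULL) {
    stopifnot(is(table, "IsaTable"), is(config, "PhenoConfig"))
    fname <- table@sourceFile
    iss <- emptyIssues()
    texts <- headerTexts(table@headers)
    cats <- headerCategories(table@headers)
    quals <- headerQualifiers(table@headers)
    blocks <- .tableBlocks(table)
    hasRows <- nrow(table@rows) > 0L

    ## duplicated headers: property columns and data nodes may not repeat
    ## (Parameter Values are scoped to their protocol block; Protocol REF,
    ## Unit and term columns repeat legitimately)
    dupIdx <- integer(0)
    flat <- cats %in% c("CHARACTERISTICS", "FACTOR_VALUE", "COMMENT",
                        .DATA_NODE_CATEGORIES,
                        "RAW_DATA_FILE", "DERIVED_DATA_FILE")
    sig <- ifelse(flat, texts, NA_character_)
    dupIdx <- which(!is.na(sig) & duplicated(sig))
    for (b in blocks) {
        pq <- quals[b$paramCols]
        dupIdx <- c(dupIdx, b$paramCols[duplicated(pq)])
    }
    for (i in sort(unique(dupIdx)))
        iss <- bindIssues(iss, issue("error", "DUPLICATE_HEADER", fname,
            row = 1L, column = .columnLabel(texts, i),
            message = sprintf("duplicated column '%s'", texts[i])))

    plan <- config@plan
    matchedCols <- integer(0)

    ## protocol blocks: match planned blocks to actual ones by cell value
    ## (positionally when the table has no rows yet)
    plannedBlocks <- unique(plan$protocol[plan$category == "PROTOCOL_REF"])
    usedBlocks <- logical(length(blocks))
    for (k in seq_along(plannedBlocks)) {
        pname <- plannedBlocks[k]
        prow <- which(plan$category == "PROTOCOL_REF" &
                      plan$protocol == pname)
        params <- plan[plan$category == "PARAMETER_VALUE" &
                       plan$protocol == pname, , drop = FALSE]
        hit <- if (hasRows)
            which(!usedBlocks &
                  vapply(blocks, `[[`, character(1), "name") == pname)
        else
            which(!usedBlocks)
        if (!length(hit)) {
            if (plan$required[prow])
                iss <- bindIssues(iss, issue("error", "MISSING_COLUMN",
                    fname, column = sprintf("Protocol REF (%s)", pname),
                    message = sprintf("protocol block '%s' is absent",
                                      pname)))
            for (j in seq_len(nrow(params)))
                if (params$required[j])
                    iss <- bindIssues(iss, issue("error", "MISSING_COLUMN",
                        fname, column = params$header[j],
                        message = sprintf(
                            "parameter '%s' of absent protocol '%s'",
                            params$qualifier[j], pname)))
            next
        }
        hit <- hit[1L]
        usedBlocks[hit] <- TRUE
        b <- blocks[[hit]]
        matchedCols <- c(matchedCols, b$refCol)
        iss <- bindIssues(iss, .emptyCellWarnings(table, b$refCol, fname))
        blockQuals <- quals[b$paramCols]
        for (j in seq_len(nrow(params))) {
            at <- b$paramCols[match(params$qualifier[j], blockQuals)]
            if (is.na(at)) {
                if (params$required[j])
                    iss <- bindIssues(iss, issue("error", "MISSING_COLUMN",
                        fname, column = params$header[j],
                        message = sprintf(
                            "parameter '%s' missing from protocol '%s'",
                            params$qualifier[j], pname)))
                next
            }
            matchedCols <- c(matchedCols, at)
            if (params$required[j])
                iss <- bindIssues(iss, .emptyCellWarnings(table, at, fname))
            if (params$unitFollows[j]) {
                if (at + 1L <= length(cats) && cats[at + 1L] == "UNIT")
                    matchedCols <- c(matchedCols, at + 1L)
                else
                    iss <- bindIssues(iss, issue("error", "MISSING_COLUMN",
                        fname, column = "Unit",
                        message = sprintf("Unit column after '%s' is absent",
                                          params$header[j])))
            }
        }
    }

    ## non-protocol planned columns, matched by canonical header text
    flatPlan <- plan[!plan$category %in% c("PROTOCOL_REF",
                                           "PARAMETER_VALUE"), ,
                     drop = FALSE]
    for (j in seq_len(nrow(flatPlan))) {
        at <- match(flatPlan$header[j], texts)
        if (is.na(at)) {
            if (flatPlan$required[j])
                iss <- bindIssues(iss, issue("error", "MISSING_COLUMN",
                    fname, column = flatPlan$header[j],
                    message = sprintf("required column '%s' is absent",
                                      flatPlan$header[j])))
            next
        }
        matchedCols <- c(matchedCols, at)
        if (flatPlan$required[j])
            iss <- bindIssues(iss, .emptyCellWarnings(table, at, fname))
    }

    ## undeclared protocols
    if (!is.null(declaredProtocols) && hasRows)
        for (b in blocks) {
            vals <- unique(table@rows[, b$refCol])
            vals <- vals[nzchar(vals)]
            for (v in setdiff(vals, declaredProtocols))
                iss <- bindIssues(iss, issue("warning",
                    "UNDECLARED_PROTOCOL", fname,
                    row = which(table@rows[, b$refCol] == v)[1L] + 1L,
                    column = .columnLabel(texts, b$refCol),
                    message = sprintf(
                        "protocol '%s' is not declared in the investigation",
                        v)))
        }

    ## extra well-formed columns outside the plan are informational
    qualifierCols <- which(cats %in% c("UNIT", "TERM_SOURCE_REF",
                                       "TERM_ACCESSION_NUMBER"))
    unplanned <- setdiff(seq_along(texts),
                         c(matchedCols, qualifierCols, dupIdx))
    for (i in unplanned)
        iss <- bindIssues(iss, issue("info", "EXTRA_COLUMN", fname,
            row = 1L, column = .columnLabel(texts, i),
            message = sprintf("column '%s' is not part of the '%s' schema",
                              texts[i], config@name)))
    sortIssues(iss)
}

## ---------------------------------------------------------------------------

.studyOfAssay <- function(investigation, assayFile) {
    for (st in investigation@studies)
        if (assayFile %in% st@assayFiles)
            return(st)
    NULL
}

.nodeColumn <- function(table, label) {
    texts <- headerTexts(table@headers)
    match(label, texts)
}

#' Cross-file link integrity of a dataset
#'
#' Checks the sample chain (every assay `Sample Name` must appear in the
#' `Sample Name` column of its study: `BROKEN_SAMPLE_LINK`), the variable
#' chain (every data-matrix column must be declared in the linked Trait
#' Definition File: `UNKNOWN_VARIABLE_ID`; matrix rows whose id is absent
#' from the linking data-node column: `ORPHAN_DATA_ROW` warnings), and file
#' references (absent Trait Definition Files and Derived Data Files:
#' `MISSING_FILE` errors; absent Raw Data Files are flagged external,
#' `EXTERNAL_FILE` info).
#'
#' @param dataset a [PhenoDataset-class].
#' @return a data.frame of issues.
#' @export
validateLinks <- function(dataset) {
    iss <- emptyIssues()
    inv <- dataset@investigation
    for (afn in names(dataset@assays)) {
        assay <- dataset@assays[[afn]]
        texts <- headerTexts(assay@headers)
        st <- .studyOfAssay(inv, afn)
        study <- if (!is.null(st)) dataset@studies[[st@fileName]] else NULL
        ## sample chain
        if (!is.null(study) && nrow(assay@rows)) {
            scol <- .nodeColumn(study, "Sample Name")
            acol <- .nodeColumn(assay, "Sample Name")
            if (!is.na(scol) && !is.na(acol)) {
                known <- study@rows[, scol]
                bad <- which(!assay@rows[, acol] %in% known)
                for (i in bad)
                    iss <- bindIssues(iss, issue("error",
                        "BROKEN_SAMPLE_LINK", afn, row = i + 1L,
                        column = "Sample Name",
                        message = sprintf(
                            "sample '%s' is not defined in study file '%s'",
                            assay@rows[i, acol], st@fileName)))
            }
        }
        ## file references
        refs <- .referencedFiles(assay)
        for (fn in setdiff(refs$tdf[nzchar(refs$tdf)],
                           names(dataset@traitDefinitions)))
            iss <- bindIssues(iss, issue("error", "MISSING_FILE", afn,
                column = "Parameter Value[Trait Definition File]",
                message = sprintf(
                    "trait definition file '%s' is referenced but not present",
                    fn)))
        for (fn in setdiff(refs$derived[nzchar(refs$derived)],
                           names(dataset@dataFiles)))
            iss <- bindIssues(iss, issue("error", "MISSING_FILE", afn,
                column = "Derived Data File",
                message = sprintf(
                    "derived data file '%s' is referenced but not present",
                    fn)))
        ext <- refs$raw[nzchar(refs$raw) & refs$raw %in%
                        dataset@externalFiles]
        if (length(ext))
            iss <- bindIssues(iss, issue("info", "EXTERNAL_FILE", afn,
                column = "Raw Data File",
                message = sprintf("%d referenced raw data file(s) are external",
                                  length(ext))))
        ## variable chain for each derived matrix referenced here
        tdfLoaded <- intersect(refs$tdf, names(dataset@traitDefinitions))
        knownVars <- unique(unlist(lapply(
            dataset@traitDefinitions[tdfLoaded], variableIds)))
        for (fn in intersect(refs$derived, names(dataset@dataFiles))) {
            m <- dataset@dataFiles[[fn]]
            if (length(tdfLoaded))
                for (v in setdiff(colnames(m@values), knownVars))
                    iss <- bindIssues(iss, issue("error",
                        "UNKNOWN_VARIABLE_ID", fn, row = 1L, column = v,
                        message = sprintf(
                            "variable '%s' is not defined in %s", v,
                            paste(tdfLoaded, collapse = ", "))))
            linkCol <- .nodeColumn(assay, m@linkNode)
            linkTable <- assay
            if (is.na(linkCol) && !is.null(study)) {
                linkCol <- .nodeColumn(study, m@linkNode)
                linkTable <- study
            }
            if (is.na(linkCol)) {
                iss <- bindIssues(iss, issue("error", "MISSING_COLUMN", fn,
                    column = m@linkNode,
                    message = sprintf(
                        "link node column '%s' not found in assay or study",
                        m@linkNode)))
                next
            }
            ids <- linkTable@rows[, linkCol]
            orphan <- which(!rownames(m@values) %in% ids)
            for (i in orphan)
                iss <- bindIssues(iss, issue("warning", "ORPHAN_DATA_ROW",
                    fn, row = i + 1L, column = m@linkNode,
                    message = sprintf(
                        "row id '%s' does not occur in the '%s' column",
                        rownames(m@values)[i], m@linkNode)))
        }
    }
    sortIssues(iss)
}

## ---------------------------------------------------------------------------

.protocolPresent <- function(dataset, protocolName) {
    for (study in dataset@studies)
        for (b in .tableBlocks(study))
            if (identical(b$name, protocolName) && length(b$paramCols) &&
                nrow(study@rows) &&
                any(nzchar(study@rows[, b$paramCols])))
                return(TRUE)
    FALSE
}

.characteristicPresent <- function(tables, qualifier) {
    header <- paste0("Characteristics[", qualifier, "]")
    for (t in tables) {
        at <- match(header, headerTexts(t@headers))
        if (!is.na(at) && nrow(t@rows) && any(nzchar(t@rows[, at])))
            return(TRUE)
    }
    FALSE
}

.tdfRowsComplete <- function(dataset, classes) {
    for (tdf in dataset@traitDefinitions) {
        d <- tdf@defs
        hit <- d$variable_class %in% classes & nzchar(d$trait) &
               nzchar(d$method) & nzchar(d$scale)
        if (any(hit))
            return(TRUE)
    }
    FALSE
}

#' MIAPPE compliance report for a dataset
#'
#' An essential attribute is "present" when its mapped ISA-Tab location (an
#' investigation field, a Characteristics column, a protocol block's
#' parameter values, a data-file reference column, or Trait Definition File
#' rows) exists with at least one non-empty value. Applicability follows
#' the configuration kind: the environment protocols and the Sampling
#' protocol apply only under the Field and Greenhouse schemas, and
#' environmental variable definitions apply only when a Trait Definition
#' File declares an environmental variable. The score is the unweighted
#' fraction of applicable essential attributes present.
#'
#' @param dataset a [PhenoDataset-class].
#' @param kind "basic", "field" or "greenhouse" (or a [StudyConfig-class],
#'   whose kind is used).
#' @return a [ComplianceReport-class].
#' @export
miappeCompliance <- function(dataset, kind = "basic") {
    if (is(kind, "PhenoConfig"))
        kind <- kind@kind
    if (!kind %in% c("basic", "field", "greenhouse"))
        stop("unknown configuration kind: '", kind, "'")
    ess <- .essentialsFor(kind)
    envDeclared <- any(vapply(dataset@traitDefinitions, function(t)
        any(t@defs$variable_class == "environmental"), logical(1)))
    keep <- !ess$conditional | envDeclared
    ess <- ess[keep, , drop = FALSE]
    inv <- dataset@investigation
    present <- logical(nrow(ess))
    for (i in seq_len(nrow(ess))) {
        present[i] <- switch(ess$type[i],
            field = nzchar(slot(inv, ess$target[i])),
            characteristic = .characteristicPresent(
                if (ess$level[i] == "study") dataset@studies
                else dataset@assays, ess$target[i]),
            protocol = .protocolPresent(dataset, ess$target[i]),
            datafile = any(vapply(dataset@assays, function(a) {
                cells <- .columnCells(a, "DERIVED_DATA_FILE")
                any(nzchar(cells))
            }, logical(1))),
            tdf_phenotypic = .tdfRowsComplete(dataset,
                c("phenotypic", "unspecified")),
            tdf_environmental = .tdfRowsComplete(dataset, "environmental"),
            FALSE)
    }
    tab <- data.frame(section = ess$section, attribute = ess$attribute,
                      present = present, stringsAsFactors = FALSE)
    score <- if (nrow(tab)) sum(tab$present) / nrow(tab) else 1
    new("ComplianceReport", kind = kind, table = tab, score = score)
}

## ---------------------------------------------------------------------------

#' Validate a dataset end to end
#'
#' Concatenates read-time parse issues, per-table structural findings
#' against the study and assay schemas, cross-file link findings, and the
#' MIAPPE compliance report, with deterministic issue ordering (by file,
#' row, column).
#'
#' @param dataset a [PhenoDataset-class].
#' @param config "basic", "field", "greenhouse" or a [StudyConfig-class]
#'   (e.g. an extended schema from [extendConfig()] or [readConfigFile()]).
#' @param assayConfig schema for the assay files; defaults to
#'   [phenotypingAssayConfig()].
#' @return a list with elements `validation` ([ValidationReport-class]) and
#'   `compliance` ([ComplianceReport-class]).
#' @export
validateDataset <- function(dataset, config = "basic",
                            assayConfig = phenotypingAssayConfig()) {
    stopifnot(is(dataset, "PhenoDataset"))
    if (is.character(config))
        config <- builtinConfig(config)
    iss <- dataset@parseIssues
    inv <- dataset@investigation
    for (st in inv@studies) {
        declared <- st@protocols$name
        study <- dataset@studies[[st@fileName]]
        if (!is.null(study))
            iss <- bindIssues(iss, validateTable(study, config, declared))
        for (afn in st@assayFiles) {
            assay <- dataset@assays[[afn]]
            if (!is.null(assay))
                iss <- bindIssues(iss,
                                  validateTable(assay, assayConfig,
                                                declared))
        }
    }
    iss <- bindIssues(iss, validateLinks(dataset))
    list(validation = ValidationReport(sortIssues(iss)),
         compliance = miappeCompliance(dataset, config@kind))
}

## --- report output ---------------------------------------------------------

#' Serialise validation + compliance reports
#'
#' `reportJSON` renders the machine-readable document (an `issues` array and
#' a `compliance` object with per-attribute coverage and the overall
#' score); `reportText` renders the human-readable form.
#'
#' @param validation a [ValidationReport-class].
#' @param compliance a [ComplianceReport-class].
#' @return `reportJSON`: a JSON string; `reportText`: a character vector of
#'   lines.
#' @export
reportJSON <- function(validation, compliance) {
    doc <- list(
        issues = validation@issues,
        compliance = list(
            kind = compliance@kind,
            score = compliance@score,
            attributes = compliance@table))
    jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                     pretty = TRUE)
}

#' @rdname reportJSON
#' @export
reportText <- function(validation, compliance) {
    tab <- validation@issues
    lines <- sprintf("validation: %d error(s), %d warning(s), %d info",
                     sum(tab$severity == "error"),
                     sum(tab$severity == "warning"),
                     sum(tab$severity == "info"))
    if (nrow(tab))
        lines <- c(lines, sprintf("  [%s] %s %s (row %s, column %s): %s",
                                  tab$severity, tab$code, tab$file, tab$row,
                                  tab$column, tab$message))
    lines <- c(lines, sprintf("compliance (%s): score %.3f",
                              compliance@kind, compliance@score))
    ct <- compliance@table
    for (sec in unique(ct$section)) {
        s <- ct[ct$section == sec, , drop = FALSE]
        miss <- s$attribute[!s$present]
        lines <- c(lines, sprintf("  %s: %d/%d present%s", sec,
                                  sum(s$present), nrow(s),
                                  if (length(miss))
                                      paste0(" (missing: ",
                                             paste(miss, collapse = ", "),
                                             ")")
                                  else ""))
    }
    lines
}
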