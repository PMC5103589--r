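## Linking Trait Definition Files and Derived Data File matrices to assays,
## long-format observation records, cross-study aggregation, and dataset
## summaries.

.LONG_COLS <- c("dataset", "study", "row_id", "variable_id", "value")

.emptyLong <- function(by = character(0)) {
    cols <- c("dataset", "study", by, "row_id", "variable_id", "value")
    setNames(as.data.frame(rep(list(character(0)), length(cols)),
                           stringsAsFactors = FALSE, col.names = cols),
             cols)
}

#' Link an observation matrix to its assay and trait definitions
#'
#' Produces one long record per (row id, variable) pair where the row id
#' resolves through the matrix's link-node column and the variable is
#' defined in the Trait Definition File; missing cells are skipped.
#' Unresolved row ids and undefined variables are reported as issues, never
#' silently dropped.
#'
#' @param assay the [AssayTable-class] the matrix is referenced from.
#' @param tdf a [TraitDefinitions-class] (or list of them).
#' @param matrix a [DataMatrix-class].
#' @param study optional [StudyTable-class], searched for the link-node
#'   column when the assay lacks it (extended data-node rule).
#' @return a list with `records` (data.frame `row_id`, `variable_id`,
#'   `value`) and `issues`.
#' @export
linkObservations <- function(assay, tdf, matrix, study = NULL) {
    stopifnot(is(assay, "AssayTable"), is(matrix, "DataMatrix"))
    if (is(tdf, "TraitDefinitions"))
        tdf <- list(tdf)
    known <- unique(unlist(lapply(tdf, variableIds)))
    linkCol <- .nodeColumn(assay, matrix@linkNode)
    linkTable <- assay
    if (is.na(linkCol) && !is.null(study)) {
        linkCol <- .nodeColumn(study, matrix@linkNode)
        linkTable <- study
    }
    if (is.na(linkCol))
        stop("link node column '", matrix@linkNode,
             "' absent from the assay",
             if (!is.null(study)) " and study" else "")
    ids <- linkTable@rows[, linkCol]
    iss <- emptyIssues()
    v <- matrix@values
    fname <- matrix@sourceFile
    goodVars <- colnames(v) %in% known
    for (var in colnames(v)[!goodVars])
        iss <- bindIssues(iss, issue("error", "UNKNOWN_VARIABLE_ID", fname,
            row = 1L, column = var,
            message = sprintf("variable '%s' is not defined", var)))
    goodRows <- rownames(v) %in% ids
    for (i in which(!goodRows))
        iss <- bindIssues(iss, issue("warning", "ORPHAN_DATA_ROW", fname,
            row = i + 1L, column = matrix@linkNode,
            message = sprintf("row id '%s' does not resolve",
                              rownames(v)[i])))
    sub <- v[goodRows, goodVars, drop = FALSE]
    miss <- sub == "" | sub == "NA"
    keep <- which(!miss, arr.ind = TRUE)
    records <- data.frame(
        row_id = rownames(sub)[keep[, 1L]],
        variable_id = colnames(sub)[keep[, 2L]],
        value = sub[keep],
        stringsAsFactors = FALSE)
    ord <- order(match(records$row_id, rownames(sub)),
                 match(records$variable_id, colnames(sub)))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, issues = sortIssues(iss))
}

.characteristicBySample <- function(study, qualifier) {
    header <- paste0("Characteristics[", qualifier, "]")
    at <- match(header, headerTexts(study@headers))
    scol <- .nodeColumn(study, "Sample Name")
    if (is.na(at) || is.na(scol) || nrow(study@rows) == 0L)
        return(NULL)
    setNames(study@rows[, at], study@rows[, scol])
}

#' Aggregate observations across studies and datasets
#'
#' Concatenates long observation records from every derived data matrix of
#' every dataset, resolving grouping characteristics (e.g. `Study start`,
#' `Geographic location`) per source row through the sample chain. Variables
#' are matched by Variable ID across Trait Definition Files; the same id
#' carrying differing Trait/Method/Scale across files is reported as a
#' `TDF_CONFLICT` warning. A study lacking a grouping characteristic yields
#' a `MISSING_GROUP_KEY` warning and the group value "unknown".
#'
#' @param datasets a [PhenoDataset-class] or list of them.
#' @param by character vector of Characteristics qualifiers to group by.
#' @return a list with `records` (data.frame `dataset`, `study`, one column
#'   per grouping key, `row_id`, `variable_id`, `value`) and `issues`.
#' @export
aggregateObservations <- function(datasets, by = character(0)) {
    if (is(datasets, "PhenoDataset"))
        datasets <- list(datasets)
    iss <- emptyIssues()
    parts <- list()
    ## trait-definition conflicts across all involved TDFs
    alldefs <- do.call(rbind, unlist(lapply(datasets, function(d)
        lapply(d@traitDefinitions, function(t)
            cbind(t@defs, file = t@sourceFile))), recursive = FALSE))
    if (!is.null(alldefs) && nrow(alldefs)) {
        for (id in unique(alldefs$variable_id)) {
            sub <- alldefs[alldefs$variable_id == id, , drop = FALSE]
            key <- paste(sub$trait, sub$method, sub$scale, sep = "\r")
            if (length(unique(key)) > 1L)
                iss <- bindIssues(iss, issue("warning", "TDF_CONFLICT",
                    paste(unique(sub$file), collapse = ","),
                    column = id,
                    message = sprintf(
                        "variable '%s' has differing Trait/Method/Scale across files",
                        id)))
        }
    }
    for (di in seq_along(datasets)) {
        d <- datasets[[di]]
        dsid <- if (nzchar(d@investigation@identifier))
            d@investigation@identifier else sprintf("dataset%d", di)
        for (st in d@investigation@studies) {
            study <- d@studies[[st@fileName]]
            for (afn in st@assayFiles) {
                assay <- d@assays[[afn]]
                if (is.null(assay))
                    next
                refs <- .referencedFiles(assay)
                tdfs <- d@traitDefinitions[intersect(refs$tdf,
                    names(d@traitDefinitions))]
                for (mfn in intersect(refs$derived, names(d@dataFiles))) {
                    got <- linkObservations(assay, tdfs,
                                            d@dataFiles[[mfn]],
                                            study = study)
                    iss <- bindIssues(iss, got$issues)
                    rec <- got$records
                    if (!nrow(rec))
                        next
                    rec$dataset <- dsid
                    rec$study <- st@fileName
                    ## resolve grouping keys through the sample chain:
                    ## matrix row id -> assay row -> sample -> study row
                    if (length(by)) {
                        m <- d@dataFiles[[mfn]]
                        linkCol <- .nodeColumn(assay, m@linkNode)
                        acol <- .nodeColumn(assay, "Sample Name")
                        sampleOf <- if (!is.na(linkCol) && !is.na(acol))
                            setNames(assay@rows[, acol],
                                     assay@rows[, linkCol])
                        else NULL
                        for (key in by) {
                            vals <- if (!is.null(study))
                                .characteristicBySample(study, key)
                            else NULL
                            if (is.null(vals) || is.null(sampleOf)) {
                                iss <- bindIssues(iss, issue("warning",
                                    "MISSING_GROUP_KEY", st@fileName,
                                    column = paste0("Characteristics[",
                                                    key, "]"),
                                    message = sprintf(
                                        "grouping characteristic '%s' not available; group set to \"unknown\"",
                                        key)))
                                rec[[key]] <- "unknown"
                            } else {
                                got <- unname(vals[sampleOf[rec$row_id]])
                                got[is.na(got) | !nzchar(got)] <- "unknown"
                                rec[[key]] <- got
                            }
                        }
                    }
                    cols <- c("dataset", "study", by, "row_id",
                              "variable_id", "value")
                    parts[[length(parts) + 1L]] <- rec[, cols, drop = FALSE]
                }
            }
        }
    }
    records <- if (length(parts))
        do.call(rbind, c(parts, list(make.row.names = FALSE)))
    else .emptyLong(by)
    list(records = records, issues = sortIssues(iss))
}

#' @rdname aggregateObservations
#' @param records a long-observation data.frame.
#' @param path output file.
#' @return `writeLongObservations` writes a tab-separated long table (fixed
#'   column order: dataset, study, group keys, row id, variable, value) and
#'   returns `path` invisibly.
#' @export
writeLongObservations <- function(records, path) {
    lines <- c(.formatCells(names(records)),
               if (nrow(records))
                   vapply(seq_len(nrow(records)), function(i)
                       .formatCells(as.character(unlist(records[i, ]))),
                       character(1)))
    .writeTextLines(lines, path)
}

#' Summarise a dataset's structure
#'
#' @param dataset a [PhenoDataset-class].
#' @return a list with counts: `studies`, `sourcesPerStudy` (distinct
#'   Source Names per study file), `samples`, `assays`, `variables`,
#'   `phenotypicVariables`, `environmentalVariables`, `dataFiles` and
#'   `matrixDims` (rows x variables per data file).
#' @export
summarizeDataset <- function(dataset) {
    stopifnot(is(dataset, "PhenoDataset"))
    sources <- vapply(dataset@studies, function(s) {
        col <- .nodeColumn(s, "Source Name")
        if (is.na(col)) 0L else length(unique(s@rows[nzchar(s@rows[, col]),
                                                     col]))
    }, integer(1))
    samples <- sum(vapply(dataset@studies, function(s) {
        col <- .nodeColumn(s, "Sample Name")
        if (is.na(col)) 0L else length(unique(s@rows[nzchar(s@rows[, col]),
                                                     col]))
    }, integer(1)))
    allDefs <- do.call(rbind, lapply(dataset@traitDefinitions,
                                     function(t) t@defs))
    nvar <- function(cls) {
        if (is.null(allDefs)) 0L
        else nrow(unique(allDefs[allDefs$variable_class %in% cls,
                                 c("variable_id", "variable_class"),
                                 drop = FALSE]))
    }
    list(studies = length(dataset@studies),
         sourcesPerStudy = sources,
         samples = samples,
         assays = length(dataset@assays),
         variables = if (is.null(allDefs)) 0L
                     else length(unique(allDefs$variable_id)),
         phenotypicVariables = nvar("phenotypic"),
         environmentalVariables = nvar("environmental"),
         dataFiles = length(dataset@dataFiles),
         matrixDims = lapply(dataset@dataFiles, dim))
}
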