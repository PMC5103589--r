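#' @import methods
NULL

## Closed vocabulary of ISA-Tab column categories. Data-node and structural
## columns carry no bracket qualifier; property columns require one.
.CATEGORY_LABELS <- c(
    SOURCE_NAME           = "Source Name",
    SAMPLE_NAME           = "Sample Name",
    EXTRACT_NAME          = "Extract Name",
    ASSAY_NAME            = "Assay Name",
    PROTOCOL_REF          = "Protocol REF",
    CHARACTERISTICS       = "Characteristics",
    FACTOR_VALUE          = "Factor Value",
    PARAMETER_VALUE       = "Parameter Value",
    UNIT                  = "Unit",
    TERM_SOURCE_REF       = "Term Source REF",
    TERM_ACCESSION_NUMBER = "Term Accession Number",
    COMMENT               = "Comment",
    RAW_DATA_FILE         = "Raw Data File",
    DERIVED_DATA_FILE     = "Derived Data File")

.QUALIFIED_CATEGORIES <- c("CHARACTERISTICS", "FACTOR_VALUE",
                           "PARAMETER_VALUE", "COMMENT")
.DATA_NODE_CATEGORIES <- c("SOURCE_NAME", "SAMPLE_NAME",
                           "EXTRACT_NAME", "ASSAY_NAME")
.PROPERTY_CATEGORIES  <- c("CHARACTERISTICS", "FACTOR_VALUE", "PARAMETER_VALUE")

#' FieldHeader: a parsed ISA-Tab column header
#'
#' A column header split into its category (the closed ISA-Tab vocabulary of
#' data nodes, property columns, qualifier columns and file references) and,
#' for property columns, the bracket qualifier. The `expected` slot is only
#' populated for `Protocol REF` headers written in the documentation
#' shorthand `Protocol REF[Name]`, where the bracketed name is the expected
#' cell value rather than a qualifier.
#'
#' @slot category character(1), one of the category keys (e.g.
#'   `"CHARACTERISTICS"`, `"SOURCE_NAME"`).
#' @slot qualifier character(1), the bracket qualifier; empty unless the
#'   category is Characteristics, Factor Value, Parameter Value or Comment.
#' @slot expected character(1), expected cell value for Protocol REF columns
#'   (otherwise empty).
#' @seealso [parseHeader()], [formatHeader()]
#' @exportClass FieldHeader
setClass("FieldHeader", representation(
    category  = "character",
    qualifier = "character",
    expected  = "character"),
    prototype(qualifier = "", expected = ""))

setValidity("FieldHeader", function(object) {
    msgs <- character(0)
    if (length(object@category) != 1L ||
        !object@category %in% names(.CATEGORY_LABELS))
        msgs <- c(msgs, "unknown header category")
    else {
        qualifiable <- object@category %in% .QUALIFIED_CATEGORIES
        if (qualifiable && !nzchar(object@qualifier))
            msgs <- c(msgs, sprintf("category %s requires a [qualifier]",
                                    object@category))
        if (!qualifiable && nzchar(object@qualifier))
            msgs <- c(msgs, sprintf("category %s does not take a qualifier",
                                    object@category))
        if (nzchar(object@expected) && object@category != "PROTOCOL_REF")
            msgs <- c(msgs, "expected cell value only applies to Protocol REF")
    }
    if (length(msgs)) msgs else TRUE
})

#' @rdname FieldHeader-class
#' @param category,qualifier,expected see slots.
#' @return a `FieldHeader` object.
#' @export
FieldHeader <- function(category, qualifier = "", expected = "")
    new("FieldHeader", category = category, qualifier = qualifier,
        expected = expected)

## ---------------------------------------------------------------------------

#' IsaTable: tab-delimited Study/Assay tables
#'
#' The physical form of an `s_*.txt` or `a_*.txt` file: an ordered header
#' sequence plus rectangular character rows. `StudyTable` must begin with
#' `Source Name` and end with `Sample Name`; `AssayTable` must begin with
#' `Sample Name`. Qualifier columns (`Unit`, `Term Source REF`,
#' `Term Accession Number`) must directly follow the column they qualify.
#'
#' @slot sourceFile character(1) file name (not path) the table came from or
#'   will be written to.
#' @slot headers list of [FieldHeader-class] objects, one per column.
#' @slot rows character matrix, one row per data row, `ncol == length(headers)`.
#' @aliases StudyTable-class AssayTable-class
#' @exportClass IsaTable
setClass("IsaTable", representation(
    sourceFile = "character",
    headers    = "list",
    rows       = "matrix"),
    contains = "VIRTUAL")

.checkTableShape <- function(object) {
    msgs <- character(0)
    cats <- vapply(object@headers, slot, character(1), "category")
    if (!is.character(object@rows))
        msgs <- c(msgs, "rows must be a character matrix")
    if (nrow(object@rows) > 0L && ncol(object@rows) != length(object@headers))
        msgs <- c(msgs, "rows are not rectangular with the header count")
    ok <- vapply(object@headers, function(h)
        isTRUE(validObject(h, test = TRUE)), logical(1))
    if (!all(ok))
        msgs <- c(msgs, "invalid FieldHeader in headers")
    for (i in seq_along(cats)) {
        prev <- if (i > 1L) cats[i - 1L] else ""
        bad <- switch(cats[i],
            UNIT = !prev %in% .PROPERTY_CATEGORIES,
            TERM_SOURCE_REF = !prev %in% c(.PROPERTY_CATEGORIES, "UNIT"),
            TERM_ACCESSION_NUMBER = !identical(prev, "TERM_SOURCE_REF"),
            FALSE)
        if (bad)
            msgs <- c(msgs, sprintf(
                "column %d (%s) does not follow a column it can qualify",
                i, .CATEGORY_LABELS[[cats[i]]]))
    }
    list(msgs = msgs, cats = cats)
}

#' @exportClass StudyTable
setClass("StudyTable", contains = "IsaTable")

setValidity("StudyTable", function(object) {
    chk <- .checkTableShape(object)
    msgs <- chk$msgs
    cats <- chk$cats
    if (length(cats) == 0L)
        msgs <- c(msgs, "table has no columns")
    else {
        if (cats[1L] != "SOURCE_NAME")
            msgs <- c(msgs, "a Study table must begin with Source Name")
        if (cats[length(cats)] != "SAMPLE_NAME")
            msgs <- c(msgs, "a Study table must end with Sample Name")
    }
    if (length(msgs)) msgs else TRUE
})

#' @exportClass AssayTable
setClass("AssayTable", contains = "IsaTable")

setValidity("AssayTable", function(object) {
    chk <- .checkTableShape(object)
    msgs <- chk$msgs
    cats <- chk$cats
    if (length(cats) == 0L || cats[1L] != "SAMPLE_NAME")
        msgs <- c(msgs, "an Assay table must begin with Sample Name")
    if (length(msgs)) msgs else TRUE
})

.emptyRows <- function(ncol) matrix(character(0), nrow = 0L, ncol = ncol)

#' @rdname IsaTable-class
#' @param sourceFile,headers,rows see slots; `rows` may be given as a list of
#'   equal-length character vectors.
#' @export
StudyTable <- function(sourceFile, headers, rows = NULL) {
    new("StudyTable", sourceFile = sourceFile, headers = headers,
        rows = .asRowMatrix(rows, length(headers)))
}

#' @rdname IsaTable-class
#' @export
AssayTable <- function(sourceFile, headers, rows = NULL) {
    new("AssayTable", sourceFile = sourceFile, headers = headers,
        rows = .asRowMatrix(rows, length(headers)))
}

.asRowMatrix <- function(rows, ncol) {
    if (is.null(rows))
        return(.emptyRows(ncol))
    if (is.matrix(rows)) {
        storage.mode(rows) <- "character"
        return(rows)
    }
    if (length(rows) == 0L)
        return(.emptyRows(ncol))
    lens <- lengths(rows)
    if (any(lens != ncol))
        stop("ragged rows: expected ", ncol, " cells, got ",
             paste(unique(lens[lens != ncol]), collapse = "/"))
    do.call(rbind, lapply(rows, as.character))
}

## ---------------------------------------------------------------------------

.emptyDF <- function(...) {
    cols <- c(...)
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
}

#' StudyRecord: one STUDY block of an Investigation file
#'
#' @slot fileName character(1), the `s_*.txt` file implementing the study.
#' @slot identifier,title,description,submissionDate,publicReleaseDate
#'   character(1) study-level metadata.
#' @slot designDescriptors character vector of design descriptor terms.
#' @slot factors data.frame with columns `name`, `type`.
#' @slot assayFiles character vector of `a_*.txt` file names.
#' @slot protocols data.frame with columns `name`, `type`, `description`,
#'   `parameters` (semicolon-joined parameter names).
#' @slot contacts data.frame with columns `lastName`, `firstName`, `email`,
#'   `affiliation`.
#' @exportClass StudyRecord
setClass("StudyRecord", representation(
    fileName          = "character",
    identifier        = "character",
    title             = "character",
    description       = "character",
    submissionDate    = "character",
    publicReleaseDate = "character",
    designDescriptors = "character",
    factors           = "data.frame",
    assayFiles        = "character",
    protocols         = "data.frame",
    contacts          = "data.frame"),
    prototype(identifier = "", title = "", description = "",
              submissionDate = "", publicReleaseDate = "",
              designDescriptors = character(0),
              assayFiles = character(0)))

#' @rdname StudyRecord-class
#' @param fileName,identifier,title,description,submissionDate,publicReleaseDate,designDescriptors,factors,assayFiles,protocols,contacts
#'   see slots.
#' @export
StudyRecord <- function(fileName, identifier = "", title = "",
                        description = "", submissionDate = "",
                        publicReleaseDate = "",
                        designDescriptors = character(0),
                        factors = .emptyDF("name", "type"),
                        assayFiles = character(0),
                        protocols = .emptyDF("name", "type", "description",
                                             "parameters"),
                        contacts = .emptyDF("lastName", "firstName", "email",
                                            "affiliation")) {
    new("StudyRecord", fileName = fileName, identifier = identifier,
        title = title, description = description,
        submissionDate = submissionDate,
        publicReleaseDate = publicReleaseDate,
        designDescriptors = designDescriptors, factors = factors,
        assayFiles = assayFiles, protocols = protocols, contacts = contacts)
}

#' Investigation: the `i_*.txt` sectioned key-value file
#'
#' @slot identifier,title,description,submissionDate,publicReleaseDate
#'   character(1) investigation-level metadata.
#' @slot ontologySources data.frame with columns `name`, `file`, `version`,
#'   `description`: the declared Term Source vocabulary.
#' @slot publications data.frame (`pubmedID`, `doi`, `authorList`, `title`,
#'   `status`).
#' @slot contacts data.frame (`lastName`, `firstName`, `email`,
#'   `affiliation`).
#' @slot studies list of [StudyRecord-class] objects.
#' @exportClass Investigation
setClass("Investigation", representation(
    identifier        = "character",
    title             = "character",
    description       = "character",
    submissionDate    = "character",
    publicReleaseDate = "character",
    ontologySources   = "data.frame",
    publications      = "data.frame",
    contacts          = "data.frame",
    studies           = "list"),
    prototype(identifier = "", title = "", description = "",
              submissionDate = "", publicReleaseDate = ""))

setValidity("Investigation", function(object) {
    msgs <- character(0)
    sfiles <- vapply(object@studies, slot, character(1), "fileName")
    if (anyDuplicated(sfiles))
        msgs <- c(msgs, "duplicated study file names in investigation")
    afiles <- unlist(lapply(object@studies, slot, "assayFiles"))
    if (anyDuplicated(afiles))
        msgs <- c(msgs, "duplicated assay file names in investigation")
    if (length(msgs)) msgs else TRUE
})

#' @rdname Investigation-class
#' @param identifier,title,description,submissionDate,publicReleaseDate,ontologySources,publications,contacts,studies
#'   see slots.
#' @export
Investigation <- function(identifier = "", title = "", description = "",
                          submissionDate = "", publicReleaseDate = "",
                          ontologySources = .emptyDF("name", "file",
                                                     "version", "description"),
                          publications = .emptyDF("pubmedID", "doi",
                                                  "authorList", "title",
                                                  "status"),
                          contacts = .emptyDF("lastName", "firstName",
                                              "email", "affiliation"),
                          studies = list()) {
    new("Investigation", identifier = identifier, title = title,
        description = description, submissionDate = submissionDate,
        publicReleaseDate = publicReleaseDate,
        ontologySources = ontologySources, publications = publications,
        contacts = contacts, studies = studies)
}

## ---------------------------------------------------------------------------

#' TraitDefinitions: a parsed Trait Definition File
#'
#' One row per observed variable with the Variable ID / Trait / Method /
#' Scale columns and their optional ontology annotations (Term Source REF +
#' Term Accession Number after Trait, Method and Scale). The optional
#' `Comment[Variable class]` column distinguishes phenotypic from
#' environmental variables; absent, the class is "unspecified".
#'
#' @slot sourceFile character(1) file name.
#' @slot defs data.frame with columns `variable_id`, `trait`,
#'   `trait_source_ref`, `trait_accession`, `method`, `method_source_ref`,
#'   `method_accession`, `scale`, `scale_source_ref`, `scale_accession`,
#'   `variable_class`.
#' @exportClass TraitDefinitions
setClass("TraitDefinitions", representation(
    sourceFile = "character",
    defs       = "data.frame"))

.TDF_COLS <- c("variable_id", "trait", "trait_source_ref", "trait_accession",
               "method", "method_source_ref", "method_accession",
               "scale", "scale_source_ref", "scale_accession",
               "variable_class")

setValidity("TraitDefinitions", function(object) {
    msgs <- character(0)
    d <- object@defs
    if (!all(.TDF_COLS %in% names(d)))
        msgs <- c(msgs, "trait definition table is missing internal columns")
    else {
        if (any(!nzchar(d$variable_id)))
            msgs <- c(msgs, "empty Variable ID")
        if (anyDuplicated(d$variable_id))
            msgs <- c(msgs, "duplicated Variable ID")
        if (!all(d$variable_class %in%
                 c("phenotypic", "environmental", "unspecified")))
            msgs <- c(msgs, "variable_class out of vocabulary")
        ann <- d$trait_accession != "" & d$trait_source_ref == "" |
               d$method_accession != "" & d$method_source_ref == "" |
               d$scale_accession != "" & d$scale_source_ref == ""
        if (any(ann))
            msgs <- c(msgs, "term accession without a Term Source REF")
    }
    if (length(msgs)) msgs else TRUE
})

#' @rdname TraitDefinitions-class
#' @param sourceFile file name; `defs` the definition table (missing optional
#'   columns are filled with empty strings, `variable_class` with
#'   "unspecified").
#' @param defs see slots.
#' @export
TraitDefinitions <- function(sourceFile, defs) {
    defs <- as.data.frame(defs, stringsAsFactors = FALSE)
    for (col in .TDF_COLS)
        if (is.null(defs[[col]]))
            defs[[col]] <- if (col == "variable_class")
                rep("unspecified", nrow(defs)) else rep("", nrow(defs))
    defs <- defs[, .TDF_COLS, drop = FALSE]
    rownames(defs) <- NULL
    new("TraitDefinitions", sourceFile = sourceFile, defs = defs)
}

#' DataMatrix: a Derived Data File observation matrix
#'
#' The default derived-data dialect: a plain tab-separated sample-by-variable
#' matrix whose first column holds values of a data-node column (by default
#' `Assay Name`) and whose remaining column names are Variable IDs declared
#' in a Trait Definition File.
#'
#' @slot sourceFile character(1) file name.
#' @slot linkNode character(1), the data-node column name used for row
#'   identity (first header cell of the file).
#' @slot values character matrix; rownames are row ids, colnames are
#'   variable ids. Empty string or "NA" cells are missing values.
#' @exportClass DataMatrix
setClass("DataMatrix", representation(
    sourceFile = "character",
    linkNode   = "character",
    values     = "matrix"))

setValidity("DataMatrix", function(object) {
    msgs <- character(0)
    v <- object@values
    if (!is.character(v))
        msgs <- c(msgs, "values must be a character matrix")
    if (is.null(rownames(v)) && nrow(v) > 0L)
        msgs <- c(msgs, "values must carry row ids as rownames")
    if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
        msgs <- c(msgs, "duplicated row ids")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
        msgs <- c(msgs, "duplicated variable ids")
    if (!nzchar(object@linkNode))
        msgs <- c(msgs, "empty link node name")
    if (length(msgs)) msgs else TRUE
})

#' @rdname DataMatrix-class
#' @param sourceFile,linkNode,values see slots.
#' @export
DataMatrix <- function(sourceFile, linkNode = "Assay Name", values) {
    storage.mode(values) <- "character"
    new("DataMatrix", sourceFile = sourceFile, linkNode = linkNode,
        values = values)
}

## ---------------------------------------------------------------------------

#' PhenoDataset: a complete ISA-Tab phenotyping dataset
#'
#' The in-memory form of one dataset directory: the Investigation, the Study
#' and Assay tables it names, plus Trait Definition Files and Derived Data
#' File matrices referenced from the assays. Files referenced but kept
#' outside the archive (raw images, remote data) are listed in
#' `externalFiles`. Problems found while reading are kept in `parseIssues`
#' (same columns as a [ValidationReport-class] issue table) so that nothing
#' is silently dropped.
#'
#' @slot rootDir character(1), directory read from ("" for in-memory).
#' @slot investigation [Investigation-class].
#' @slot studies named list of [StudyTable-class] keyed by file name.
#' @slot assays named list of [AssayTable-class] keyed by file name.
#' @slot traitDefinitions named list of [TraitDefinitions-class].
#' @slot dataFiles named list of [DataMatrix-class].
#' @slot externalFiles character vector of referenced-but-external names.
#' @slot parseIssues data.frame of read-time findings.
#' @exportClass PhenoDataset
setClass("PhenoDataset", representation(
    rootDir          = "character",
    investigation    = "Investigation",
    studies          = "list",
    assays           = "list",
    traitDefinitions = "list",
    dataFiles        = "list",
    externalFiles    = "character",
    parseIssues      = "data.frame"),
    prototype(rootDir = "", externalFiles = character(0)))

#' @rdname PhenoDataset-class
#' @param rootDir,investigation,studies,assays,traitDefinitions,dataFiles,externalFiles,parseIssues
#'   see slots.
#' @export
PhenoDataset <- function(investigation = Investigation(), studies = list(),
                         assays = list(), traitDefinitions = list(),
                         dataFiles = list(), externalFiles = character(0),
                         rootDir = "", parseIssues = emptyIssues()) {
    new("PhenoDataset", rootDir = rootDir, investigation = investigation,
        studies = studies, assays = assays,
        traitDefinitions = traitDefinitions, dataFiles = dataFiles,
        externalFiles = externalFiles, parseIssues = parseIssues)
}

## ---------------------------------------------------------------------------

#' PhenoConfig: a Phenotyping Configuration schema
#'
#' A named column schema for a Study or Assay file: the planned headers in
#' order (with required/optional flags, expected cell values for Protocol REF
#' columns, and unit-follows markers), the protocol blocks with their
#' parameters, and the set of essential MIAPPE attributes applicable under
#' the configuration. Extension is additive only: a derived configuration
#' must contain its parent's plan as an identical-spelling subsequence.
#'
#' @slot name configuration name ("basic", "field", "greenhouse",
#'   "phenotyping" or a derived name).
#' @slot kind one of "basic", "field", "greenhouse" for study configs,
#'   "phenotyping" for the assay config; derived configs keep their base
#'   kind.
#' @slot parent name of the base configuration ("" for builtins).
#' @slot plan data.frame with columns `header` (canonical text), `category`,
#'   `qualifier`, `expected` (Protocol REF cell value or ""), `required`
#'   (logical), `unitFollows` (logical), `protocol` (owning protocol block
#'   name or "").
#' @slot essentials data.frame of applicable essential attributes (columns
#'   `section`, `attribute`, `level`, `type`, `target`).
#' @aliases StudyConfig-class AssayConfig-class
#' @exportClass PhenoConfig
setClass("PhenoConfig", representation(
    name       = "character",
    kind       = "character",
    parent     = "character",
    plan       = "data.frame",
    essentials = "data.frame"),
    contains = "VIRTUAL",
    prototype(parent = ""))

.PLAN_COLS <- c("header", "category", "qualifier", "expected", "required",
                "unitFollows", "protocol")

.checkPlan <- function(plan) {
    msgs <- character(0)
    if (!all(.PLAN_COLS %in% names(plan)))
        msgs <- c(msgs, "plan is missing internal columns")
    msgs
}

#' @exportClass StudyConfig
setClass("StudyConfig", contains = "PhenoConfig")

setValidity("StudyConfig", function(object) {
    msgs <- .checkPlan(object@plan)
    p <- object@plan
    if (!length(msgs) && nrow(p)) {
        if (p$category[1L] != "SOURCE_NAME")
            msgs <- c(msgs, "study plan must start with Source Name")
        if (p$category[nrow(p)] != "SAMPLE_NAME")
            msgs <- c(msgs, "study plan must end with Sample Name")
    }
    if (length(msgs)) msgs else TRUE
})

#' @exportClass AssayConfig
setClass("AssayConfig", contains = "PhenoConfig")

setValidity("AssayConfig", function(object) {
    msgs <- .checkPlan(object@plan)
    p <- object@plan
    if (!length(msgs)) {
        tdf <- p$category == "PARAMETER_VALUE" &
               p$qualifier == "Trait Definition File"
        if (sum(tdf) != 1L)
            msgs <- c(msgs,
                "assay plan must contain exactly one Parameter Value[Trait Definition File]")
        if (nrow(p) && p$category[1L] != "SAMPLE_NAME")
            msgs <- c(msgs, "assay plan must start with Sample Name")
    }
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------

#' ValidationReport: located, coded validation findings
#'
#' @slot issues data.frame with columns `severity` (error/warning/info),
#'   `code` (stable identifier such as `MISSING_COLUMN`), `file`, `row`
#'   (1-based counting the header row as row 1, or "-"), `column` (canonical
#'   header text plus occurrence suffix, or "-"), `message`.
#' @exportClass ValidationReport
setClass("ValidationReport", representation(issues = "data.frame"))

#' @rdname ValidationReport-class
#' @param issues see slot.
#' @export
ValidationReport <- function(issues = emptyIssues())
    new("ValidationReport", issues = issues)

#' ComplianceReport: per-section MIAPPE essential-attribute coverage
#'
#' @slot kind configuration kind the report was computed under.
#' @slot table data.frame with one row per applicable essential attribute:
#'   `section`, `attribute`, `present` (logical).
#' @slot score fraction of applicable essential attributes present, in
#'   `[0, 1]`.
#' @exportClass ComplianceReport
setClass("ComplianceReport", representation(
    kind  = "character",
    table = "data.frame",
    score = "numeric"))

setValidity("ComplianceReport", function(object) {
    msgs <- character(0)
    t <- object@table
    if (!all(c("section", "attribute", "present") %in% names(t)))
        msgs <- c(msgs, "compliance table is missing internal columns")
    else if (nrow(t)) {
        expect <- sum(t$present) / nrow(t)
        if (abs(object@score - expect) > 1e-12)
            msgs <- c(msgs, "score does not equal present/applicable")
    }
    if (length(msgs)) msgs else TRUE
})
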