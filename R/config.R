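## The Phenotyping Configuration registry: the Basic / Field / Greenhouse
## Study schemas, the Phenotyping Assay schema, the essential-attribute
## applicability sets, and additive schema extension.

.planRow <- function(category, qualifier = "", expected = "",
                     required = TRUE, unitFollows = FALSE, protocol = "") {
    header <- formatHeader(FieldHeader(category, qualifier))
    data.frame(header = header, category = category, qualifier = qualifier,
               expected = expected, required = required,
               unitFollows = unitFollows, protocol = protocol,
               stringsAsFactors = FALSE)
}

.protocolBlock <- function(name, params, unitAfter = character(0)) {
    rows <- list(.planRow("PROTOCOL_REF", expected = name, protocol = name))
    for (p in params)
        rows <- c(rows, list(.planRow("PARAMETER_VALUE", qualifier = p,
                                      unitFollows = p %in% unitAfter,
                                      protocol = name)))
    do.call(rbind, rows)
}

.basicCharacteristics <- c("Organism", "Infraspecific name", "Seed origin",
                           "Study start", "Study duration",
                           "Growth facility", "Geographic location")

.basicStudyPlan <- function() {
    rows <- list(.planRow("SOURCE_NAME"))
    for (q in .basicCharacteristics)
        rows <- c(rows, list(.planRow("CHARACTERISTICS", qualifier = q)))
    rows <- c(rows, list(.planRow("SAMPLE_NAME")))
    do.call(rbind, rows)
}

.sharedProtocolBlocks <- function(rooting) {
    rbind(
        rooting,
        .protocolBlock("Aerial conditions",
                       c("Air humidity", "Daily photon flux",
                         "Length of light period", "Day temperature",
                         "Night temperature")),
        .protocolBlock("Nutrition",
                       c("N before fertilisation", "Type of fertiliser",
                         "Amount of fertiliser")),
        .protocolBlock("Watering",
                       c("Irrigation type", "Volume", "Frequency")),
        .protocolBlock("Sampling", "Experimental unit"))
}

.fieldStudyPlan <- function() {
    base <- .basicStudyPlan()
    blocks <- .sharedProtocolBlocks(
        .protocolBlock("Rooting",
                       c("Rooting medium", "Plot size", "Sowing density",
                         "pH"),
                       unitAfter = "Plot size"))
    rbind(base[-nrow(base), ], blocks, base[nrow(base), ])
}

.greenhouseStudyPlan <- function() {
    base <- .basicStudyPlan()
    blocks <- .sharedProtocolBlocks(
        .protocolBlock("Rooting",
                       c("Rooting medium", "Container type",
                         "Container volume", "Container dimension",
                         "Number of plants per container", "pH"),
                       unitAfter = "Container dimension"))
    rbind(base[-nrow(base), ], blocks, base[nrow(base), ])
}

## ---------------------------------------------------------------------------
## Essential MIAPPE attributes and where each lives in the ISA-Tab mapping.
## `type` says how presence is checked: an investigation field, a study/assay
## Characteristics column, a protocol block's parameter values, a data-file
## reference column, or Trait Definition File rows. Environmental variables
## are conditionally applicable: only when a TDF declares one.

.MIAPPE_SECTIONS <- c("General metadata", "Timing and location", "Biosource",
                      "Environment", "Treatments", "Experimental design",
                      "Sample collection, processing, management",
                      "Observed variables")

.essRow <- function(section, attribute, level, type, target,
                    basic, field, greenhouse, conditional = FALSE) {
    data.frame(section = section, attribute = attribute, level = level,
               type = type, target = target, basic = basic, field = field,
               greenhouse = greenhouse, conditional = conditional,
               stringsAsFactors = FALSE)
}

#' The essential-attribute registry of the MIAPPE checklist
#'
#' One row per essential MIAPPE attribute with its checklist section, the
#' ISA-Tab location it maps to under the Phenotyping Configuration, and its
#' applicability under each of the Basic, Field and Greenhouse study
#' schemas. Treatments and raw data are specific per experiment and not part
#' of any built-in configuration; environmental variable definitions are
#' applicable only when a Trait Definition File declares an environmental
#' variable.
#'
#' @return a data.frame with columns `section`, `attribute`, `level`,
#'   `type`, `target`, `basic`, `field`, `greenhouse`, `conditional`.
#' @export
miappeEssentials <- function() {
    rbind(
        .essRow("General metadata", "Unique identifier", "investigation",
                "field", "identifier", TRUE, TRUE, TRUE),
        .essRow("General metadata", "Title", "investigation", "field",
                "title", TRUE, TRUE, TRUE),
        .essRow("General metadata", "Description", "investigation", "field",
                "description", TRUE, TRUE, TRUE),
        .essRow("Timing and location", "Study start", "study",
                "characteristic", "Study start", TRUE, TRUE, TRUE),
        .essRow("Timing and location", "Study duration", "study",
                "characteristic", "Study duration", TRUE, TRUE, TRUE),
        .essRow("Timing and location", "Geographic location", "study",
                "characteristic", "Geographic location", TRUE, TRUE, TRUE),
        .essRow("Biosource", "Organism", "study", "characteristic",
                "Organism", TRUE, TRUE, TRUE),
        .essRow("Biosource", "Infraspecific name", "study", "characteristic",
                "Infraspecific name", TRUE, TRUE, TRUE),
        .essRow("Biosource", "Seed origin", "study", "characteristic",
                "Seed origin", TRUE, TRUE, TRUE),
        .essRow("Environment", "Growth facility", "study", "characteristic",
                "Growth facility", TRUE, TRUE, TRUE),
        .essRow("Environment", "Aerial conditions", "study", "protocol",
                "Aerial conditions", FALSE, TRUE, TRUE),
        .essRow("Environment", "Rooting conditions", "study", "protocol",
                "Rooting", FALSE, TRUE, TRUE),
        .essRow("Environment", "Nutrients", "study", "protocol",
                "Nutrition", FALSE, TRUE, TRUE),
        .essRow("Environment", "Watering", "study", "protocol",
                "Watering", FALSE, TRUE, TRUE),
        .essRow("Experimental design", "Experimental unit", "study",
                "protocol", "Sampling", FALSE, TRUE, TRUE),
        .essRow("Sample collection, processing, management",
                "Plant body of interest", "assay", "characteristic",
                "Plant body of interest", TRUE, TRUE, TRUE),
        .essRow("Observed variables", "Phenotypic variables", "tdf",
                "tdf_phenotypic", "-", TRUE, TRUE, TRUE),
        .essRow("Observed variables", "Environmental variables", "tdf",
                "tdf_environmental", "-", TRUE, TRUE, TRUE,
                conditional = TRUE),
        .essRow("Observed variables", "Derived data", "assay", "datafile",
                "Derived Data File", TRUE, TRUE, TRUE))
}

.essentialsFor <- function(kind) {
    reg <- miappeEssentials()
    reg[reg[[kind]], c("section", "attribute", "level", "type", "target",
                       "conditional")]
}

## ---------------------------------------------------------------------------

#' Built-in Phenotyping Configuration study schemas
#'
#' Returns the default Study file schema of the Phenotyping Configuration.
#' The Basic schema is a data-node pair (`Source Name` ... `Sample Name`)
#' around seven Characteristics columns (Organism, Infraspecific name, Seed
#' origin, Study start, Study duration, Growth facility, Geographic
#' location) and carries no protocol blocks. The Field and Greenhouse
#' schemas extend Basic with the environment protocol blocks Rooting, Aerial
#' conditions, Nutrition, Watering and Sampling; Rooting's parameters differ
#' between the two (plot-based in the field, container-based in the
#' greenhouse).
#'
#' @param kind "basic", "field" or "greenhouse".
#' @return a [StudyConfig-class].
#' @examples
#' planHeaders(builtinConfig("basic"))
#' @export
builtinConfig <- function(kind = c("basic", "field", "greenhouse")) {
    if (length(kind) != 1L || !kind %in% c("basic", "field", "greenhouse"))
        stop("unknown configuration kind: '", paste(kind, collapse = ","),
             "'")
    plan <- switch(kind,
        basic = .basicStudyPlan(),
        field = .fieldStudyPlan(),
        greenhouse = .greenhouseStudyPlan())
    ess <- .essentialsFor(kind)
    new("StudyConfig", name = kind, kind = kind, parent = "", plan = plan,
        essentials = ess)
}

#' The Phenotyping Assay schema
#'
#' The common Assay schema used by all three study schemas: `Sample Name`,
#' the organ characteristic `Characteristics[Plant body of interest]`, the
#' `Data transformation` protocol with its `Trait Definition File`
#' parameter, `Assay Name`, an optional `Raw Data File` reference (raw data
#' are specific per experiment) and a required `Derived Data File`
#' reference.
#'
#' @return an [AssayConfig-class].
#' @export
phenotypingAssayConfig <- function() {
    plan <- rbind(
        .planRow("SAMPLE_NAME"),
        .planRow("CHARACTERISTICS", qualifier = "Plant body of interest"),
        .protocolBlock("Data transformation", "Trait Definition File"),
        .planRow("ASSAY_NAME"),
        .planRow("RAW_DATA_FILE", required = FALSE),
        .planRow("DERIVED_DATA_FILE"))
    new("AssayConfig", name = "phenotyping", kind = "phenotyping",
        parent = "", plan = plan, essentials = .essentialsFor("basic")[0, ])
}

#' @describeIn builtinConfig the full ordered header sequence the schema
#'   plans, with `Unit` columns expanded in place.
#' @param config a [PhenoConfig-class].
#' @export
planHeaders <- function(config) {
    p <- config@plan
    out <- character(0)
    for (i in seq_len(nrow(p))) {
        out <- c(out, p$header[i])
        if (p$unitFollows[i])
            out <- c(out, "Unit")
    }
    out
}

#' @describeIn builtinConfig names of the protocol blocks in plan order.
#' @export
configProtocols <- function(config)
    unique(config@plan$protocol[nzchar(config@plan$protocol)])

#' @describeIn builtinConfig ordered parameter qualifiers of one protocol
#'   block.
#' @param protocol a protocol block name.
#' @export
protocolParameters <- function(config, protocol) {
    p <- config@plan
    p$qualifier[p$protocol == protocol & p$category == "PARAMETER_VALUE"]
}

.planSignatures <- function(plan) {
    sig <- plan$header
    pr <- plan$category == "PROTOCOL_REF"
    sig[pr] <- paste0(sig[pr], "=", plan$expected[pr])
    pv <- plan$category == "PARAMETER_VALUE"
    sig[pv] <- paste0(sig[pv], "@", plan$protocol[pv])
    sig
}

## ---------------------------------------------------------------------------

#' Additively extend a Phenotyping Configuration schema
#'
#' Derived schemas may only add columns: inherited fields keep their exact
#' spelling and order, none may be removed or shadowed by a duplicate. Each
#' addition is a list with elements `header` (canonical text; the shorthand
#' `Protocol REF[Name]` starts a new protocol block named `Name`), optional
#' `after` (canonical header text of the anchor column; default inserts
#' before the final `Sample Name` of a study plan, at the end of an assay
#' plan), optional `required` (default `TRUE`), `unitFollows` (default
#' `FALSE`), and `protocol` (owning block, for `Parameter Value` additions).
#' An addition with `action = "drop"` is always refused.
#'
#' @param base a [PhenoConfig-class] to derive from.
#' @param additions list of addition specifications (a single specification
#'   may be passed bare).
#' @param name name of the derived configuration.
#' @return a derived config of the same class whose plan contains `base`'s
#'   plan as an identical-spelling subsequence.
#' @examples
#' fld <- extendConfig(builtinConfig("field"),
#'                     list(list(header = "Factor Value[Watering regime]")))
#' @export
extendConfig <- function(base, additions, name = paste0(base@name,
                                                        "_derived")) {
    stopifnot(is(base, "PhenoConfig"))
    if (!is.null(additions$header))
        additions <- list(additions)
    plan <- base@plan
    for (add in additions) {
        if (identical(add$action, "drop"))
            stop("removal forbidden: fields inherited from the base ",
                 "configuration may not be removed (requested '",
                 add$header, "')")
        h <- parseHeader(add$header)
        row <- .planRow(h@category, h@qualifier, expected = h@expected,
                        required = !isFALSE(add$required),
                        unitFollows = isTRUE(add$unitFollows),
                        protocol = if (nzchar(h@expected)) h@expected
                                   else if (!is.null(add$protocol))
                                       add$protocol
                                   else "")
        sig <- .planSignatures(row)
        if (sig %in% .planSignatures(plan))
            stop("shadowing forbidden: '", add$header,
                 "' duplicates an existing planned column")
        if (h@category %in% c("CHARACTERISTICS", "FACTOR_VALUE", "COMMENT") &&
            row$header %in% plan$header)
            stop("shadowing forbidden: '", add$header,
                 "' duplicates an existing planned column")
        if (!is.null(add$after)) {
            at <- which(plan$header == add$after)
            if (!length(at))
                stop("unknown anchor column '", add$after, "'")
            at <- at[length(at)]
        } else if (is(base, "StudyConfig")) {
            at <- nrow(plan) - 1L  # before the closing Sample Name
        } else {
            at <- nrow(plan)
        }
        plan <- rbind(plan[seq_len(at), , drop = FALSE], row,
                      if (at < nrow(plan))
                          plan[(at + 1L):nrow(plan), , drop = FALSE])
        rownames(plan) <- NULL
    }
    out <- new(class(base), name = name, kind = base@kind,
               parent = base@name, plan = plan, essentials = base@essentials)
    validObject(out)
    ## additive-only invariant: the base plan must survive as a subsequence
    if (!.isSubsequence(.planSignatures(base@plan), .planSignatures(plan)))
        stop("internal error: extension broke the base plan subsequence")
    out
}

.isSubsequence <- function(a, b) {
    j <- 1L
    for (x in a) {
        while (j <= length(b) && b[j] != x)
            j <- j + 1L
        if (j > length(b))
            return(FALSE)
        j <- j + 1L
    }
    TRUE
}

#' Compare two configuration schemas
#'
#' Reports planned columns present in `b` but not `a` (`additions`), columns
#' present in `a` but not `b` (`missing`, conflict-free sibling branches
#' when the two schemas extend a common base in different directions), and
#' spelling conflicts: qualifiers that match case-insensitively but differ
#' in exact spelling.
#'
#' @param a,b [PhenoConfig-class] objects.
#' @return a list with data.frame `additions`, data.frame `missing` and
#'   character `conflicts`.
#' @export
configDiff <- function(a, b) {
    sa <- .planSignatures(a@plan)
    sb <- .planSignatures(b@plan)
    additions <- b@plan[!sb %in% sa, , drop = FALSE]
    missing <- a@plan[!sa %in% sb, , drop = FALSE]
    rownames(additions) <- rownames(missing) <- NULL
    qa <- unique(a@plan$qualifier[nzchar(a@plan$qualifier)])
    qb <- unique(b@plan$qualifier[nzchar(b@plan$qualifier)])
    onlyb <- setdiff(qb, qa)
    conflicts <- onlyb[tolower(onlyb) %in% tolower(setdiff(qa, qb))]
    list(additions = additions, missing = missing, conflicts = conflicts)
}

## ---------------------------------------------------------------------------
## Declarative plain-text serialization of a configuration: one line per
## planned header, `<canonical header>\t<required|optional>\t<expected or
## ->\t<unit|nounit>`; protocol blocks introduced by `protocol\t<name>`; a
## leading `config` line carries name/kind/parent.

#' Read / write configuration schema files
#'
#' @param path file path.
#' @return `readConfigFile` returns a [StudyConfig-class] or
#'   [AssayConfig-class]; `writeConfigFile` returns `path` invisibly.
#' @export
readConfigFile <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines) || !startsWith(lines[1L], "config\t"))
        stop("not a configuration file (missing 'config' line): ", path)
    head <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(head) < 4L)
        stop("malformed 'config' line in ", path)
    name <- head[2L]; kind <- head[3L]; parent <- head[4L]
    rows <- list()
    curProtocol <- ""
    for (line in lines[-1L]) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (f[1L] == "protocol") {
            curProtocol <- f[2L]
            next
        }
        if (length(f) != 4L)
            stop("malformed configuration line: '", line, "'")
        if (f[1L] == "Unit") {  # folded into the preceding parameter
            rows[[length(rows)]]$unitFollows <- TRUE
            next
        }
        h <- parseHeader(f[1L])
        rows[[length(rows) + 1L]] <- list(
            category = h@category, qualifier = h@qualifier,
            expected = if (nzchar(h@expected)) h@expected
                       else if (f[3L] != "-") f[3L] else "",
            required = f[2L] == "required",
            unitFollows = f[4L] == "unit",
            protocol = if (h@category %in% c("PROTOCOL_REF",
                                             "PARAMETER_VALUE"))
                           curProtocol else "")
    }
    plan <- do.call(rbind, lapply(rows, function(r)
        .planRow(r$category, r$qualifier, r$expected, r$required,
                 r$unitFollows, r$protocol)))
    cls <- if (kind == "phenotyping") "AssayConfig" else "StudyConfig"
    baseKind <- if (kind == "phenotyping") "basic" else kind
    new(cls, name = name, kind = kind, parent = parent, plan = plan,
        essentials = if (cls == "AssayConfig") .essentialsFor("basic")[0, ]
                     else .essentialsFor(kind))
}

#' @rdname readConfigFile
#' @param config the configuration to serialise.
#' @export
writeConfigFile <- function(config, path) {
    p <- config@plan
    lines <- sprintf("config\t%s\t%s\t%s", config@name, config@kind,
                     config@parent)
    lastProtocol <- ""
    for (i in seq_len(nrow(p))) {
        if (nzchar(p$protocol[i]) && p$protocol[i] != lastProtocol) {
            lines <- c(lines, paste0("protocol\t", p$protocol[i]))
            lastProtocol <- p$protocol[i]
        }
        lines <- c(lines, sprintf("%s\t%s\t%s\t%s", p$header[i],
                                  if (p$required[i]) "required" else "optional",
                                  if (nzchar(p$expected[i])) p$expected[i]
                                  else "-",
                                  if (p$unitFollows[i]) "unit" else "nounit"))
    }
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

setMethod("show", "StudyConfig", function(object) {
    cat(sprintf("StudyConfig '%s' (kind %s%s): %d planned columns, %d protocol block(s)\n",
                object@name, object@kind,
                if (nzchar(object@parent))
                    paste0(", extends ", object@parent) else "",
                length(planHeaders(object)),
                length(configProtocols(object))))
})

setMethod("show", "AssayConfig", function(object) {
    cat(sprintf("AssayConfig '%s': %d planned columns\n", object@name,
                length(planHeaders(object))))
})
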