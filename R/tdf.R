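## Trait Definition Files: the per-variable Trait / Method / Scale table
## referenced from the Phenotyping Assay via the "Data transformation"
## protocol's "Trait Definition File" parameter.

.TDF_MANDATORY <- c("Variable ID", "Trait", "Method", "Scale")

#' Read a Trait Definition File
#'
#' The file is tab-delimited with a header row containing at least
#' `Variable ID`, `Trait`, `Method` and `Scale`. Optional
#' `Term Source REF` / `Term Accession Number` columns directly after
#' `Trait`, `Method` or `Scale` are captured as ontology annotations; an
#' optional `Comment[Variable class]` column ("phenotypic" or
#' "environmental") classifies each variable, defaulting to "unspecified".
#'
#' @param path path to the file.
#' @return a [TraitDefinitions-class].
#' @export
readTDF <- function(path) {
    fname <- basename(path)
    lines <- .readTabLines(path)
    lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
    if (!length(lines))
        stop("empty trait definition file: ", fname)
    header <- .splitCells(lines[1L])
    missing <- setdiff(.TDF_MANDATORY, header)
    if (length(missing))
        stop("trait definition file ", fname, " is missing mandatory ",
             "column(s): ", paste(missing, collapse = ", "))
    cells <- lapply(lines[-1L], function(l) {
        x <- .splitCells(l)
        c(x, character(length(header)))[seq_along(header)]
    })
    grid <- if (length(cells)) do.call(rbind, cells)
            else matrix(character(0), 0L, length(header))
    colOf <- function(name, after = NULL) {
        idx <- which(header == name)
        if (!is.null(after))
            idx <- idx[idx == after + 1L]
        if (length(idx)) grid[, idx[1L]] else rep("", nrow(grid))
    }
    annotated <- function(base) {
        i <- which(header == base)[1L]
        src <- if (!is.na(i) && i + 1L <= length(header) &&
                   header[i + 1L] == "Term Source REF")
                   grid[, i + 1L] else rep("", nrow(grid))
        acc <- if (!is.na(i) && i + 2L <= length(header) &&
                   header[i + 1L] == "Term Source REF" &&
                   header[i + 2L] == "Term Accession Number")
                   grid[, i + 2L] else rep("", nrow(grid))
        list(src = src, acc = acc)
    }
    traitAnn <- annotated("Trait")
    methodAnn <- annotated("Method")
    scaleAnn <- annotated("Scale")
    cls <- colOf("Comment[Variable class]")
    cls[!nzchar(cls)] <- "unspecified"
    ids <- colOf("Variable ID")
    if (any(!nzchar(ids)))
        stop("empty Variable ID in ", fname)
    if (anyDuplicated(ids))
        stop("duplicated Variable ID in ", fname, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    TraitDefinitions(fname, data.frame(
        variable_id = ids,
        trait = colOf("Trait"),
        trait_source_ref = traitAnn$src, trait_accession = traitAnn$acc,
        method = colOf("Method"),
        method_source_ref = methodAnn$src, method_accession = methodAnn$acc,
        scale = colOf("Scale"),
        scale_source_ref = scaleAnn$src, scale_accession = scaleAnn$acc,
        variable_class = cls,
        stringsAsFactors = FALSE))
}

#' @rdname readTDF
#' @param tdf a [TraitDefinitions-class] to serialise.
#' @export
writeTDF <- function(tdf, path) {
    validObject(tdf)
    d <- tdf@defs
    header <- c("Variable ID",
                "Trait", "Term Source REF", "Term Accession Number",
                "Method", "Term Source REF", "Term Accession Number",
                "Scale", "Term Source REF", "Term Accession Number",
                "Comment[Variable class]")
    cls <- d$variable_class
    cls[cls == "unspecified"] <- ""
    body <- cbind(d$variable_id,
                  d$trait, d$trait_source_ref, d$trait_accession,
                  d$method, d$method_source_ref, d$method_accession,
                  d$scale, d$scale_source_ref, d$scale_accession,
                  cls)
    lines <- c(.formatCells(header),
               if (nrow(body)) apply(body, 1L, .formatCells))
    .writeTextLines(lines, path)
}

#' @describeIn readTDF number of variables, optionally by class.
#' @param class restrict to "phenotypic", "environmental" or "unspecified".
#' @export
variableCount <- function(tdf, class = NULL) {
    d <- tdf@defs
    if (!is.null(class))
        d <- d[d$variable_class %in% class, , drop = FALSE]
    nrow(d)
}

#' @describeIn readTDF the Variable ID column.
#' @export
variableIds <- function(tdf) tdf@defs$variable_id

setMethod("show", "TraitDefinitions", function(object) {
    cls <- table(factor(object@defs$variable_class,
                        c("phenotypic", "environmental", "unspecified")))
    cat(sprintf(
        "TraitDefinitions '%s': %d variable(s) (%d phenotypic, %d environmental, %d unspecified)\n",
        object@sourceFile, nrow(object@defs), cls[["phenotypic"]],
        cls[["environmental"]], cls[["unspecified"]]))
})
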