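# Independent brute-force compliance counter: scans the written files of a
# dataset directory with plain base R (readLines/strsplit), counting the
# essential checklist attributes present, without touching the package's
# parsing or validation code paths. Serves as the oracle for the
# compliance-score tests.

.oracleReadGrid <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    cells <- strsplit(lines, "\t", fixed = TRUE)
    n <- length(cells[[1L]])
    list(header = cells[[1L]],
         rows = lapply(cells[-1L], function(x) c(x, rep("", n))[seq_len(n)]))
}

.oracleColumn <- function(grid, name) {
    at <- which(grid$header == name)
    if (!length(at))
        return(NULL)
    vapply(grid$rows, `[[`, character(1), at[1L])
}

bruteComplianceScore <- function(dir, kind) {
    files <- list.files(dir)
    ifile <- files[grepl("^i_", files)][1L]
    ilines <- readLines(file.path(dir, ifile))
    invHas <- function(key) {
        hit <- ilines[startsWith(ilines, paste0(key, "\t"))]
        length(hit) > 0 &&
            any(nzchar(strsplit(hit[1L], "\t", fixed = TRUE)[[1L]][-1L]))
    }
    sgrids <- lapply(files[grepl("^s_", files)],
                     function(f) .oracleReadGrid(file.path(dir, f)))
    agrids <- lapply(files[grepl("^a_", files)],
                     function(f) .oracleReadGrid(file.path(dir, f)))
    charPresent <- function(qual) {
        any(vapply(sgrids, function(g) {
            v <- .oracleColumn(g, paste0("Characteristics[", qual, "]"))
            !is.null(v) && any(nzchar(v))
        }, logical(1)))
    }
    protoPresent <- function(name) {
        any(vapply(sgrids, function(g) {
            refs <- which(g$header == "Protocol REF")
            for (k in seq_along(refs)) {
                from <- refs[k]
                to <- if (k < length(refs)) refs[k + 1L] - 1L
                      else length(g$header)
                vals <- vapply(g$rows, `[[`, character(1), from)
                if (!any(vals == name))
                    next
                params <- which(startsWith(g$header, "Parameter Value["))
                params <- params[params >= from & params <= to]
                for (p in params)
                    if (any(nzchar(vapply(g$rows, `[[`, character(1), p))))
                        return(TRUE)
            }
            FALSE
        }, logical(1)))
    }
    assayCol <- function(name) {
        any(vapply(agrids, function(g) {
            v <- .oracleColumn(g, name)
            !is.null(v) && any(nzchar(v))
        }, logical(1)))
    }
    # trait definition files named in the assays
    tdfFiles <- unique(unlist(lapply(agrids, function(g)
        .oracleColumn(g, "Parameter Value[Trait Definition File]"))))
    tdfFiles <- tdfFiles[!is.null(tdfFiles) & nzchar(tdfFiles)]
    tdfFiles <- tdfFiles[file.exists(file.path(dir, tdfFiles))]
    tdfComplete <- function(classes) {
        any(vapply(tdfFiles, function(f) {
            g <- .oracleReadGrid(file.path(dir, f))
            cls <- .oracleColumn(g, "Comment[Variable class]")
            if (is.null(cls))
                cls <- rep("", length(g$rows))
            cls[!nzchar(cls)] <- "unspecified"
            tr <- .oracleColumn(g, "Trait")
            me <- .oracleColumn(g, "Method")
            sc <- .oracleColumn(g, "Scale")
            any(cls %in% classes & nzchar(tr) & nzchar(me) & nzchar(sc))
        }, logical(1)))
    }
    envDeclared <- any(vapply(tdfFiles, function(f) {
        g <- .oracleReadGrid(file.path(dir, f))
        cls <- .oracleColumn(g, "Comment[Variable class]")
        !is.null(cls) && any(cls == "environmental")
    }, logical(1)))

    present <- c(
        invHas("Investigation Identifier"),
        invHas("Investigation Title"),
        invHas("Investigation Description"),
        charPresent("Study start"),
        charPresent("Study duration"),
        charPresent("Geographic location"),
        charPresent("Organism"),
        charPresent("Infraspecific name"),
        charPresent("Seed origin"),
        charPresent("Growth facility"),
        assayCol("Characteristics[Plant body of interest]"),
        assayCol("Derived Data File"),
        tdfComplete(c("phenotypic", "unspecified")))
    if (kind %in% c("field", "greenhouse"))
        present <- c(present,
                     protoPresent("Aerial conditions"),
                     protoPresent("Rooting"),
                     protoPresent("Nutrition"),
                     protoPresent("Watering"),
                     protoPresent("Sampling"))
    if (envDeclared)
        present <- c(present, tdfComplete("environmental"))
    sum(present) / length(present)
}
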