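# Small deterministic fixtures used across the suite. Sizes are reduced
# relative to the generator defaults to keep tests fast; the defaults
# themselves are exercised in the acceptance tests.

smallBasic <- function(seed = 7, sources = 5, reps = 2, vars = 4)
    generateDataset("basic_gwas", seed = seed, sources = sources,
                    reps = reps, vars = vars)

smallField <- function(seed = 42, lines = 4, parents = 2, years = 2,
                       reps = 2)
    generateDataset("field_multiyear", seed = seed, lines = lines,
                    parents = parents, years = years, reps = reps)

smallGreenhouse <- function(seed = 1, plants = 8, vars = 2)
    generateDataset("greenhouse_hts", seed = seed, plants = plants,
                    vars = vars)

writeTempDataset <- function(dataset, name = "ds") {
    dir <- file.path(tempfile(name), "d")
    writeDataset(dataset, dir)
    dir
}

errorCodes <- function(report) {
    iss <- if (is.data.frame(report)) report else issues(report)
    unique(iss$code[iss$severity == "error"])
}

issueTable <- function(dataset, kind) {
    rep <- validateDataset(dataset, kind)
    issues(rep$validation)
}

# Expand a configuration plan into (header, expected-protocol) pairs with
# Unit columns in place, for comparison against the schema transcription.
expandedPlan <- function(config) {
    p <- config@plan
    out <- data.frame(header = character(0), expected = character(0),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(p))) {
        out <- rbind(out, data.frame(header = p$header[i],
                                     expected = p$expected[i],
                                     stringsAsFactors = FALSE))
        if (p$unitFollows[i])
            out <- rbind(out, data.frame(header = "Unit", expected = "",
                                         stringsAsFactors = FALSE))
    }
    out
}

# Parse one column of the schema-transcription fixture into the same shape.
schemaColumn <- function(which) {
    path <- system.file("extdata", "phenotyping_study_schemas.tsv",
                        package = "phenotab")
    lines <- readLines(path)
    grid <- lapply(strsplit(lines[-1], "\t", fixed = TRUE),
                   function(x) c(x, "", "")[1:3])
    col <- vapply(grid, `[[`, character(1),
                  match(which, c("Basic", "Field", "Greenhouse")))
    col <- col[nzchar(col)]
    parsed <- lapply(col, parseHeader)
    data.frame(header = vapply(parsed, formatHeader, character(1)),
               expected = vapply(parsed, methods::slot, character(1),
                                 "expected"),
               stringsAsFactors = FALSE)
}
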