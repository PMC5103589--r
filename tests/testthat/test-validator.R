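test_that("generated fixtures validate with zero errors", {
    for (fix in list(list(smallBasic(), "basic"),
                     list(smallField(), "field"),
                     list(smallGreenhouse(), "greenhouse"))) {
        rep <- validateDataset(fix[[1]], fix[[2]])
        iss <- issues(rep$validation)
        expect_equal(sum(iss$severity == "error"), 0, label = fix[[2]])
        expect_equal(sum(iss$severity == "warning"), 0, label = fix[[2]])
    }
})

test_that("a deleted protocol block is reported as one missing-column group", {
    d <- smallField()
    s <- d@studies[[1]]
    texts <- vapply(s@headers, formatHeader, character(1))
    # drop the Watering block: its Protocol REF column and 3 parameters
    refCols <- which(texts == "Protocol REF")
    watering <- refCols[vapply(refCols, function(i)
        s@rows[1, i] == "Watering", logical(1))]
    drop <- watering:(watering + 3)
    s2 <- new("StudyTable", sourceFile = s@sourceFile,
              headers = s@headers[-drop],
              rows = s@rows[, -drop, drop = FALSE])
    iss <- validateTable(s2, builtinConfig("field"))
    missing <- iss[iss$code == "MISSING_COLUMN", ]
    expect_equal(nrow(missing), 4)  # protocol + its 3 parameters
    expect_true(any(grepl("Watering", missing$message)))
    expect_equal(unique(missing$severity), "error")
})

test_that("empty cells in required columns are warnings, not errors", {
    d <- smallField()
    s <- d@studies[[1]]
    texts <- vapply(s@headers, formatHeader, character(1))
    col <- which(texts == "Characteristics[Seed origin]")
    s@rows[, col] <- ""
    iss <- validateTable(s, builtinConfig("field"))
    expect_equal(sum(iss$severity == "error"), 0)
    empt <- iss[iss$code == "EMPTY_ESSENTIAL_CELL", ]
    expect_equal(nrow(empt), nrow(s@rows))
    expect_equal(empt$column[1], "Characteristics[Seed origin]")
    # rows are 1-based counting the header row as row 1
    expect_equal(empt$row[1], "2")
})

test_that("a scaffold validates cleanly against its own configuration", {
    for (kind in c("basic", "field", "greenhouse")) {
        dir <- tempfile()
        ds <- scaffoldDataset(kind, dir)
        rep <- validateDataset(readDataset(dir), kind)
        iss <- issues(rep$validation)
        expect_equal(sum(iss$severity %in% c("error", "warning")), 0,
                     label = kind)
        expect_equal(complianceScore(rep$compliance), 0, label = kind)
        expect_false(any(rep$compliance@table$present))
        unlink(dir, recursive = TRUE)
    }
})

test_that("undeclared protocols are warnings tied to the investigation", {
    d <- smallField()
    d2 <- injectDefect(d, "UNDECLARED_PROTOCOL")
    iss <- issueTable(d2, "field")
    hit <- iss[iss$code == "UNDECLARED_PROTOCOL", ]
    expect_gt(nrow(hit), 0)
    expect_equal(unique(hit$severity), "warning")
    expect_true(any(grepl("Sampling", hit$message)))
    expect_equal(sum(iss$severity == "error"), 0)
})

test_that("extra well-formed columns are informational only", {
    d <- smallBasic()
    s <- d@studies[[1]]
    n <- length(s@headers)
    headers <- append(s@headers, list(FieldHeader("CHARACTERISTICS",
                                                  "Altitude")),
                      after = n - 1)
    rows <- cbind(s@rows[, 1:(n - 1), drop = FALSE], "120 m",
                  s@rows[, n, drop = FALSE])
    s2 <- new("StudyTable", sourceFile = s@sourceFile, headers = headers,
              rows = rows)
    iss <- validateTable(s2, builtinConfig("basic"))
    expect_equal(unique(iss$severity), "info")
    expect_equal(unique(iss$code), "EXTRA_COLUMN")
    expect_true(any(grepl("Altitude", iss$column)))
})

test_that("cross-file link breakage is located precisely", {
    d <- smallBasic()
    d2 <- injectDefect(d, "BROKEN_SAMPLE_LINK")
    iss <- validateLinks(d2)
    hit <- iss[iss$code == "BROKEN_SAMPLE_LINK", ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$row, "2")  # first data row
    expect_true(grepl("P999_unused", hit$message))

    iss <- validateLinks(injectDefect(d, "UNKNOWN_VARIABLE_ID"))
    expect_true("UNKNOWN_VARIABLE_ID" %in% iss$code)
    iss <- validateLinks(injectDefect(d, "ORPHAN_DATA_ROW"))
    expect_equal(iss$code[iss$severity == "warning"], "ORPHAN_DATA_ROW")
    expect_equal(nrow(validateLinks(d)), 0)
})

test_that("deleting the trait definition file yields exactly one new error", {
    d <- smallField()
    base <- issueTable(d, "field")
    mutated <- issueTable(injectDefect(d, "MISSING_FILE"), "field")
    baseErr <- base[base$severity == "error", ]
    mutErr <- mutated[mutated$severity == "error", ]
    expect_equal(nrow(baseErr), 0)
    expect_equal(nrow(mutErr), 2)  # one reference per assay file
    expect_equal(unique(mutErr$code), "MISSING_FILE")
})

test_that("every documented defect code triggers itself and nothing worse", {
    codes <- c("MISSING_COLUMN", "EMPTY_ESSENTIAL_CELL",
               "UNDECLARED_PROTOCOL", "BROKEN_SAMPLE_LINK",
               "UNKNOWN_VARIABLE_ID", "ORPHAN_DATA_ROW",
               "DUPLICATE_HEADER", "RAGGED_ROW", "MISSING_FILE")
    warningCodes <- c("EMPTY_ESSENTIAL_CELL", "UNDECLARED_PROTOCOL",
                      "ORPHAN_DATA_ROW")
    d <- smallField()
    for (code in codes) {
        if (code == "RAGGED_ROW") {
            dir <- injectDefect(d, code, dir = tempfile())
            mutated <- readDataset(dir)
            unlink(dir, recursive = TRUE)
        } else {
            mutated <- injectDefect(d, code)
        }
        iss <- issueTable(mutated, "field")
        expect_true(code %in% iss$code, info = code)
        if (code %in% warningCodes) {
            expect_equal(sum(iss$severity == "error"), 0, info = code)
        } else {
            expect_equal(errorCodes(iss), code, info = code)
        }
    }
    expect_error(injectDefect(d, "NOT_A_CODE"), "unknown defect code")
})

test_that("duplicate property columns are errors", {
    d <- smallBasic()
    d2 <- injectDefect(d, "DUPLICATE_HEADER")
    iss <- issueTable(d2, "basic")
    hit <- iss[iss$code == "DUPLICATE_HEADER", ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$column, "Characteristics[Organism]#2")
})

test_that("validation is idempotent and deterministically ordered", {
    d <- injectDefect(smallField(), "EMPTY_ESSENTIAL_CELL")
    r1 <- issueTable(d, "field")
    r2 <- issueTable(d, "field")
    expect_identical(r1, r2)
})

test_that("blanking cells never decreases the issue count", {
    d <- smallField(seed = 5)
    base <- nrow(issueTable(d, "field"))
    set.seed(99)
    for (rep in 1:12) {
        d2 <- d
        sname <- sample(names(d2@studies), 1)
        s <- d2@studies[[sname]]
        i <- sample(nrow(s@rows), 1)
        j <- sample(ncol(s@rows), 1)
        s@rows[i, j] <- ""
        d2@studies[[sname]] <- s
        after <- issueTable(d2, "field")
        expect_gte(nrow(after), base)
    }
})
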