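tdfLines <- function(...) {
    path <- tempfile(fileext = ".txt")
    writeLines(c(...), path)
    path
}

test_that("trait definition files parse with annotations and classes", {
    path <- tdfLines(
        "Variable ID\tTrait\tTerm Source REF\tTerm Accession Number\tMethod\tScale\tComment[Variable class]",
        "PH\tplant height\tTO\tTO:0000207\truler\tcm\tphenotypic",
        "TP\ttotal precipitation\t\t\tstation\tmm\tenvironmental")
    tdf <- readTDF(path)
    expect_equal(variableCount(tdf), 2)
    expect_equal(variableIds(tdf), c("PH", "TP"))
    expect_equal(tdf@defs$trait_source_ref, c("TO", ""))
    expect_equal(tdf@defs$trait_accession, c("TO:0000207", ""))
    expect_equal(tdf@defs$variable_class, c("phenotypic", "environmental"))
})

test_that("minimal trait definition files default to empty annotations", {
    path <- tdfLines("Variable ID\tTrait\tMethod\tScale",
                     "PH\tplant height\truler\tcm",
                     "TN\ttiller number\tcount\tcount")
    tdf <- readTDF(path)
    expect_equal(variableCount(tdf), 2)
    expect_true(all(tdf@defs$trait_source_ref == ""))
    expect_true(all(tdf@defs$variable_class == "unspecified"))
})

test_that("malformed trait definition files are rejected", {
    expect_error(readTDF(tdfLines("Variable ID\tTrait\tMethod\tScale",
                                  "PH\ta\tb\tc", "PH\td\te\tf")),
                 "duplicated Variable ID")
    expect_error(readTDF(tdfLines("Variable ID\tTrait\tMethod",
                                  "PH\ta\tb")),
                 "missing mandatory column")
    empty <- tempfile(); file.create(empty)
    expect_error(readTDF(empty), "empty trait definition file")
})

test_that("trait definitions round-trip through read-write-read", {
    d <- smallField()
    tdf <- d@traitDefinitions[[1]]
    path <- tempfile(fileext = ".txt")
    writeTDF(tdf, path)
    back <- readTDF(path)
    expect_equal(back@defs, tdf@defs)
})

test_that("data matrices parse and honour the extended data-node rule", {
    path <- tempfile()
    writeLines(c("Assay Name\tPH\tTN",
                 "a1\t10.2\t4", "a2\t11.0\t5", "a3\tNA\t3"), path)
    m <- readDataMatrix(path)
    expect_equal(m@linkNode, "Assay Name")
    expect_equal(dim(m), c(3L, 2L))
    expect_equal(sum(missingMask(m)), 1)

    writeLines(c("Sample Name\tPH", "s1\t10"), path)
    m <- readDataMatrix(path)
    expect_equal(m@linkNode, "Sample Name")
    expect_error(readDataMatrix(path, expectedLinkNode = "Assay Name"),
                 "links on")

    writeLines(c("Assay Name\tPH\tTN", "a1\t10.2"), path)
    expect_error(readDataMatrix(path), "ragged row")
    writeLines(c("Assay Name\tPH", "a1\t1", "a1\t2"), path)
    expect_error(readDataMatrix(path), "duplicated row id")
    writeLines(c("\tPH", "a1\t1"), path)
    expect_error(readDataMatrix(path), "empty header")
    writeLines("Assay Name\tPH", path)
    expect_error(readDataMatrix(path), "at least one row")
})

test_that("linking produces one record per resolvable non-missing cell", {
    d <- smallBasic(sources = 3, reps = 2, vars = 4)  # 6 rows x 4 vars
    assay <- d@assays[[1]]
    tdf <- d@traitDefinitions[[1]]
    m <- d@dataFiles[[1]]
    got <- linkObservations(assay, tdf, m)
    nMissing <- sum(missingMask(m))
    expect_equal(nrow(got$records), 6 * 4 - nMissing)
    expect_equal(nrow(got$issues), 0)
    # exhaustive enumeration oracle
    expected <- list()
    for (i in seq_len(nrow(m@values)))
        for (j in seq_len(ncol(m@values)))
            if (!m@values[i, j] %in% c("", "NA"))
                expected[[length(expected) + 1]] <-
                    c(rownames(m@values)[i], colnames(m@values)[j],
                      m@values[i, j])
    expect_equal(nrow(got$records), length(expected))
    expect_equal(unname(as.matrix(got$records)),
                 do.call(rbind, expected))
})

test_that("orphan rows are excluded and reported, not dropped silently", {
    d <- smallBasic(sources = 3, reps = 2, vars = 4)
    m <- d@dataFiles[[1]]
    rownames(m@values)[2] <- "nobody"
    got <- linkObservations(d@assays[[1]], d@traitDefinitions[[1]], m)
    expect_equal(got$issues$code, "ORPHAN_DATA_ROW")
    expect_false("nobody" %in% got$records$row_id)
    expect_equal(nrow(got$records), 5 * 4 - sum(missingMask(m)[-2, ]))
})

test_that("linking fails cleanly when the link node is absent", {
    d <- smallBasic(sources = 2, reps = 1, vars = 2)
    m <- d@dataFiles[[1]]
    m@linkNode <- "Extract Name"
    expect_error(linkObservations(d@assays[[1]], d@traitDefinitions[[1]],
                                  m),
                 "link node column")
})

test_that("aggregation partitions a two-year fixture by study start", {
    d <- smallField()
    got <- aggregateObservations(d, by = "Study start")
    expect_true(all(c("2012-05-10", "2013-05-10") %in%
                    got$records$`Study start`))
    expect_equal(length(unique(got$records$`Study start`)), 2)
    tab <- table(got$records$`Study start`, got$records$study)
    expect_equal(sum(tab["2012-05-10", "s_study2.txt"]), 0)
    expect_equal(sum(tab["2013-05-10", "s_study1.txt"]), 0)
})

test_that("aggregating then filtering equals linking a study alone", {
    d <- smallField()
    got <- aggregateObservations(d, by = "Study start")
    one <- got$records[got$records$study == "s_study1.txt", ]
    direct <- linkObservations(d@assays[[1]], d@traitDefinitions[[1]],
                               d@dataFiles[[1]],
                               study = d@studies[[1]])$records
    expect_equal(one[, c("row_id", "variable_id", "value")], direct,
                 ignore_attr = TRUE)
})

test_that("a missing grouping characteristic yields group 'unknown'", {
    d <- smallBasic(sources = 2, reps = 1, vars = 2)
    got <- aggregateObservations(d, by = "Altitude")
    expect_true(all(got$records$Altitude == "unknown"))
    expect_true("MISSING_GROUP_KEY" %in% got$issues$code)
})

test_that("an empty grouping is the identity on a single dataset", {
    d <- smallBasic(sources = 2, reps = 2, vars = 3)
    agg <- aggregateObservations(d)$records
    direct <- linkObservations(d@assays[[1]], d@traitDefinitions[[1]],
                               d@dataFiles[[1]])$records
    expect_equal(agg[, c("row_id", "variable_id", "value")], direct,
                 ignore_attr = TRUE)
})

test_that("conflicting trait definitions across files are reported", {
    d1 <- smallField(seed = 1)
    d2 <- smallField(seed = 2)
    t2 <- d2@traitDefinitions[[1]]
    t2@defs$scale[1] <- "inches"
    t2@sourceFile <- "tdf_other.txt"
    d2@traitDefinitions <- list(tdf_other.txt = t2)
    # keep the assay reference pointing at the renamed file
    for (a in names(d2@assays)) {
        tab <- d2@assays[[a]]
        tab@rows[tab@rows == "tdf_field.txt"] <- "tdf_other.txt"
        d2@assays[[a]] <- tab
    }
    got <- aggregateObservations(list(d1, d2))
    conflict <- got$issues[got$issues$code == "TDF_CONFLICT", ]
    expect_equal(conflict$column, d1@traitDefinitions[[1]]@defs$variable_id[1])
})

test_that("summaries report the structural counts", {
    d <- smallBasic(sources = 5, reps = 2, vars = 3)
    s <- summarizeDataset(d)
    expect_equal(s$studies, 1)
    expect_equal(unname(s$sourcesPerStudy), 5)
    expect_equal(s$samples, 10)
    expect_equal(s$variables, 3)
    expect_equal(s$matrixDims[[1]], c(10L, 3L))

    empty <- PhenoDataset()
    s0 <- summarizeDataset(empty)
    expect_equal(s0$studies, 0)
    expect_equal(s0$samples, 0)
    expect_equal(s0$variables, 0)
})
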