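test_that("a written dataset reads back structurally identical", {
    d <- smallField()
    dir <- writeTempDataset(d)
    d2 <- readDataset(dir)
    expect_true(isTRUE(datasetEqual(d, d2)))
    expect_equal(length(d2@studies), 2)
    expect_equal(length(d2@assays), 2)
    expect_equal(length(d2@traitDefinitions), 1)
    expect_equal(length(d2@dataFiles), 2)
    unlink(dirname(dir), recursive = TRUE)
})

test_that("serialisation is deterministic byte for byte", {
    d <- smallBasic()
    dir1 <- writeTempDataset(d)
    dir2 <- writeTempDataset(d)
    for (f in list.files(dir1)) {
        b1 <- readBin(file.path(dir1, f), "raw", n = 10^7)
        b2 <- readBin(file.path(dir2, f), "raw", n = 10^7)
        expect_identical(b1, b2, label = f)
    }
    unlink(c(dirname(dir1), dirname(dir2)), recursive = TRUE)
})

test_that("reading never mutates the files", {
    d <- smallBasic()
    dir <- writeTempDataset(d)
    before <- lapply(list.files(dir, full.names = TRUE), readBin,
                     what = "raw", n = 10^7)
    invisible(readDataset(dir))
    after <- lapply(list.files(dir, full.names = TRUE), readBin,
                    what = "raw", n = 10^7)
    expect_identical(before, after)
    unlink(dirname(dir), recursive = TRUE)
})

test_that("directories without exactly one investigation file are rejected", {
    empty <- tempfile()
    dir.create(empty)
    expect_error(readDataset(empty), "no investigation file")
    writeLines("INVESTIGATION", file.path(empty, "i_a.txt"))
    writeLines("INVESTIGATION", file.path(empty, "i_b.txt"))
    expect_error(readDataset(empty), "multiple investigation files")
    expect_error(readDataset(tempfile()), "no such directory")
    unlink(empty, recursive = TRUE)
})

test_that("ragged rows are reported with file, row and column", {
    d <- smallBasic()
    dir <- writeTempDataset(d)
    sfile <- file.path(dir, "s_study1.txt")
    lines <- readLines(sfile)
    lines[3] <- sub("\t[^\t]*$", "", lines[3])
    writeLines(lines, sfile)
    d2 <- readDataset(dir)
    iss <- d2@parseIssues
    hit <- iss[iss$code == "RAGGED_ROW", ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$file, "s_study1.txt")
    expect_equal(hit$row, "3")
    expect_equal(hit$severity, "error")
    unlink(dirname(dir), recursive = TRUE)
})

test_that("ragged in-memory rows are refused before any file is written", {
    headers <- parseHeaders(c("Source Name", "Sample Name"))
    expect_error(StudyTable("s_x.txt", headers,
                            list(c("a", "s1"), c("b"))),
                 "ragged")
})

test_that("quoted cells survive a round trip", {
    d <- smallBasic(sources = 2, reps = 1, vars = 2)
    s <- d@studies[[1]]
    s@rows[1, 2] <- 'Arabidopsis "mouse-ear" cress'
    d@studies[[1]] <- s
    dir <- writeTempDataset(d)
    d2 <- readDataset(dir)
    expect_equal(d2@studies[[1]]@rows[1, 2],
                 'Arabidopsis "mouse-ear" cress')
    expect_true(isTRUE(datasetEqual(d, d2)))
    unlink(dirname(dir), recursive = TRUE)
})

test_that("cells containing tabs or newlines are rejected on write", {
    d <- smallBasic(sources = 2, reps = 1, vars = 2)
    s <- d@studies[[1]]
    s@rows[1, 2] <- "bad\tvalue"
    d@studies[[1]] <- s
    expect_error(writeDataset(d, tempfile()), "tabs or newlines")
})

test_that("investigation records round-trip including factors and contacts", {
    d <- smallGreenhouse()
    dir <- writeTempDataset(d)
    inv <- readDataset(dir)@investigation
    expect_equal(inv@identifier, "SYNTH-GREENHOUSE-HTS")
    st <- inv@studies[[1]]
    expect_equal(st@factors$name, c("Plant movement", "Soil cover"))
    expect_true("Rooting" %in% st@protocols$name)
    expect_equal(st@assayFiles, "a_study1_imaging.txt")
    expect_equal(inv@ontologySources$name, c("CO", "TO", "NCBITaxon"))
    unlink(dirname(dir), recursive = TRUE)
})

test_that("nonconforming file names are warned about on read", {
    d <- smallBasic(sources = 2, reps = 1, vars = 2)
    names(d@studies) <- "study1.txt"
    d@studies[[1]]@sourceFile <- "study1.txt"
    d@investigation@studies[[1]]@fileName <- "study1.txt"
    expect_error(writeDataset(d, tempfile()), "must start with 's_'")
    # write manually to exercise the read-side warning
    dir <- tempfile(); dir.create(dir)
    writeDataset(smallBasic(sources = 2, reps = 1, vars = 2), dir)
    file.rename(file.path(dir, "s_study1.txt"),
                file.path(dir, "study1.txt"))
    ilines <- readLines(file.path(dir, "i_investigation.txt"))
    ilines <- sub("^Study File Name\ts_study1.txt",
                  "Study File Name\tstudy1.txt", ilines)
    writeLines(ilines, file.path(dir, "i_investigation.txt"))
    d2 <- readDataset(dir)
    expect_true("NAMING_CONVENTION" %in% d2@parseIssues$code)
    unlink(dir, recursive = TRUE)
})
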