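test_that("identical inputs give byte-identical dataset trees", {
    for (spec in list(list("basic_gwas", list(sources = 3, reps = 2,
                                              vars = 5)),
                      list("field_multiyear", list(lines = 3, parents = 2,
                                                   years = 2, reps = 1)),
                      list("greenhouse_hts", list(plants = 8, vars = 2)))) {
        d1 <- do.call(generateDataset,
                      c(list(profile = spec[[1]], seed = 123), spec[[2]]))
        d2 <- do.call(generateDataset,
                      c(list(profile = spec[[1]], seed = 123), spec[[2]]))
        dir1 <- writeTempDataset(d1)
        dir2 <- writeTempDataset(d2)
        expect_identical(list.files(dir1), list.files(dir2))
        for (f in list.files(dir1))
            expect_identical(readBin(file.path(dir1, f), "raw", 10^7),
                             readBin(file.path(dir2, f), "raw", 10^7),
                             label = paste(spec[[1]], f))
        unlink(c(dirname(dir1), dirname(dir2)), recursive = TRUE)
        # and different seeds differ
        d3 <- do.call(generateDataset,
                      c(list(profile = spec[[1]], seed = 124), spec[[2]]))
        expect_false(isTRUE(datasetEqual(d1, d3)))
    }
})

test_that("generation does not disturb the caller's random stream", {
    set.seed(500)
    before <- runif(3)
    set.seed(500)
    invisible(generateDataset("basic_gwas", seed = 9, sources = 2,
                              reps = 1, vars = 2))
    after <- runif(3)
    expect_identical(before, after)
})

test_that("every profile at several seeds validates with zero errors", {
    for (seed in c(2, 13, 77)) {
        for (profile in c("basic_gwas", "field_multiyear",
                          "greenhouse_hts")) {
            d <- switch(profile,
                basic_gwas = smallBasic(seed = seed),
                field_multiyear = smallField(seed = seed),
                greenhouse_hts = smallGreenhouse(seed = seed))
            rep <- validateDataset(d, profileConfigKind(profile))
            expect_equal(sum(issues(rep$validation)$severity == "error"),
                         0, label = paste(profile, seed))
            expect_equal(complianceScore(rep$compliance), 1,
                         label = paste(profile, seed))
        }
    }
})

test_that("the field profile reproduces the published structural counts", {
    d <- generateDataset("field_multiyear", seed = 42)
    s <- summarizeDataset(d)
    expect_equal(s$studies, 2)
    expect_equal(unname(s$sourcesPerStudy), c(102, 102))
    expect_equal(s$variables, 10)
    expect_equal(s$phenotypicVariables, 8)
    expect_equal(s$environmentalVariables, 2)
    expect_equal(s$assays, 2)
    expect_equal(s$dataFiles, 2)
})

test_that("the greenhouse profile is a balanced two-by-two factorial", {
    d <- smallGreenhouse(plants = 16)
    s <- d@studies[[1]]
    texts <- vapply(s@headers, formatHeader, character(1))
    move <- s@rows[, which(texts == "Factor Value[Plant movement]")]
    cover <- s@rows[, which(texts == "Factor Value[Soil cover]")]
    expect_setequal(unique(move), c("rotating", "stationary"))
    expect_setequal(unique(cover), c("covered", "uncovered"))
    expect_true(all(table(move, cover) == 4))
})

test_that("environmental values are constant within a study", {
    d <- smallField()
    for (m in d@dataFiles) {
        for (v in c("VPD", "TP"))
            expect_equal(length(unique(m@values[, v])), 1)
    }
    # but differ between the two seasons
    expect_false(d@dataFiles[[1]]@values[1, "TP"] ==
                 d@dataFiles[[2]]@values[1, "TP"])
})

test_that("around two percent of phenotypic cells are missing at scale", {
    d <- generateDataset("field_multiyear", seed = 8)
    m <- d@dataFiles[[1]]
    pheno <- m@values[, 1:8]
    frac <- mean(pheno == "")
    expect_gt(frac, 0.005)
    expect_lt(frac, 0.05)
    # environmental columns stay complete
    expect_true(all(nzchar(m@values[, 9:10])))
})

test_that("invalid generator parameters are refused", {
    expect_error(generateDataset("basic_gwas", seed = 1, sources = 0),
                 "positive")
    expect_error(generateDataset("basic_gwas", seed = 1, vars = 0),
                 "positive")
    expect_error(generateDataset("field_multiyear", seed = 1, lines = 0),
                 "invalid")
    expect_error(generateDataset("nonsense", seed = 1), "arg")
})

test_that("raw image references in the greenhouse profile stay external", {
    d <- smallGreenhouse(plants = 4)
    expect_length(d@externalFiles, 4)
    dir <- writeTempDataset(d)
    d2 <- readDataset(dir)
    expect_equal(d2@externalFiles, d@externalFiles)
    iss <- issueTable(d2, "greenhouse")
    expect_equal(sum(iss$severity == "error"), 0)
    expect_true("EXTERNAL_FILE" %in% iss$code)
    unlink(dirname(dir), recursive = TRUE)
})
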