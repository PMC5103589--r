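blankStudyColumn <- function(dataset, header, study = 1) {
    s <- dataset@studies[[study]]
    texts <- vapply(s@headers, formatHeader, character(1))
    at <- which(texts == header)
    s@rows[, at] <- ""
    dataset@studies[[study]] <- s
    dataset
}

test_that("complete fixtures score exactly 1 in every section", {
    for (fix in list(list(smallBasic(), "basic"),
                     list(smallField(), "field"),
                     list(smallGreenhouse(), "greenhouse"))) {
        rep <- miappeCompliance(fix[[1]], fix[[2]])
        expect_equal(complianceScore(rep), 1, label = fix[[2]])
        expect_true(all(complianceTable(rep)$present))
    }
    expect_error(miappeCompliance(smallBasic(), "lunar"), "unknown")
})

test_that("sections follow the checklist and presence drives the score", {
    rep <- miappeCompliance(smallField(), "field")
    tab <- complianceTable(rep)
    expect_setequal(unique(tab$section),
                    c("General metadata", "Timing and location",
                      "Biosource", "Environment", "Experimental design",
                      "Sample collection, processing, management",
                      "Observed variables"))
    # 18 unconditional attributes + environmental variables (declared here)
    expect_equal(nrow(tab), 19)
    expect_equal(complianceScore(rep), sum(tab$present) / nrow(tab))
})

test_that("blanking a geographic location column is reported as missing", {
    d <- blankStudyColumn(smallBasic(),
                          "Characteristics[Geographic location]")
    rep <- miappeCompliance(d, "basic")
    tab <- complianceTable(rep)
    row <- tab[tab$attribute == "Geographic location", ]
    expect_equal(row$section, "Timing and location")
    expect_false(row$present)
    expect_equal(complianceScore(rep), (nrow(tab) - 1) / nrow(tab))
})

test_that("blanking the nutrition parameters loses the fertiliser attribute", {
    d <- smallField()
    for (k in seq_along(d@studies)) {
        s <- d@studies[[k]]
        texts <- vapply(s@headers, formatHeader, character(1))
        for (h in c("Parameter Value[N before fertilisation]",
                    "Parameter Value[Type of fertiliser]",
                    "Parameter Value[Amount of fertiliser]"))
            s@rows[, which(texts == h)] <- ""
        d@studies[[k]] <- s
    }
    tab <- complianceTable(miappeCompliance(d, "field"))
    expect_false(tab$present[tab$attribute == "Nutrients"])
    expect_true(all(tab$present[tab$attribute != "Nutrients"]))
})

test_that("environment protocols are applicable only under field/greenhouse", {
    basic <- complianceTable(miappeCompliance(smallBasic(), "basic"))
    expect_false(any(basic$attribute %in%
                     c("Aerial conditions", "Rooting conditions",
                       "Nutrients", "Watering", "Experimental unit")))
    fld <- complianceTable(miappeCompliance(smallField(), "field"))
    expect_true(all(c("Aerial conditions", "Rooting conditions",
                      "Nutrients", "Watering", "Experimental unit") %in%
                    fld$attribute))
})

test_that("environmental variable definitions apply only when declared", {
    withEnv <- complianceTable(miappeCompliance(smallField(), "field"))
    expect_true("Environmental variables" %in% withEnv$attribute)
    noEnv <- complianceTable(miappeCompliance(smallBasic(), "basic"))
    expect_false("Environmental variables" %in% noEnv$attribute)
})

test_that("scores agree with the independent brute-force counter", {
    cases <- list(
        list(smallBasic(), "basic"),
        list(smallField(), "field"),
        list(smallGreenhouse(), "greenhouse"),
        list(blankStudyColumn(smallBasic(),
                              "Characteristics[Geographic location]"),
             "basic"),
        list(blankStudyColumn(smallField(),
                              "Characteristics[Seed origin]", study = 1),
             "field"),
        list(injectDefect(smallField(), "MISSING_FILE"), "field"))
    for (case in cases) {
        dir <- writeTempDataset(case[[1]])
        expect_equal(complianceScore(miappeCompliance(case[[1]],
                                                      case[[2]])),
                     bruteComplianceScore(dir, case[[2]]),
                     label = case[[2]])
        unlink(dirname(dir), recursive = TRUE)
    }
})

test_that("blanking cells or columns never raises the score", {
    d <- smallField(seed = 3)
    full <- complianceScore(miappeCompliance(d, "field"))
    expect_equal(full, 1)
    # column-level blanking, every study column in turn
    s <- d@studies[[1]]
    texts <- vapply(s@headers, formatHeader, character(1))
    for (h in unique(texts)) {
        d2 <- d
        for (k in seq_along(d2@studies))
            d2 <- blankStudyColumn(d2, h, study = k)
        expect_lte(complianceScore(miappeCompliance(d2, "field")), full,
                   label = h)
    }
    # random cell-level blanking
    set.seed(17)
    for (rep in 1:10) {
        d2 <- d
        sname <- sample(names(d2@studies), 1)
        s <- d2@studies[[sname]]
        s@rows[sample(nrow(s@rows), 1), sample(ncol(s@rows), 1)] <- ""
        d2@studies[[sname]] <- s
        expect_lte(complianceScore(miappeCompliance(d2, "field")), full)
    }
})
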