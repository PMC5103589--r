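test_that("headers parse into category and verbatim qualifier", {
    h <- parseHeader("Characteristics[Organism]")
    expect_s4_class(h, "FieldHeader")
    expect_equal(h@category, "CHARACTERISTICS")
    expect_equal(h@qualifier, "Organism")

    h <- parseHeader("Parameter Value[Daily photon flux]")
    expect_equal(h@category, "PARAMETER_VALUE")
    expect_equal(h@qualifier, "Daily photon flux")

    h <- parseHeader("Source Name")
    expect_equal(h@category, "SOURCE_NAME")
    expect_equal(h@qualifier, "")

    # inner whitespace is preserved, outer whitespace trimmed
    h <- parseHeader("  Factor Value[ Watering  regime ]  ")
    expect_equal(h@qualifier, "Watering  regime")
})

test_that("malformed and unknown headers are rejected", {
    expect_error(parseHeader(""), "empty")
    expect_error(parseHeader("   "), "empty")
    expect_error(parseHeader("Characteristics[Organism"), "bracket")
    expect_error(parseHeader("Characteristics Organism]"), "bracket")
    expect_error(parseHeader("Charcteristics[Organism]"), "unknown")
    expect_error(parseHeader("Plot Name"), "unknown")
    expect_error(parseHeader("Unit[cm]"), "does not take a qualifier")
    expect_error(parseHeader("Characteristics"), "requires")
    expect_error(parseHeader("Characteristics[]"), "empty qualifier")
})

test_that("Protocol REF shorthand normalises to an expected cell value", {
    h <- parseHeader("Protocol REF[Rooting]")
    expect_equal(h@category, "PROTOCOL_REF")
    expect_equal(h@qualifier, "")
    expect_equal(h@expected, "Rooting")
    expect_equal(formatHeader(h), "Protocol REF")
})

test_that("formatHeader renders canonical spelling and enforces invariants", {
    expect_equal(formatHeader(FieldHeader("FACTOR_VALUE",
                                          "Watering regime")),
                 "Factor Value[Watering regime]")
    expect_equal(formatHeader(FieldHeader("PROTOCOL_REF")), "Protocol REF")
    expect_equal(formatHeader(FieldHeader("TERM_SOURCE_REF")),
                 "Term Source REF")
    expect_error(FieldHeader("SOURCE_NAME", "x"), "qualifier")
    expect_error(FieldHeader("CHARACTERISTICS"), "requires")
})

test_that("parse-format is the identity on random valid headers", {
    set.seed(11)
    qualifiable <- c("CHARACTERISTICS", "FACTOR_VALUE", "PARAMETER_VALUE",
                     "COMMENT")
    plain <- c("SOURCE_NAME", "SAMPLE_NAME", "EXTRACT_NAME", "ASSAY_NAME",
               "PROTOCOL_REF", "UNIT", "TERM_SOURCE_REF",
               "TERM_ACCESSION_NUMBER", "RAW_DATA_FILE",
               "DERIVED_DATA_FILE")
    alphabet <- c(letters, LETTERS, 0:9, " ", "-", "_", "/", "%", ".")
    for (i in 1:200) {
        if (runif(1) < 0.5) {
            qual <- paste(sample(alphabet, sample(1:20, 1), replace = TRUE),
                          collapse = "")
            qual <- trimws(qual)
            if (!nzchar(qual))
                next
            h <- FieldHeader(sample(qualifiable, 1), qual)
        } else {
            h <- FieldHeader(sample(plain, 1))
        }
        h2 <- parseHeader(formatHeader(h))
        expect_equal(h2@category, h@category)
        expect_equal(h2@qualifier, h@qualifier)
    }
})
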