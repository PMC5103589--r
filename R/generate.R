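## Deterministic generator of MIAPPE-compliant synthetic datasets. Three
## profiles emulate the canonical phenotyping situations: a replicated
## GWAS-style collection under the Basic schema, a two-year field trial of a
## RIL population under the Field schema, and a 2x2 factorial imaging
## experiment under the Greenhouse schema. All randomness flows from one
## Mersenne-Twister stream seeded once per dataset, so identical inputs give
## byte-identical output trees. All constants are synthetic by design and
## marked as such where they appear in the files.

.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    force(expr)
}

.num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

.MISSING_FRACTION <- 0.02  # fraction of phenotypic matrix cells left blank

.applyMissing <- function(values, cols = seq_len(ncol(values))) {
    n <- length(values[, cols])
    if (n == 0L)
        return(values)
    k <- round(.MISSING_FRACTION * n)
    if (k > 0L) {
        hit <- sample.int(n, k)
        sub <- values[, cols, drop = FALSE]
        sub[hit] <- ""
        values[, cols] <- sub
    }
    values
}

.studyTableFromPlan <- function(config, fileName, cellsByHeader, n) {
    headers <- parseHeaders(planHeaders(config))
    texts <- vapply(headers, formatHeader, character(1))
    cols <- lapply(seq_along(headers), function(i) {
        key <- texts[i]
        occ <- sum(texts[seq_len(i)] == key)
        v <- cellsByHeader[[sprintf("%s#%d", key, occ)]]
        if (is.null(v))
            v <- cellsByHeader[[key]]
        if (is.null(v))
            v <- ""
        rep_len(as.character(v), n)
    })
    rows <- do.call(cbind, cols)
    StudyTable(fileName, headers, rows)
}

.protocolDF <- function(config, withDataTransformation = TRUE) {
    names <- configProtocols(config)
    rows <- lapply(names, function(p) data.frame(
        name = p, type = tolower(p),
        description = sprintf("%s conditions of the experiment", p),
        parameters = paste(protocolParameters(config, p), collapse = ";"),
        stringsAsFactors = FALSE))
    if (withDataTransformation)
        rows <- c(rows, list(data.frame(
            name = "Data transformation", type = "data transformation",
            description = "derivation of the observation matrix from raw records",
            parameters = "Trait Definition File",
            stringsAsFactors = FALSE)))
    if (length(rows)) do.call(rbind, rows)
    else .emptyDF("name", "type", "description", "parameters")
}

.assayTable <- function(fileName, samples, assayNames, organ, tdfFile,
                        derivedFile, rawFiles = NULL) {
    headers <- parseHeaders(planHeaders(phenotypingAssayConfig()))
    n <- length(samples)
    rows <- cbind(samples, rep(organ, n), rep("Data transformation", n),
                  rep(tdfFile, n), assayNames,
                  if (is.null(rawFiles)) rep("", n) else rawFiles,
                  rep(derivedFile, n))
    AssayTable(fileName, headers, rows)
}

.syntheticTDF <- function(fileName, ids, traits, methods, scales, classes,
                          ontology = "CO") {
    TraitDefinitions(fileName, data.frame(
        variable_id = ids, trait = traits,
        trait_source_ref = rep(ontology, length(ids)),
        trait_accession = sprintf("%s:%04d", ontology, seq_along(ids)),
        method = methods, method_source_ref = "", method_accession = "",
        scale = scales, scale_source_ref = "", scale_accession = "",
        variable_class = classes, stringsAsFactors = FALSE))
}

.drawMatrix <- function(file, rowIds, ids, quantitative, means, sds,
                        categories = c("low", "medium", "high")) {
    n <- length(rowIds)
    cols <- lapply(seq_along(ids), function(j) {
        if (quantitative[j])
            .num(stats::rnorm(n, means[j], sds[j]))
        else
            sample(categories, n, replace = TRUE)
    })
    values <- do.call(cbind, cols)
    dimnames(values) <- list(rowIds, ids)
    DataMatrix(file, linkNode = "Assay Name", values = values)
}

.ontologySources <- function() {
    data.frame(
        name = c("CO", "TO", "NCBITaxon"),
        file = c("http://www.cropontology.org",
                 "http://purl.obolibrary.org/obo/to.owl",
                 "http://purl.obolibrary.org/obo/ncbitaxon.owl"),
        version = c("2016", "2016", "2016"),
        description = c("Crop Ontology", "Plant Trait Ontology",
                        "NCBI organismal taxonomy"),
        stringsAsFactors = FALSE)
}

## --- profiles --------------------------------------------------------------

.generateBasicGwas <- function(sources = 20, reps = 2, vars = 107) {
    if (sources < 1 || reps < 1 || vars < 1)
        stop("invalid parameters: sources, reps and vars must be positive")
    config <- builtinConfig("basic")
    src <- sprintf("Acc%03d", seq_len(sources))
    srcRep <- rep(src, each = reps)
    repIdx <- rep(seq_len(reps), times = sources)
    samples <- sprintf("%s_s1_r%d", srcRep, repIdx)
    study <- .studyTableFromPlan(config, "s_study1.txt", list(
        "Source Name" = srcRep,
        "Characteristics[Organism]" = "Arabidopsis thaliana",
        "Characteristics[Infraspecific name]" = srcRep,
        "Characteristics[Seed origin]" = "stock centre collection",
        "Characteristics[Study start]" = "2010-03-01",
        "Characteristics[Study duration]" = "60 days",
        "Characteristics[Growth facility]" = "growth chamber",
        "Characteristics[Geographic location]" = "Vienna, Austria",
        "Sample Name" = samples), length(samples))
    assayNames <- paste0(samples, "_a")
    assay <- .assayTable("a_study1.txt", samples, assayNames,
                         organ = "whole plant", tdfFile = "tdf.txt",
                         derivedFile = "d_data.txt")
    ids <- sprintf("V%03d", seq_len(vars))
    quantitative <- seq_len(vars) %% 10L != 0L  # every 10th is categorical
    tdf <- .syntheticTDF("tdf.txt", ids,
        traits = sprintf("synthetic trait %03d", seq_len(vars)),
        methods = ifelse(quantitative, "manual measurement",
                         "visual scoring"),
        scales = ifelse(quantitative, "cm", "ordinal category"),
        classes = rep("phenotypic", vars), ontology = "TO")
    means <- stats::runif(vars, 10, 100)
    matrix <- .drawMatrix("d_data.txt", assayNames, ids, quantitative,
                          means, 0.1 * means)
    matrix@values <- .applyMissing(matrix@values)
    inv <- Investigation(
        identifier = "SYNTH-BASIC-GWAS",
        title = "Synthetic replicated accession collection (basic schema)",
        description = paste("Synthetic dataset emulating a replicated",
                            "multi-accession phenotyping collection",
                            "exported from a GWAS platform."),
        submissionDate = "2016-01-01", publicReleaseDate = "2016-06-01",
        ontologySources = .ontologySources(),
        studies = list(StudyRecord(
            fileName = "s_study1.txt", identifier = "STUDY1",
            title = "Replicated accession collection",
            description = "Basic-schema study of synthetic accessions",
            assayFiles = "a_study1.txt",
            protocols = .protocolDF(config))))
    PhenoDataset(investigation = inv,
                 studies = list(s_study1.txt = study),
                 assays = list(a_study1.txt = assay),
                 traitDefinitions = list(tdf.txt = tdf),
                 dataFiles = list(d_data.txt = matrix))
}

.FIELD_TRAITS <- data.frame(
    id = c("PH", "HD", "SL", "GN", "TGW", "GY", "TN", "BM"),
    trait = c("plant height", "heading time", "spike length",
              "grain number per spike", "thousand grain weight",
              "grain yield per plot", "tiller number", "above-ground biomass"),
    method = c("ruler measurement", "days from sowing to heading",
               "ruler measurement", "manual count", "grain counter and scale",
               "plot harvest and scale", "manual count",
               "harvest and drying"),
    scale = c("cm", "days", "cm", "count", "g", "g", "count", "g"),
    mean = c(85, 62, 9, 24, 48, 310, 4, 520),
    sd = c(8, 5, 1.2, 4, 5, 40, 1, 60),
    stringsAsFactors = FALSE)

.FIELD_ENV <- data.frame(
    id = c("VPD", "TP"),
    trait = c("water vapour pressure deficit", "total precipitation"),
    method = c("weather station record, season mean",
               "weather station record, season total"),
    scale = c("kPa", "mm"),
    mean = c(0.85, 450), sd = c(0.1, 60),
    stringsAsFactors = FALSE)

.generateFieldMultiyear <- function(lines = 100, parents = 2, years = 2,
                                    reps = 2, phenoVars = 8, envVars = 2) {
    if (lines < 1 || parents < 0 || years < 1 || reps < 1 ||
        phenoVars < 1 || envVars < 0)
        stop("invalid parameters for field_multiyear")
    if (phenoVars > nrow(.FIELD_TRAITS) || envVars > nrow(.FIELD_ENV))
        stop("at most ", nrow(.FIELD_TRAITS), " phenotypic and ",
             nrow(.FIELD_ENV), " environmental variables are available")
    config <- builtinConfig("field")
    src <- c(sprintf("RIL%03d", seq_len(lines)),
             if (parents > 0) paste0("Parent", LETTERS[seq_len(parents)]))
    ph <- .FIELD_TRAITS[seq_len(phenoVars), ]
    ev <- .FIELD_ENV[seq_len(min(envVars, nrow(.FIELD_ENV))), ]
    tdf <- .syntheticTDF("tdf_field.txt", c(ph$id, ev$id),
                         traits = c(ph$trait, ev$trait),
                         methods = c(ph$method, ev$method),
                         scales = c(ph$scale, ev$scale),
                         classes = c(rep("phenotypic", nrow(ph)),
                                     rep("environmental", nrow(ev))))
    studies <- list(); assays <- list(); matrices <- list()
    records <- list()
    for (y in seq_len(years)) {
        year <- 2011 + y
        sfile <- sprintf("s_study%d.txt", y)
        afile <- sprintf("a_study%d_phenotyping_field%d.txt", y, year)
        dfile <- sprintf("d_field%d.txt", year)
        srcRep <- rep(src, each = reps)
        repIdx <- rep(seq_len(reps), times = length(src))
        samples <- sprintf("%s_s%d_r%d", srcRep, y, repIdx)
        dayT <- .num(stats::rnorm(1, 22, 2), 1)
        nightT <- .num(stats::rnorm(1, 12, 2), 1)
        study <- .studyTableFromPlan(config, sfile, list(
            "Source Name" = srcRep,
            "Characteristics[Organism]" = "Hordeum vulgare",
            "Characteristics[Infraspecific name]" = srcRep,
            "Characteristics[Seed origin]" = "institute genebank",
            "Characteristics[Study start]" = sprintf("%d-05-10", year),
            "Characteristics[Study duration]" = "110 days",
            "Characteristics[Growth facility]" = "experimental field",
            "Characteristics[Geographic location]" = "Poznan, Poland",
            "Protocol REF#1" = "Rooting",
            "Parameter Value[Rooting medium]" = "soil: loam",
            "Parameter Value[Plot size]" = "2.5",
            "Unit" = "m2",
            "Parameter Value[Sowing density]" = "300 seeds/m2",
            "Parameter Value[pH]" = "6.5",
            "Protocol REF#2" = "Aerial conditions",
            "Parameter Value[Air humidity]" = "70%",
            "Parameter Value[Daily photon flux]" = "35 mol/m2/day",
            "Parameter Value[Length of light period]" = "15 h",
            "Parameter Value[Day temperature]" = dayT,
            "Parameter Value[Night temperature]" = nightT,
            "Protocol REF#3" = "Nutrition",
            "Parameter Value[N before fertilisation]" = "45 kg/ha",
            "Parameter Value[Type of fertiliser]" = "NPK 6-20-30",
            "Parameter Value[Amount of fertiliser]" = "250 kg/ha",
            "Protocol REF#4" = "Watering",
            "Parameter Value[Irrigation type]" = "rainfed",
            "Parameter Value[Volume]" = "natural precipitation",
            "Parameter Value[Frequency]" = "continuous",
            "Protocol REF#5" = "Sampling",
            "Parameter Value[Experimental unit]" = "plot",
            "Sample Name" = samples), length(samples))
        assayNames <- paste0(samples, "_a")
        assay <- .assayTable(afile, samples, assayNames,
                             organ = "whole plant",
                             tdfFile = "tdf_field.txt",
                             derivedFile = dfile)
        matrix <- .drawMatrix(dfile, assayNames, ph$id,
                              rep(TRUE, nrow(ph)), ph$mean, ph$sd)
        ## environmental variables: one season value, constant per study
        if (nrow(ev)) {
            envVals <- .num(stats::rnorm(nrow(ev), ev$mean, ev$sd))
            envBlock <- matrix@values[, 0]
            for (j in seq_len(nrow(ev)))
                envBlock <- cbind(envBlock,
                                  rep(envVals[j], length(assayNames)))
            colnames(envBlock) <- ev$id
            vals <- cbind(.applyMissing(matrix@values), envBlock)
            rownames(vals) <- assayNames
            matrix <- DataMatrix(dfile, linkNode = "Assay Name",
                                 values = vals)
        } else {
            matrix@values <- .applyMissing(matrix@values)
        }
        studies[[sfile]] <- study
        assays[[afile]] <- assay
        matrices[[dfile]] <- matrix
        records[[y]] <- StudyRecord(
            fileName = sfile, identifier = sprintf("STUDY%d", y),
            title = sprintf("Field trial %d", year),
            description = sprintf(
                "Synthetic field trial of a RIL population, season %d",
                year),
            submissionDate = sprintf("%d-01-15", year + 1),
            publicReleaseDate = sprintf("%d-06-01", year + 1),
            assayFiles = afile,
            protocols = .protocolDF(config))
    }
    inv <- Investigation(
        identifier = "SYNTH-FIELD-RIL",
        title = "Synthetic multi-year field trial of a RIL population",
        description = paste("Synthetic dataset emulating a two-season field",
                            "experiment on recombinant inbred lines and",
                            "their parents, with environment protocols and",
                            "seasonal environmental variables."),
        submissionDate = "2014-01-15", publicReleaseDate = "2014-06-01",
        ontologySources = .ontologySources(),
        studies = records)
    PhenoDataset(investigation = inv, studies = studies, assays = assays,
                 traitDefinitions = list(tdf_field.txt = tdf),
                 dataFiles = matrices)
}

.GREENHOUSE_FEATURES <- data.frame(
    id = c("PLA", "PHT", "CMP", "DBM"),
    trait = c("projected leaf area", "plant height",
              "plant compactness", "digital biomass"),
    method = c("top-view image segmentation", "side-view image analysis",
               "image-derived area ratio", "voxel volume estimate"),
    scale = c("px", "mm", "ratio", "px3"),
    mean = c(5200, 48, 0.62, 80000),
    sd = c(900, 7, 0.08, 15000),
    stringsAsFactors = FALSE)

.generateGreenhouseHts <- function(plants = 484, vars = 4) {
    if (plants < 1 || vars < 1)
        stop("invalid parameters: plants and vars must be positive")
    if (vars > nrow(.GREENHOUSE_FEATURES))
        stop("at most ", nrow(.GREENHOUSE_FEATURES),
             " image-derived features are available")
    base <- builtinConfig("greenhouse")
    config <- extendConfig(base, list(
        list(header = "Factor Value[Plant movement]"),
        list(header = "Factor Value[Soil cover]"),
        list(header = "Comment[Data provenance]", required = FALSE)),
        name = "greenhouse_hts")
    src <- sprintf("Plant%03d", seq_len(plants))
    ## balanced 2x2 factorial assignment by cycling the four combinations
    moveLevels <- c("rotating", "stationary")
    coverLevels <- c("covered", "uncovered")
    combo <- expand.grid(move = moveLevels, cover = coverLevels,
                         stringsAsFactors = FALSE)
    pick <- ((seq_len(plants) - 1L) %% 4L) + 1L
    samples <- sprintf("%s_s1_r1", src)
    study <- .studyTableFromPlan(config, "s_study1.txt", list(
        "Source Name" = src,
        "Characteristics[Organism]" = "Arabidopsis thaliana",
        "Characteristics[Infraspecific name]" = "Col-0",
        "Characteristics[Seed origin]" = "stock centre collection",
        "Characteristics[Study start]" = "2014-02-01",
        "Characteristics[Study duration]" = "35 days",
        "Characteristics[Growth facility]" = "greenhouse",
        "Characteristics[Geographic location]" = "Gatersleben, Germany",
        "Protocol REF#1" = "Rooting",
        "Parameter Value[Rooting medium]" = "soil: peat substrate",
        "Parameter Value[Container type]" = "pot",
        "Parameter Value[Container volume]" = "0.5 L",
        "Parameter Value[Container dimension]" = "10",
        "Unit" = "cm",
        "Parameter Value[Number of plants per container]" = "1",
        "Parameter Value[pH]" = "6.0",
        "Protocol REF#2" = "Aerial conditions",
        "Parameter Value[Air humidity]" = "60%",
        "Parameter Value[Daily photon flux]" = "20 mol/m2/day",
        "Parameter Value[Length of light period]" = "16 h",
        "Parameter Value[Day temperature]" = "21",
        "Parameter Value[Night temperature]" = "18",
        "Protocol REF#3" = "Nutrition",
        "Parameter Value[N before fertilisation]" = "20 mg/L",
        "Parameter Value[Type of fertiliser]" = "complete nutrient solution",
        "Parameter Value[Amount of fertiliser]" = "100 ml/week",
        "Protocol REF#4" = "Watering",
        "Parameter Value[Irrigation type]" = "drip irrigation",
        "Parameter Value[Volume]" = "50 ml",
        "Parameter Value[Frequency]" = "daily",
        "Protocol REF#5" = "Sampling",
        "Parameter Value[Experimental unit]" = "pot",
        "Factor Value[Plant movement]" = combo$move[pick],
        "Factor Value[Soil cover]" = combo$cover[pick],
        "Comment[Data provenance]" = "synthetic constant",
        "Sample Name" = samples), plants)
    assayNames <- paste0(samples, "_a")
    rawFiles <- sprintf("images/%s_vis_top.png", samples)
    assay <- .assayTable("a_study1_imaging.txt", samples, assayNames,
                         organ = "rosette", tdfFile = "tdf_greenhouse.txt",
                         derivedFile = "d_greenhouse.txt",
                         rawFiles = rawFiles)
    feat <- .GREENHOUSE_FEATURES[seq_len(vars), ]
    tdf <- .syntheticTDF("tdf_greenhouse.txt", feat$id, feat$trait,
                         feat$method, feat$scale,
                         rep("phenotypic", nrow(feat)))
    matrix <- .drawMatrix("d_greenhouse.txt", assayNames, feat$id,
                          rep(TRUE, nrow(feat)), feat$mean, feat$sd)
    matrix@values <- .applyMissing(matrix@values)
    inv <- Investigation(
        identifier = "SYNTH-GREENHOUSE-HTS",
        title = "Synthetic high-throughput greenhouse imaging experiment",
        description = paste("Synthetic dataset emulating an automated",
                            "imaging experiment with a balanced 2x2",
                            "factorial design (plant movement x soil",
                            "cover); raw image files are referenced but",
                            "kept external."),
        submissionDate = "2015-01-15", publicReleaseDate = "2015-06-01",
        ontologySources = .ontologySources(),
        studies = list(StudyRecord(
            fileName = "s_study1.txt", identifier = "STUDY1",
            title = "Greenhouse imaging validation trial",
            description = "2x2 factorial imaging study of rosette growth",
            factors = data.frame(
                name = c("Plant movement", "Soil cover"),
                type = c("treatment", "treatment"),
                stringsAsFactors = FALSE),
            assayFiles = "a_study1_imaging.txt",
            protocols = .protocolDF(base))))
    PhenoDataset(investigation = inv,
                 studies = list(s_study1.txt = study),
                 assays = list(a_study1_imaging.txt = assay),
                 traitDefinitions = list(tdf_greenhouse.txt = tdf),
                 dataFiles = list(d_greenhouse.txt = matrix),
                 externalFiles = sort(rawFiles))
}

#' Generate a synthetic MIAPPE-compliant dataset
#'
#' Deterministically builds (and optionally writes) a complete synthetic
#' dataset under one of three profiles: `basic_gwas` (a replicated
#' accession collection under the Basic schema, 107 variables by default),
#' `field_multiyear` (a recombinant-inbred-line population of 100 lines
#' plus 2 parents observed over two field seasons, 8 phenotypic and 2
#' environmental variables by default) and `greenhouse_hts` (a balanced
#' 2x2 factorial imaging experiment of 484 plants under the Greenhouse
#' schema with external raw image references). Quantitative observations
#' are drawn from per-variable normal distributions, categorical ones
#' uniformly from a small category set, seasonal environmental values are
#' constant within a study, and 2% of phenotypic matrix cells are set
#' missing. Every generated dataset validates with zero errors under its
#' profile's configuration.
#'
#' @param profile one of "basic_gwas", "field_multiyear",
#'   "greenhouse_hts".
#' @param seed integer seed for the dataset's random stream.
#' @param outDir if non-`NULL`, the dataset is also written there.
#' @param ... profile parameters: `sources`, `reps`, `vars`
#'   (basic_gwas); `lines`, `parents`, `years`, `reps`, `phenoVars`,
#'   `envVars` (field_multiyear); `plants`, `vars` (greenhouse_hts).
#' @return a [PhenoDataset-class].
#' @examples
#' d <- generateDataset("basic_gwas", seed = 7, sources = 5, reps = 2,
#'                      vars = 3)
#' summarizeDataset(d)$samples
#' @export
generateDataset <- function(profile = c("basic_gwas", "field_multiyear",
                                        "greenhouse_hts"),
                            seed = 1L, outDir = NULL, ...) {
    profile <- match.arg(profile)
    dataset <- .withSeed(seed, switch(profile,
        basic_gwas = .generateBasicGwas(...),
        field_multiyear = .generateFieldMultiyear(...),
        greenhouse_hts = .generateGreenhouseHts(...)))
    if (!is.null(outDir))
        writeDataset(dataset, outDir)
    dataset
}

#' @describeIn generateDataset the configuration kind a profile's datasets
#'   validate under.
#' @export
profileConfigKind <- function(profile) {
    switch(profile,
        basic_gwas = "basic",
        field_multiyear = "field",
        greenhouse_hts = "greenhouse",
        stop("unknown profile: '", profile, "'"))
}

## --- scaffolding -----------------------------------------------------------

#' Scaffold an empty dataset template
#'
#' Writes an empty-but-complete template for a configuration: the
#' investigation file with the schema's protocols declared, a study file
#' and a phenotyping assay file containing exactly the planned headers and
#' no rows, and a header-only Trait Definition File. The template
#' validates with zero errors and zero warnings and has zero-present
#' compliance.
#'
#' @param config "basic", "field", "greenhouse" or a [StudyConfig-class].
#' @param dir target directory; must be absent or empty.
#' @return invisibly, the scaffolded [PhenoDataset-class].
#' @export
scaffoldDataset <- function(config, dir) {
    if (is.character(config))
        config <- builtinConfig(config)
    if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                             no.. = TRUE)))
        stop("target directory is not empty: ", dir)
    assayConfig <- phenotypingAssayConfig()
    study <- StudyTable("s_study1.txt", parseHeaders(planHeaders(config)))
    assay <- AssayTable("a_study1_phenotyping.txt",
                        parseHeaders(planHeaders(assayConfig)))
    tdf <- TraitDefinitions("tdf.txt", data.frame(
        variable_id = character(0), stringsAsFactors = FALSE))
    inv <- Investigation(
        ontologySources = .ontologySources(),
        studies = list(StudyRecord(
            fileName = "s_study1.txt",
            assayFiles = "a_study1_phenotyping.txt",
            protocols = .protocolDF(config))))
    dataset <- PhenoDataset(investigation = inv,
                            studies = list(s_study1.txt = study),
                            assays = list(a_study1_phenotyping.txt = assay),
                            traitDefinitions = list(tdf.txt = tdf))
    writeDataset(dataset, dir)
    invisible(dataset)
}

## --- defect injection ------------------------------------------------------

.DEFECT_CODES <- c("MISSING_COLUMN", "EMPTY_ESSENTIAL_CELL",
                   "UNDECLARED_PROTOCOL", "BROKEN_SAMPLE_LINK",
                   "UNKNOWN_VARIABLE_ID", "ORPHAN_DATA_ROW",
                   "DUPLICATE_HEADER", "RAGGED_ROW", "MISSING_FILE")

.dropTableColumn <- function(table, header) {
    at <- match(header, headerTexts(table@headers))
    stopifnot(!is.na(at))
    initialize(table, headers = table@headers[-at],
               rows = table@rows[, -at, drop = FALSE])
}

.duplicateTableColumn <- function(table, header) {
    at <- match(header, headerTexts(table@headers))
    stopifnot(!is.na(at))
    n <- length(table@headers)
    ord <- append(seq_len(n), at, after = at)
    initialize(table, headers = table@headers[ord],
               rows = table@rows[, ord, drop = FALSE])
}

#' Inject a single documented defect into a clean dataset
#'
#' Mutation-testing support: applies one minimal edit guaranteed to trigger
#' exactly the given issue code's class when the mutated dataset is
#' validated. One defect exists per documented code. `RAGGED_ROW` is a
#' file-level defect (the in-memory model is rectangular by construction):
#' it requires `dir`, writes the dataset there, truncates one data row on
#' disk and returns the directory; re-reading it surfaces the issue. All
#' other codes mutate and return the in-memory dataset.
#'
#' @param dataset a clean [PhenoDataset-class] (e.g. from
#'   [generateDataset()]).
#' @param code one of the documented issue codes.
#' @param dir directory for the `RAGGED_ROW` defect.
#' @return the mutated dataset, or the directory path for `RAGGED_ROW`.
#' @export
injectDefect <- function(dataset, code, dir = NULL) {
    stopifnot(is(dataset, "PhenoDataset"))
    if (!code %in% .DEFECT_CODES)
        stop("unknown defect code: '", code, "'")
    sname <- names(dataset@studies)[1L]
    study <- dataset@studies[[sname]]
    switch(code,
        MISSING_COLUMN = {
            dataset@studies[[sname]] <-
                .dropTableColumn(study, "Characteristics[Seed origin]")
            dataset
        },
        DUPLICATE_HEADER = {
            dataset@studies[[sname]] <-
                .duplicateTableColumn(study, "Characteristics[Organism]")
            dataset
        },
        EMPTY_ESSENTIAL_CELL = {
            at <- match("Characteristics[Organism]",
                        headerTexts(study@headers))
            study@rows[1L, at] <- ""
            dataset@studies[[sname]] <- study
            dataset
        },
        UNDECLARED_PROTOCOL = {
            st <- dataset@investigation@studies[[1L]]
            keep <- st@protocols$name != "Sampling"
            if (all(keep))
                stop("fixture has no Sampling protocol to undeclare")
            st@protocols <- st@protocols[keep, , drop = FALSE]
            dataset@investigation@studies[[1L]] <- st
            dataset
        },
        BROKEN_SAMPLE_LINK = {
            aname <- names(dataset@assays)[1L]
            assay <- dataset@assays[[aname]]
            at <- .nodeColumn(assay, "Sample Name")
            assay@rows[1L, at] <- "P999_unused"
            dataset@assays[[aname]] <- assay
            dataset
        },
        UNKNOWN_VARIABLE_ID = {
            mname <- names(dataset@dataFiles)[1L]
            m <- dataset@dataFiles[[mname]]
            colnames(m@values)[1L] <- "XYZ_undefined"
            dataset@dataFiles[[mname]] <- m
            dataset
        },
        ORPHAN_DATA_ROW = {
            mname <- names(dataset@dataFiles)[1L]
            m <- dataset@dataFiles[[mname]]
            rownames(m@values)[1L] <- "orphan_row_1"
            dataset@dataFiles[[mname]] <- m
            dataset
        },
        MISSING_FILE = {
            stopifnot(length(dataset@traitDefinitions) > 0L)
            dataset@traitDefinitions <- dataset@traitDefinitions[-1L]
            dataset
        },
        RAGGED_ROW = {
            if (is.null(dir))
                stop("the RAGGED_ROW defect operates on files; supply 'dir'")
            writeDataset(dataset, dir)
            ## truncate an assay row: its last column (Derived Data File)
            ## is referenced from every other row, so only the ragged-row
            ## error itself (plus cell-level warnings) can surface
            path <- file.path(dir, names(dataset@assays)[1L])
            lines <- readLines(path)
            lines[2L] <- sub("\t[^\t]*$", "", lines[2L])
            .writeTextLines(lines, path)
            dir
        })
}
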