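---
title: "phenotab: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenotab: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotab)
```

## What the package models

MIAPPE (Minimum Information About a Plant Phenotyping Experiment) is a
checklist of attributes — organised in eight sections from general metadata
through biosource and environment to observed variables — that a plant
phenotyping dataset should carry to be interpretable and reusable. A subset
of attributes is marked *essential*; the rest form an extended description.
The ISA-Tab Phenotyping Configuration turns the checklist into concrete file
schemas: a Basic Study schema for minimal descriptions, Field and Greenhouse
Study schemas that add environment protocol blocks (Rooting, Aerial
conditions, Nutrition, Watering, Sampling), and a common Phenotyping Assay
schema that links each assay to a Trait Definition File (TDF) and a derived
observation matrix.

phenotab makes those artefacts executable. Its central objects are S4
classes: `FieldHeader` (the column-header grammar), `StudyTable` /
`AssayTable` (header sequence + rectangular rows), `Investigation`,
`TraitDefinitions`, `DataMatrix`, the containing `PhenoDataset`, the schema
classes `StudyConfig` / `AssayConfig`, and the report classes
`ValidationReport` / `ComplianceReport`. Validity methods enforce the
format's structural invariants at construction time: tables are rectangular,
a Study table runs from `Source Name` to `Sample Name`, qualifier columns
(`Unit`, `Term Source REF`, `Term Accession Number`) directly follow a
column they can qualify, and an accession is never recorded without its term
source.

## The header grammar

Headers are matched case-sensitively and exactly after trimming outer
whitespace, against a closed vocabulary; unknown categories are errors
rather than pass-throughs, so dialect drift fails fast. Bracket qualifiers
are taken verbatim (inner whitespace preserved). One deliberate
normalisation: the configuration documentation writes protocol columns as
`Protocol REF[Rooting]`, while conformant files carry a plain
`Protocol REF` column whose *cell value* names the protocol. The parser
accepts the bracketed shorthand and normalises it to a `Protocol REF`
column with an expected cell value, so emitted files are always
spec-conformant while schema transcriptions remain readable.

## Schemas and additive extension

`builtinConfig()` returns the three Study schemas; the package treats the
Basic plan's seven characteristics and the Field/Greenhouse protocol
parameter lists as fixed reference data (a transcription ships in
`inst/extdata/phenotyping_study_schemas.tsv` and the acceptance tests
compare the registry against it header by header). Extension via
`extendConfig()` is additive only: additions may introduce Characteristics,
Factor Values, Comments, parameters or whole protocol blocks, but any
request that renames, removes or duplicates an inherited column is refused.
This mirrors the configuration's own extension rule — local configurations
must keep every inherited field so that datasets remain comparable across
sites.

Treatments are deliberately absent from all built-in plans: they are
specific per experiment, entering through extension either as a
`Factor Value` or as a protocol with parameters. The package exposes both
routes and does not prefer one, since the mapping gives no rule for the
choice. Similarly, the Basic schema *omits* protocol blocks but does not
forbid them: user-added blocks under Basic are accepted.

## Validation semantics

Findings are coded and located (file; 1-based row counting the header row
as row 1; column by canonical header text with an occurrence suffix for
legitimately repeated headers). Two severity decisions shape the model:

* **Absent required columns are errors; empty required cells are only
  warnings.** Published phenotyping archives legitimately ship with empty
  required columns when information was unavailable; a schema-conformant
  skeleton with gaps is structurally valid but incomplete. The CLI's
  `--strict` flag promotes these warnings to errors for repositories that
  want to insist on completeness.
* **Missing referenced files depend on their role.** Raw data files
  routinely live outside the metadata archive (terabytes of images), so an
  absent `Raw Data File` reference is flagged external (info). Trait
  Definition Files and Derived Data Files are the dataset's substance, so an
  absent one is a `MISSING_FILE` error.

Protocol blocks in a table are located structurally (each `Protocol REF`
column opens a block running to the next one) and matched to planned blocks
by their modal non-empty cell value; in a template with no rows yet, blocks
match positionally. Duplicate property columns are errors, scoped to the
table for Characteristics/Factor Value/Comment qualifiers and to the
protocol block for Parameter Values (the same parameter name may
legitimately recur in different blocks). Repeating qualifiers within one
table is rejected — the format is silent on duplicates, and accepting them
would make cell addressing ambiguous.

## Compliance scoring

`miappeCompliance()` evaluates the applicable essential attributes for a
configuration kind (`miappeEssentials()` is the registry). An attribute is
*present* when its mapped location exists with at least one non-empty value
— presence speaks to the attribute being provided at all, not to cell-level
completeness, which the validator's warnings already cover. The score is
the unweighted fraction of applicable attributes present, reported per
section and overall; no section weighting is applied because the checklist
defines none.

Two applicability subtleties: the environment protocols and the Sampling
protocol apply only under Field/Greenhouse; and environmental variable
definitions are treated as essential only when a TDF actually declares an
environmental variable (the checklist stars their Trait/Method/Scale while
the configuration mapping marks them experiment-specific — scoring a
dataset down for not defining variables it never measured would conflate
the two). Under this rule, blanking cells in study and assay tables can
never raise the score, and the tests verify that monotonicity on the
metadata tables; reclassifying a TDF variable can change the applicable
set itself, which is outside the monotone surface.

## The TDF variable-class column

MIAPPE distinguishes phenotypic from environmental variables, but the TDF
format has no class column. phenotab carries the class in an optional
`Comment[Variable class]` column — Comment columns being the format's
sanctioned extension point — defaulting to "unspecified" when absent.
Unspecified variables count toward phenotypic presence in compliance
scoring. Missing values in matrices are the empty cell or the literal
`NA`; values are kept as text (observations may be qualitative), with
numeric interpretation left to consumers.

Environmental measurements repeated over time can be encoded three ways
(time-suffixed variable ids, a Time factor, or a separate assay); the
generator emits the first, and the reader is agnostic — any column defined
in the TDF links. Seasonal environmental values are stored repeated per
matrix row (constant within a study), following common practice rather
than a format rule.

## The synthetic generator

`generateDataset()` emulates three canonical dataset shapes, and its
defaults are the study conditions of the published examples the package is
tested against:

* `field_multiyear`: 100 recombinant inbred lines + 2 parents = **102
  biosources**, **2** seasons (2012/2013) as separate studies
  distinguishable by `Characteristics[Study start]`, **8 phenotypic + 2
  environmental** variables in one shared TDF, matrices keyed by
  `Assay Name`.
* `basic_gwas`: a replicated accession collection under the Basic schema
  with **107** variables (every 10th categorical); sources = 20 and
  replicates = 2 are not printed anywhere and were chosen once as a
  realistic collection size.
* `greenhouse_hts`: **484** plants in a balanced 2x2 factorial
  (rotating/stationary x covered/uncovered) under the Greenhouse schema,
  with external raw-image references and 4 image-derived features (a
  typical biomass-proxy panel; the published count is not stated).

Quantitative traits are drawn from per-variable normal distributions with
field-plausible means (e.g. plant height 85 +/- 8 cm), categorical traits
uniformly from a small ordinal set, and 2% of phenotypic matrix cells are
set missing — enough to exercise missing-value handling without dominating
small fixtures. Environment protocol parameter values are fixed plausible
constants (pH 6.0 and the like), marked as synthetic where a Comment column
exists; they are arbitrary by design and never asserted as biological
truth. All draws flow from one Mersenne-Twister stream seeded per dataset
(the caller's random state is saved and restored), giving byte-identical
output trees for identical inputs.

What the generator does **not** emulate: genetic structure or
genotype-by-environment effects, realistic trait correlations, time-series
imaging, or ontology-correct accession numbers (annotations are
syntactically valid placeholders). Passing tests therefore demonstrate
format, linkage and scoring behaviour — not statistical realism of the
values.

`injectDefect()` provides the validator's mutation catalogue: one minimal
edit per documented issue code. `RAGGED_ROW` is the one file-level defect
(the in-memory model is rectangular by construction), implemented by
truncating one assay row in a written copy.

## Numerical and serialisation choices

Files are UTF-8 without BOM, `\n`-terminated, tabs as separators; `\r\n`
is accepted on read. Cells are quoted on write only when they contain a
double quote (doubled inside); tabs and newlines inside cells are rejected
outright. Trailing empty rows/columns are stripped on read with an info
entry. Ragged data rows are padded to the header width so that reading can
continue, and reported as located errors. Serialisation order is the
object order, making writes deterministic; `datasetEqual()` defines
structural equality over header sequences, cell values and investigation
records while ignoring the root directory and read-time issue tables.

The declarative configuration file format (one header per line with
required/expected/unit flags, `protocol` lines opening blocks) replaces the
official XML configuration dialect, which is out of scope; it is
human-diffable and round-trips exactly.

## Problem sizes in the test suite

The unit tests run reduced fixtures (4–6 sources, 2 seasons, 8–16 plants)
chosen so each property is still fully exercised — e.g. 2% missingness
rounds to zero cells in the smallest matrices, so conservation tests use
fixtures on both sides of that line. The acceptance tests run the full
default sizes (102 biosources across two seasons; 107 variables) and 20
seeds x 3 profiles for round-trip fidelity.

## Known limitations

* Ontology annotations are carried and round-tripped but never resolved
  against term services; accession syntax is not checked.
* Only the default derived-data dialect (tab-separated matrix keyed by a
  data node) is parsed; a matrix described as having a custom format in its
  Data transformation protocol is treated as opaque.
* Scientific plausibility (units, value ranges) is out of scope for the
  validator; it checks structure, linkage and presence.
* The Investigation parser implements the standard section vocabulary with
  one value column per record; exotic multi-study-per-block layouts are
  not supported.
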