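# phenotab

Executable metadata standards for plant phenotyping: **phenotab** implements
the MIAPPE checklist (Minimum Information About a Plant Phenotyping
Experiment) and the ISA-Tab Phenotyping Configuration as working code. It
reads, writes, scaffolds, validates and summarises ISA-Tab
(Investigation–Study–Assay) archives of phenotyping experiments, links trait
definitions to observation matrices, aggregates observations across studies,
and generates deterministic synthetic MIAPPE-compliant datasets so that
pipelines can be tested without real data.

It is written for data managers and developers in plant phenomics who curate
or produce ISA-Tab phenotyping archives — the people who would otherwise
check the checklist by hand.

## The model

An ISA-Tab dataset is a directory of tab-delimited text files: one
**Investigation** file (`i_*.txt`, sectioned key–value metadata), one or more
**Study** files (`s_*.txt`) and **Assay** files (`a_*.txt`). Study and Assay
files are column-structured tables whose headers follow a closed grammar:
*data nodes* (`Source Name`, `Sample Name`, `Assay Name`, …) trace material
through the experiment, described by `Characteristics[...]`,
`Factor Value[...]`, `Protocol REF` columns with `Parameter Value[...]`,
`Comment[...]`, optional `Unit` columns and ontology annotation pairs
(`Term Source REF` / `Term Accession Number`).

The **Phenotyping Configuration** fixes three Study schemas — *Basic* (seven
core characteristics from `Organism` to `Geographic location`), and *Field* /
*Greenhouse*, which extend Basic with the environment protocol blocks
`Rooting`, `Aerial conditions`, `Nutrition`, `Watering` and `Sampling` — plus
one *Phenotyping Assay* schema whose `Data transformation` protocol carries a
`Trait Definition File` parameter. A **Trait Definition File** defines each
observed variable by `Variable ID`, `Trait`, `Method` and `Scale`; a
**Derived Data File** is a plain tab-separated sample-by-variable matrix
keyed by `Assay Name` (or another data node) whose column names are Variable
IDs. Schemas are extensible *additively only*: derived configurations may add
columns but never rename or remove inherited ones.

The validator reports coded, located issues (`MISSING_COLUMN`,
`BROKEN_SAMPLE_LINK`, `UNKNOWN_VARIABLE_ID`, …; empty required cells are
warnings, absent required columns are errors) and a **compliance report**:
for each MIAPPE checklist section, which essential attributes applicable
under the configuration are present (at least one non-empty value at their
mapped ISA-Tab location), with the overall score the unweighted fraction
present.

## Worked example

```r
library(phenotab)

# a synthetic two-season field trial of a barley RIL population
d <- generateDataset("field_multiyear", seed = 42)
summarizeDataset(d)[c("studies", "sourcesPerStudy", "variables")]
#> $studies
#> [1] 2
#> $sourcesPerStudy
#> s_study1.txt s_study2.txt
#>          102          102
#> $variables
#> [1] 10

rep <- validateDataset(d, "field")
rep$validation
#> ValidationReport: 0 error(s), 0 warning(s), 0 info
rep$compliance
#> ComplianceReport (field configuration): score 1.000
#>   General metadata                           3/3
#>   Timing and location                        3/3
#>   Biosource                                  3/3
#>   Environment                                5/5
#>   Experimental design                        1/1
#>   Sample collection, processing, management  1/1
#>   Observed variables                         3/3

# break the sample chain and watch the validator catch it
bad <- injectDefect(d, "BROKEN_SAMPLE_LINK")
issues(validateDataset(bad, "field")$validation)[, c("code", "file", "row")]
#>                 code                                  file row
#> 1 BROKEN_SAMPLE_LINK a_study1_phenotyping_field2012.txt   2

# aggregate observations across the two seasons
agg <- aggregateObservations(d, by = "Study start")
table(agg$records$`Study start`)
#> 2012-05-10 2013-05-10
#>       2007       2007
```

The two studies hold 102 distinct biosources each (100 recombinant inbred
lines plus two parents), described by 8 phenotypic and 2 environmental
variables; validation is clean and every applicable essential attribute is
present. Each season yields 2007 long records rather than the full
204 samples x 10 variables = 2040 because about 2% of phenotypic cells are
generated missing.

A command-line wrapper is installed at
`system.file("scripts", "phenotab", package = "phenotab")` with the commands
`validate`, `scaffold`, `simulate`, `summarize` and `aggregate` (exit status
0 = valid, 1 = validation errors, 2 = usage/IO failure).

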