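Package: stemwall
Title: Developmental-Context Classification of Cell-Wall Gene Families from
    Stem Internode RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies members of cell-wall-related gene families of a grass
    stem into primary-wall (elongation), transitional, and secondary-wall
    expression contexts from internode RNA-seq read counts; assigns genes to
    family subgroups via bootstrapped neighbor-joining trees polarized by
    cross-species anchor genes; and calls putative orthologs by shared
    developmental context rather than sequence similarity alone. Includes a
    synthetic-data generator producing aligned gene families with known clade
    structure, duplicated paralog pairs sharing ambiguously mapped reads, and
    internode count profiles with known expression class, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
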