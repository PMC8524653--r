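Package: dnaforge
Title: Multi-Objective Design of Synthesizable DNA Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Redesigns annotated DNA constructs for manufacturability by
    jointly recoding coding sequences (GC content, codon usage) and
    partitioning the construct into synthesizable blocks. A multi-objective
    evolutionary optimizer with domination-count ranking, crowding-distance
    selection and a bounded non-dominated archive returns a set of
    Pareto-optimal trade-off designs. Includes analytic and heuristic
    objective bounds, hypervolume-based quality metrics, a synthetic
    benchmark generator for transcription-unit constructs, GenBank and YAML
    interfaces, and Gibson-assembly fragment export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
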