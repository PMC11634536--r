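Package: varcat
Title: Annotation-Driven Harmonization of Heterogeneous Variant Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unifies somatic small-variant tables stored across cohorts in
    mixed formats (CSV, TSV, MAF, VCF, optionally gzip-compressed) into one
    customizable tabular output. Parsing is governed by declarative YAML
    annotation files that describe which files to read, which output columns
    to produce, and how each column's value is obtained: literals, input
    columns matched through header aliases, regex captures from file or
    directory names, two-column mapping tables, or per-record plugins.
    Provides streaming find/cat/group-by/count tasks with a deterministic
    parallel execution contract, a plugin scaffold generator with a built-in
    alteration-type classifier (SNV, MNV, insertion, deletion), a
    deterministic multi-format fixture generator with a ground-truth
    manifest, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
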