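---
title: "Harmonizing heterogeneous variant cohorts with declarative annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous variant cohorts with declarative annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcat)
```

## The problem

Somatic small-variant calls accumulate across projects in incompatible
shapes. One cohort ships a MAF with `Chromosome` / `Start_Position` /
`Reference_Allele` headers and `-` placeholders for indels; another ships a
VCF with `##` metadata, a `#CHROM` header and anchored indel alleles; a
third exports ad-hoc CSV or TSV tables, sometimes gzipped. Integrative
analyses additionally need metadata that lives *outside* the files — which
dataset a row came from, which directory, which file — injected as ordinary
columns so that downstream tools can group and filter on them.

varcat treats this as a declarative parsing problem. The user writes an
*annotation file* per cohort: a YAML document stating which files to read,
which output columns to produce, and how each column's value is obtained.
The engine applies those rules row by row and emits one uniform table,
whatever the input dialects were. Nothing about the transformation is
hard-coded; changing the output means editing a YAML document, not code.

## The annotation model

An annotation has file-selection properties (`pattern`, a list of file-name
globs; `recursive`; `format` for the output, TSV or CSV) and a `columns`
list fixing the ordered output shape. Every output column obtains its value
in exactly one of seven ways — six explicit field kinds plus pass-through:

| kind          | value source                                              |
|---------------|-----------------------------------------------------------|
| `static`      | a literal, constant per annotation (e.g. the dataset name)|
| `internal`    | first input column present among an alias list            |
| `filename`    | one regex capture group applied to the file name          |
| `dirname`     | the same, applied to the immediate parent directory name  |
| `mapping`     | an aliased input value translated via a two-column table  |
| `plugin`      | a registered per-record function of the parsing context   |
| *pass-through*| the input column with the same name as the output column  |

Header matching (for `internal` aliases and pass-through) is
case-insensitive after trimming, because MAF dialects disagree on casing.
When several aliases are present in one header, the first alias in schema
order wins — deterministic and user-controllable. A field that cannot be
resolved yields the schema's `missing_value` sentinel (default: the empty
string) unless it is marked `required`, in which case the file aborts with
an error naming the field, the file and the row. `required` defaults to
false because heterogeneous cohorts routinely lack columns; totality of
parsing is worth more than early failure for optional metadata.

Rows can be dropped declaratively (`exclude_rows`: exact string equality on
a named field, e.g. `FILTER == LowQual`). Column exclusion is structural:
the output contains exactly `columns`, so input columns not listed never
appear; `exclude_columns` documents input headers that must not leak
through and is validated not to overlap `columns`. We considered the
alternative reading — output = columns ∪ (input header − excluded) — and
rejected it because it breaks the engine's central guarantee that every
record under one schema has an identical ordered key set regardless of
which input file produced it.

### Resolution order and the context object

Fields are resolved in schema column order, and each plugin receives the
record in progress read-only with only *earlier* columns populated. This
makes evaluation order well-defined, lets plugins build on resolved fields
(the built-in classifier prefers the already-unified `REF`/`ALT` over raw
header lookups), and keeps per-file parallelism safe. The context handed to
plugins carries the source path, file and directory names, the header, the
raw split row with its 1-based data-row number, and the partial record.

## Reading dialects

Dialects are chosen by extension after stripping one optional `.gz`:
`.csv` (comma, RFC 4180 quoting — embedded delimiters, doubled quotes and
quoted newlines), `.tsv`/`.txt` (tab), `.maf` (tab, `#` pragma lines),
`.vcf` (tab, `##` metadata, header at the `#CHROM` line with the `#`
stripped). Three choices are deliberate:

* **VCF records stay opaque.** INFO/FORMAT/sample columns are carried as
  strings and never exploded; multi-allelic ALT values pass through
  unsplit. The engine unifies formats, it does not interpret VCF
  semantics — a plugin can, explicitly.
* **Coordinates are never adjusted.** MAF and VCF are both passed through
  as written. Silent 0/1-based arithmetic is the classic corruption bug;
  any conversion belongs in a visible plugin.
* **Ragged rows are a hard error by default**, with file and row in the
  message; `skip_bad_rows` demotes them to a counted skip. Silent
  truncation would corrupt cohort-level counts.

Encoding is validated (invalid UTF-8 is an error with the line number)
rather than silently replaced; a lenient mode substitutes `?`. The reader
streams in chunks of 4096 physical lines, so memory use is independent of
file size; quoted CSV records spanning chunk boundaries are carried over
before splitting.

## Tasks and the parallelism contract

Four operations cover cohort curation: `find_files()` (pair every input
with its governing annotation), `cat_variants()` (the unified table),
`group_by_variants()` and `count_variants()` (streaming aggregation with an
optional single-comparison `where` filter). Discovery uses a
nearest-ancestor rule: the closest annotation up the directory tree whose
patterns match the file governs it; two applicable annotations in one
directory are ambiguous and raise an error rather than guessing.

The parallel contract is: *the worker count never changes any output
byte*. The unit of work is one input file; results are merged by
lexicographic path order (locale-independent radix sort), and rows keep
source order within files. Grouping therefore orders records by (file,
row) within each key, keys sorted. Records whose group key is unresolvable
fall into the sentinel-labelled group — dropping them would break the
conservation law that group sizes sum to the total count, which the test
suite asserts on every fixture.

The `where` grammar is deliberately one comparison (`FIELD OP LITERAL`,
`OP ∈ {==, !=, <, <=, >, >=}`). Ordering operators require both sides to
parse as decimal numbers; a non-numeric cell under an ordering comparison
is an error by default (surfacing dirty data) or counts as false under
`lenient_where`. Equality compares numerically when both sides are numeric
— so `POS == 05` matches `5` — and as strings otherwise. Conjunctions are
out of scope; compose filters by piping.

## The plugin system

A plugin is a named `process(ctx)` function returning one string per row.
User plugins live one-per-subdirectory (a `plugin.yaml` descriptor plus a
`plugin.R` implementation); `scaffold_plugin()` generates a template that
loads unmodified, and a user plugin overriding a built-in name wins with a
warning. A plugin failure on an optional field yields the sentinel; on a
required field it aborts with provenance, consistent with every other
resolution failure.

The built-in `alteration_type` classifier assigns SNV / MNV / INS / DEL /
UNKNOWN from the `REF`/`ALT` pair. Its rules accept both indel encodings:
MAF dashes (`-` → INS/DEL directly) and VCF anchors (classified by raw
length comparison — the shared leading base is *not* trimmed, because
classification must not rewrite alleles). Two corner decisions: characters
outside `A,C,G,T,N` classify as UNKNOWN before any length rule fires, and
a pair with both alleles empty/dash is UNKNOWN rather than INS — there is
no event to classify, and this keeps the swap symmetry exact: exchanging
ref and alt maps INS ↔ DEL and fixes SNV, MNV and UNKNOWN, a property the
tests check over every short allele pair.

## The fixture generator

`generate_cohorts()` builds the cohort trees the whole test suite runs on:
one directory per cohort, one file per requested format, each with
`rows_per_file` synthetic mutations (chromosome uniform over 1–22/X,
position uniform over 1..1e8, alteration class uniform over the four
types, alleles drawn per the file's indel convention, and an exactly
planted fraction — default 15%, i.e. `round(0.15 * rows)` rows per file —
of `FILTER = LowQual`). Each cohort gets a matching annotation exercising
all six field kinds, and a manifest records every per-file, per-type and
per-filter count as ground truth. The same seed reproduces a
byte-identical tree, and the caller's RNG state is restored.

What the fixtures emulate is format heterogeneity: divergent header
spellings, pragma lines, quoting, compression, and the two indel
encodings. What they deliberately do not emulate: realistic mutation
spectra, reference-genome-consistent alleles, multi-sample VCFs with
genotype columns, or malformed files beyond what individual tests
construct. Green tests therefore demonstrate the *parsing contract* —
shape uniformity, conservation, determinism, oracle agreement — not
robustness to every pathology of real-world submissions.

## Problem sizes and verification

The suite checks the engine against deliberately naive references
(whole-file read-then-split, per-row field loops, brute-force joins and
filters, an enumerated classifier truth table) that share no code with the
streaming paths. Randomized cross-checks run 50 generated cohorts of up to
a few hundred rows each; determinism and conservation are additionally
asserted on a 5-cohort × 1000-row tree, and the classifier table covers
all ~24 000 ref/alt pairs over `{A,C,G,T,-}` up to length 3. These sizes
exercise every code path (chunked streaming included, via small chunk
sizes) while keeping the default test run fast.

## Known limitations

* One output schema per run: `cat` across annotations with different
  column lists is an error, not a column union.
* No BCF/tabix, no Excel, no JSON/TOML annotation dialects, no remote
  mapping tables, no schema inheritance.
* No genome-build liftover and no reference-allele validation; both need
  external resources and belong in explicit plugins.
* Sample columns of multi-sample VCFs are pass-through strings only; they
  never contribute rows.
* The where grammar is a single comparison by design.
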