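# varcat

Annotation-driven harmonization of heterogeneous small-variant files.

Cancer-genomics analyses routinely integrate somatic mutations called by
many projects, and each project ships its own shape: MAF tables with
`Chromosome` / `Start_Position` headers and `-` indel placeholders, VCFs
with `##` metadata and anchored indel alleles, ad-hoc CSV/TSV exports,
everything sometimes gzipped. On top of the format problem, integrative
work needs per-cohort metadata — dataset name, directory name, file name —
injected as ordinary columns so rows stay attributable after aggregation.

varcat solves both with a declarative *annotation file* per cohort: a YAML
document stating which files to read (`pattern` globs), the ordered output
`columns`, and how each column's value is obtained. Six field kinds cover
the transformations:

| kind       | value                                                  |
|------------|--------------------------------------------------------|
| `static`   | a literal (e.g. the dataset label)                     |
| `internal` | first input column present among an alias list         |
| `filename` | regex capture from the file name                       |
| `dirname`  | regex capture from the parent directory name           |
| `mapping`  | aliased input value translated via a two-column table  |
| `plugin`   | a per-record function of the parsing context           |

Columns without a definition pass through from the same-named input column
(matched case-insensitively); unresolvable optional fields emit a sentinel.
Four streaming tasks operate on any annotated tree — `find_files()`,
`cat_variants()`, `group_by_variants()`, `count_variants()` — with a strict
contract: the worker count (`workers =` / `--cores`) never changes an
output byte. A plugin system extends per-record transformation; the
built-in `alteration_type` plugin classifies REF/ALT pairs as
SNV / MNV / INS / DEL / UNKNOWN under both the MAF-dash and VCF-anchored
indel conventions.

## Worked example

```r
library(varcat)

d <- file.path(tempdir(), "demo")
generate_cohorts(d, n_cohorts = 2, rows_per_file = 4,
                 formats = c("MAF", "VCF"), seed = 7)
writeLines(head(cat_variants(d, header = TRUE), 6))
```

```
CHROM	POS	REF	ALT	FILTER	DATASET	COHORT_DIR	SOURCE_FILE	ALT_TYPE	CHROM_CLASS
15	79343125	CG	CC	PASS	cohortA	cohortA	variants.maf	MNV	autosome
6	58929035	-	TTC	PASS	cohortA	cohortA	variants.maf	INS	autosome
16	14057346	-	TGC	LowQual	cohortA	cohortA	variants.maf	INS	autosome
22	40097446	TTC	-	PASS	cohortA	cohortA	variants.maf	DEL	autosome
12	78465402	AT	A	PASS	cohortA	cohortA	variants.vcf	DEL	autosome
```

One schema has unified a MAF (dash indels, MAF header spellings) and a VCF
(anchored indels, `#CHROM` header) into a single fixed column set.
`DATASET`, `COHORT_DIR` and `SOURCE_FILE` are injected metadata —
a literal, a directory-name capture and a file-name capture — while
`ALT_TYPE` comes from the built-in classifier and `CHROM_CLASS` from a
mapping table.

```r
count_variants(d, group_by = "ALT_TYPE")
```

```
DEL	7
INS	4
MNV	3
SNV	2
TOTAL	16
```

The per-type counts partition the 16 records (2 cohorts × 2 files × 4
rows); the same conservation holds for any grouping key. Filtering uses a
single comparison: `count_variants(d, where = 'FILTER != "LowQual"')$total`
returns `12` here, the 16 records minus the 4 planted low-quality rows.

The same operations are available from a shell:

```sh
varcat=$(Rscript -e 'cat(system.file("scripts", "varcat", package = "varcat"))')
Rscript "$varcat" cat -i demo/ --header
Rscript "$varcat" count -i demo/ -g DATASET --where 'ALT_TYPE == "SNV"' --cores 4
Rscript "$varcat" plugin new my_filter --dir plugins/
```

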