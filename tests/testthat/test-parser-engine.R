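make_ctx <- function(path = "proj/TCGA_OV/muts.tsv",
                     header = c("Chromosome", "POS"),
                     values = c("7", "123"), row = 1L, schema = NULL) {
  new_context(path, header, values, row, schema = schema)
}

test_that("each field kind resolves per its rule", {
  ctx <- make_ctx()
  expect_equal(resolve_field(field_def("D", "static", value = "cohortA"), ctx),
               "cohortA")
  # working-directory metadata: capture-all regex on the parent dir name
  expect_equal(resolve_field(field_def("DIR", "dirname", regex = "(.*)"), ctx),
               "TCGA_OV")
  expect_equal(resolve_field(field_def("F", "filename",
                                       regex = "(.*)\\.tsv"), ctx),
               "muts")
  # first alias present in the header wins, case-insensitively
  expect_equal(resolve_field(field_def("CHROM", "internal",
                                       aliases = c("chromosome", "CHROM",
                                                   "chr")), ctx),
               "7")
  expect_equal(resolve_field(field_def("P", "internal",
                                       aliases = c("Start_Position", "POS")),
                             ctx),
               "123")
})

test_that("optional unresolvable fields yield the sentinel; required ones abort", {
  sch <- annotation_schema("*.tsv", c("X"), missing_sentinel = "?")
  ctx <- make_ctx(schema = sch)
  fd <- field_def("X", "internal", aliases = "absent_column")
  expect_equal(resolve_field(fd, ctx), "?")
  fd_req <- field_def("X", "internal", aliases = "absent_column",
                      required = TRUE)
  expect_error(resolve_field(fd_req, ctx), "required field 'X'",
               class = "varcat_parse_error")
  # regex miss on a required metadata field
  expect_error(resolve_field(field_def("X", "filename", regex = "(zzz)",
                                       required = TRUE), ctx),
               class = "varcat_parse_error")
})

test_that("mapping resolution agrees with a brute-force join on random data", {
  set.seed(7)
  keys <- sprintf("K%03d", 1:1000)
  vals <- replicate(1000, paste(sample(LETTERS, 4, TRUE), collapse = ""))
  d <- tmp_tree()
  writeLines(c("key\tvalue", paste(keys, vals, sep = "\t")),
             file.path(d, "map.mapping"))
  probe_keys <- sample(keys, 200, replace = TRUE)
  write_tsv_file(file.path(d, "probes.tsv"), c("CODE"),
                 as.list(probe_keys))
  ann <- write_annotation_file(file.path(d, "ann.yaml"), list(
    pattern = list("*.tsv"), columns = list("CODE", "MAPPED"),
    annotation = list(list(type = "mapping", name = "MAPPED",
                           aliases = list("CODE"),
                           mapping_file = "map.mapping",
                           key_column = "key", value_column = "value"))))
  sch <- load_annotation(ann)
  got <- parse_file(file.path(d, "probes.tsv"), sch)
  # brute-force join oracle over the raw table
  lookup <- setNames(vals, keys)
  expect_equal(got$MAPPED, unname(lookup[probe_keys]))
})

test_that("one schema unifies three formats into identically shaped records", {
  d <- tmp_tree()
  write_tsv_file(file.path(d, "a.tsv"), c("CHROM", "POS", "EXTRA"),
                 list(c("1", "100", "x"), c("2", "200", "y")))
  write_csv_file(file.path(d, "b.csv"), c("Chromosome", "POS"),
                 list(c("3", "300"), c("4", "400")))
  write_vcf_file(file.path(d, "c.vcf"),
                 list(c("5", "500", ".", "A", "T", "9", "PASS", ".")))
  sch <- annotation_schema(
    patterns = c("*.tsv", "*.csv", "*.vcf"),
    columns = c("CHROM", "POS", "DATASET"),
    field_defs = list(
      field_def("CHROM", "internal", aliases = c("CHROM", "Chromosome")),
      field_def("DATASET", "static", value = "demo")))
  recs <- lapply(file.path(d, c("a.tsv", "b.csv", "c.vcf")), parse_file,
                 schema = sch)
  for (r in recs) {
    expect_equal(names(r), c("CHROM", "POS", "DATASET"))
  }
  all <- do.call(rbind, recs)
  expect_equal(nrow(all), 5L)
  expect_equal(all$CHROM, as.character(1:5))
  expect_equal(all$POS, as.character(1:5 * 100L))
  expect_equal(unique(all$DATASET), "demo")
})

test_that("an empty data section yields an empty frame, not an error", {
  f <- write_tsv_file(tempfile(fileext = ".tsv"), c("A", "B"), list())
  sch <- annotation_schema("*.tsv", c("A", "B"))
  out <- parse_file(f, sch)
  expect_equal(nrow(out), 0L)
  expect_equal(names(out), c("A", "B"))
})

test_that("row exclusions drop exactly the matching records", {
  set.seed(3)
  n <- 100
  filt <- rep("PASS", n)
  filt[sample.int(n, 17)] <- "LowQual"
  f <- write_tsv_file(tempfile(fileext = ".tsv"), c("POS", "FILTER"),
                      Map(c, seq_len(n), filt))
  sch_drop <- annotation_schema("*.tsv", c("POS", "FILTER"),
                                exclusions = list(list(field = "FILTER",
                                                       value = "LowQual")))
  expect_equal(nrow(parse_file(f, sch_drop)), 83L)
  # no exclusions: identity
  sch_keep <- annotation_schema("*.tsv", c("POS", "FILTER"))
  expect_equal(nrow(parse_file(f, sch_keep)), 100L)
  # per-record decision helper agrees
  expect_false(apply_exclusions(c(POS = "1", FILTER = "LowQual"), sch_drop))
  expect_true(apply_exclusions(c(POS = "1", FILTER = "PASS"), sch_drop))
  expect_true(apply_exclusions(c(POS = "1", FILTER = "LowQual"), sch_keep))
})

test_that("ragged rows abort with provenance by default and are counted when skipped", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "1\t2", "only_one_field", "3\t4"), f)
  sch <- annotation_schema("*.tsv", c("A", "B"))
  err <- tryCatch(parse_file(f, sch), error = identity)
  expect_s3_class(err, "varcat_parse_error")
  expect_match(conditionMessage(err), "row 2")
  out <- parse_file(f, sch, skip_bad_rows = TRUE)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "skipped"), 1L)
  expect_equal(attr(out, "provenance")$row, c(1L, 3L))
})

test_that("with no required fields, parsing is total over random header/row shapes", {
  set.seed(19)
  sch <- annotation_schema(
    "*.tsv", c("CHROM", "POS", "MISSING_EVERYWHERE", "TYPE"),
    field_defs = list(
      field_def("TYPE", "plugin", plugin = "alteration_type")),
    missing_sentinel = "-")
  for (rep in 1:20) {
    cols <- sample(c("CHROM", "POS", "REF", "ALT", "junk1", "junk2"),
                   sample(1:5, 1))
    n <- sample(0:8, 1)
    rows <- lapply(seq_len(n), function(i)
      replicate(length(cols), sample(c(LETTERS, "-"), 1)))
    f <- write_tsv_file(tempfile(fileext = ".tsv"), cols, rows)
    out <- parse_file(f, sch)
    expect_equal(nrow(out), n)
    expect_equal(names(out), sch$columns)
  }
})

test_that("parse_file matches the naive whole-file oracle record-for-record", {
  d <- tmp_tree()
  dir.create(file.path(d, "TCGA_OV"))
  writeLines(c("k\tv", paste0("K", 1:50, "\tV", 1:50)),
             file.path(d, "m.mapping"))
  set.seed(23)
  n <- 300
  rows <- lapply(seq_len(n), function(i) {
    c(sample(c(1:22, "X"), 1), sample.int(1e8, 1),
      sample(c("A", "ACT", "-", "G"), 1), sample(c("T", "A", "-", "GC"), 1),
      sample(c("PASS", "LowQual"), 1), paste0("K", sample.int(60, 1)))
  })
  f <- write_maf_file(file.path(d, "TCGA_OV", "muts.maf"),
                      c("Chromosome", "Start_Position", "Reference_Allele",
                        "Tumor_Seq_Allele2", "FILTER", "CODE"), rows)
  ann <- write_annotation_file(file.path(d, "ann.yaml"), list(
    pattern = list("*.maf"),
    columns = list("CHROM", "POS", "REF", "ALT", "FILTER", "DS", "DIR",
                   "SRC", "VAL", "TYPE"),
    exclude_rows = list(list(field = "FILTER", value = "LowQual")),
    missing_value = "NA",
    annotation = list(
      list(type = "internal", name = "CHROM",
           aliases = list("Chromosome", "CHROM")),
      list(type = "internal", name = "POS",
           aliases = list("Start_Position", "POS")),
      list(type = "internal", name = "REF",
           aliases = list("Reference_Allele", "REF")),
      list(type = "internal", name = "ALT",
           aliases = list("Tumor_Seq_Allele2", "ALT")),
      list(type = "static", name = "DS", value = "ovarian"),
      list(type = "dirname", name = "DIR", regex = "(.*)"),
      list(type = "filename", name = "SRC", regex = "(.*)"),
      list(type = "mapping", name = "VAL", aliases = list("CODE"),
           mapping_file = "m.mapping", key_column = "k", value_column = "v"),
      list(type = "plugin", name = "TYPE", plugin = "alteration_type"))))
  sch <- load_annotation(ann)
  got <- parse_file(f, sch)
  want <- oracle_parse(f, sch)
  attr(got, "provenance") <- NULL
  attr(got, "skipped") <- NULL
  expect_equal(got, want)
  # order preservation: source order of kept rows
  kept_pos <- vapply(rows, `[`, character(1), 2)[
    vapply(rows, `[`, character(1), 5) != "LowQual"]
  expect_equal(got$POS, kept_pos)
})
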