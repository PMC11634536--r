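test_that("find_files pairs inputs with annotations by pattern", {
  d <- tmp_tree()
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.maf", c("Chromosome")))
  write_maf_file(file.path(d, "a.maf"), c("Chromosome"), list("1"))
  write_vcf_file(file.path(d, "b.vcf"),
                 list(c("1", "5", ".", "A", "T", "9", "PASS", ".")))
  pairs <- quiet(find_files(d))
  expect_equal(nrow(pairs), 1L)
  expect_equal(basename(pairs$path), "a.maf")
  expect_equal(basename(pairs$annotation), "ann.yaml")
  # the unmatched vcf produces a warning, not an error
  expect_warning(find_files(d), "no applicable annotation")
})

test_that("the nearest ancestor annotation wins; same-directory ties fail", {
  d <- tmp_tree()
  dir.create(file.path(d, "sub"))
  write_annotation_file(file.path(d, "outer.yaml"),
                        passthrough_doc("*.tsv", c("A"), missing_value = "o"))
  write_annotation_file(file.path(d, "sub", "inner.yaml"),
                        passthrough_doc("*.tsv", c("A"), missing_value = "i"))
  write_tsv_file(file.path(d, "top.tsv"), "A", list("1"))
  write_tsv_file(file.path(d, "sub", "deep.tsv"), "A", list("2"))
  pairs <- find_files(d)
  got <- setNames(basename(pairs$annotation), basename(pairs$path))
  expect_equal(got[["deep.tsv"]], "inner.yaml")
  expect_equal(got[["top.tsv"]], "outer.yaml")

  # a second applicable annotation in the same directory is ambiguous
  write_annotation_file(file.path(d, "sub", "inner2.yaml"),
                        passthrough_doc("*.tsv", c("A")))
  expect_error(find_files(d), "ambiguous", class = "varcat_schema_error")
})

test_that("recursive: false restricts an annotation to its own directory", {
  d <- tmp_tree()
  dir.create(file.path(d, "sub"))
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.tsv", c("A"), recursive = FALSE))
  write_tsv_file(file.path(d, "here.tsv"), "A", list("1"))
  write_tsv_file(file.path(d, "sub", "below.tsv"), "A", list("2"))
  pairs <- quiet(find_files(d))
  expect_equal(basename(pairs$path), "here.tsv")
})

test_that("an annotation override bypasses discovery entirely", {
  d <- tmp_tree()
  write_tsv_file(file.path(d, "a.tsv"), c("A", "B"), list(c("1", "2")))
  ann <- write_annotation_file(tempfile(fileext = ".yaml"),
                               passthrough_doc("*.tsv", c("A", "B")))
  pairs <- find_files(d, annotation = ann)
  expect_equal(nrow(pairs), 1L)
  lines <- cat_variants(d, annotation = ann, header = TRUE)
  expect_equal(as.character(lines), c("A\tB", "1\t2"))
})

test_that("cat emits header plus one line per kept record, in file and row order", {
  d <- tmp_tree()
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.tsv", c("A", "B")))
  write_tsv_file(file.path(d, "x.tsv"), c("A", "B"),
                 list(c("1", "a"), c("2", "b"), c("3", "c")))
  lines <- cat_variants(d, header = TRUE)
  expect_length(lines, 4L)
  expect_equal(lines[1], "A\tB")
  expect_equal(lines[2:4], c("1\ta", "2\tb", "3\tc"))
  # conservation: data lines equal the unfiltered count
  expect_equal(length(lines) - 1L, count_variants(d)$total)
})

test_that("cat refuses to mix annotations with different column sets", {
  d <- tmp_tree()
  dir.create(file.path(d, "c1")); dir.create(file.path(d, "c2"))
  write_annotation_file(file.path(d, "c1", "ann.yaml"),
                        passthrough_doc("*.tsv", c("A", "B")))
  write_annotation_file(file.path(d, "c2", "ann.yaml"),
                        passthrough_doc("*.tsv", c("A", "Z")))
  write_tsv_file(file.path(d, "c1", "x.tsv"), c("A", "B"), list(c("1", "2")))
  write_tsv_file(file.path(d, "c2", "y.tsv"), c("A", "Z"), list(c("3", "4")))
  expect_error(cat_variants(d), "mismatch", class = "varcat_schema_error")
})

test_that("CSV output quotes fields per RFC 4180", {
  d <- tmp_tree()
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.tsv", c("A", "B"),
                                        format = "csv"))
  write_tsv_file(file.path(d, "x.tsv"), c("A", "B"),
                 list(c("with,comma", 'with"quote')))
  lines <- cat_variants(d, header = TRUE)
  expect_equal(lines[2], '"with,comma","with""quote"')
  # and the emitted csv re-parses to the same values
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  back <- iter_rows(f)
  expect_equal(back$rows[[1]]$values, c("with,comma", 'with"quote'))
})

test_that("group_by partitions records; unresolvable keys join the sentinel group", {
  d <- tmp_tree()
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.tsv", c("A", "K")))
  write_tsv_file(file.path(d, "x.tsv"), c("A", "K"),
                 list(c("1", "g1"), c("2", "g2"), c("3", "g1")))
  write_tsv_file(file.path(d, "y.tsv"), c("A"),   # lacks K entirely
                 list("4", "5"))
  g <- group_by_variants(d, "K")
  expect_equal(names(g), c("", "g1", "g2"))  # sentinel group sorts first
  expect_equal(vapply(g, nrow, integer(1)),
               c(2L, 2L, 1L), ignore_attr = TRUE)
  # conservation: groups partition the records
  expect_equal(sum(vapply(g, nrow, integer(1))), count_variants(d)$total)
  # within-group order follows (file, row)
  expect_equal(g[["g1"]]$A, c("1", "3"))
})

test_that("an unknown group key fails before any file is parsed", {
  d <- tmp_tree()
  write_annotation_file(file.path(d, "ann.yaml"),
                        passthrough_doc("*.tsv", c("A")))
  f <- file.path(d, "x.tsv")
  writeLines(c("A", "1", "ragged\textra"), f)  # parsing this would error
  expect_error(group_by_variants(d, "NOT_A_COLUMN"), "unknown group key",
               class = "varcat_schema_error")
})

test_that("counts with a where clause match a brute-force filter", {
  fix <- tmp_tree()
  m <- quiet(generate_cohorts(fix, n_cohorts = 3, rows_per_file = 120,
                              formats = c("TSV", "CSV"), seed = 13))
  lines <- cat_variants(fix, header = FALSE)
  tab <- as.data.frame(do.call(rbind, strsplit(as.character(lines), "\t")),
                       stringsAsFactors = FALSE)
  names(tab) <- c("CHROM", "POS", "REF", "ALT", "FILTER", "DATASET",
                  "COHORT_DIR", "SOURCE_FILE", "ALT_TYPE", "CHROM_CLASS")
  for (w in list(c("POS", ">=", "50000000"), c("POS", "<", "1000000"),
                 c("DATASET", "==", "cohortB"), c("ALT_TYPE", "!=", "SNV"))) {
    got <- count_variants(fix, where = paste(w, collapse = " "))$total
    expect_equal(got, sum(oracle_where_keep(tab, w[1], w[2], w[3])),
                 info = paste(w, collapse = " "))
  }
  # per-group totals sum to the total under a filter
  cnt <- count_variants(fix, where = "POS >= 50000000",
                        group_by = "DATASET")
  expect_equal(sum(cnt$groups), cnt$total)
})

test_that("fixture manifests agree with every engine count", {
  fix <- tmp_tree()
  m <- quiet(generate_cohorts(fix, n_cohorts = 3, rows_per_file = 100,
                              formats = c("TSV", "VCF"), seed = 42))
  expect_equal(count_variants(fix)$total, m$totals$rows)
  # per-cohort counts
  cnt <- count_variants(fix, group_by = "DATASET")
  expect_equal(as.list(cnt$groups), m$totals$per_cohort)
  expect_equal(count_variants(fix, where = 'DATASET == "cohortB"')$total,
               m$totals$per_cohort$cohortB)
  # per-alteration-type group sizes
  g <- group_by_variants(fix, "ALT_TYPE")
  expect_equal(lapply(g, nrow)[names(m$totals$types)], m$totals$types)
})

test_that("worker count never changes any output byte", {
  fix <- tmp_tree()
  quiet(generate_cohorts(fix, n_cohorts = 3, rows_per_file = 80,
                         formats = c("TSV", "VCF", "CSV"), seed = 99,
                         gzip_fraction = 0.4))
  ref_cat <- cat_variants(fix, workers = 1)
  ref_grp <- group_by_variants(fix, "ALT_TYPE", workers = 1)
  ref_cnt <- count_variants(fix, group_by = "DATASET", workers = 1)
  for (w in c(2L, 4L)) {
    expect_identical(cat_variants(fix, workers = w), ref_cat)
    expect_identical(group_by_variants(fix, "ALT_TYPE", workers = w),
                     ref_grp)
    expect_identical(count_variants(fix, group_by = "DATASET", workers = w),
                     ref_cnt)
  }
})
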