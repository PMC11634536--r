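# Synthetic cohort generation: deterministic toy mutation tables in every
# supported dialect, with a ground-truth manifest of the counts every task
# should reproduce. Not biologically realistic by design — the fixtures
# exercise format heterogeneity (header spellings, comment pragmas, quoting,
# compression), not mutation spectra.

BASES <- c("A", "C", "G", "T")

random_allele <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# draw one REF/ALT pair of a given class, in the requested encoding
# convention; "anchored" = VCF style (shared leading base), "dash" = MAF
# style ("-" placeholder). Classified as written, both encodings land in
# the intended class.
draw_alleles <- function(type, convention) {
  switch(type,
    SNV = {
      ref <- random_allele(1L)
      alt <- sample(setdiff(BASES, ref), 1L)
      c(ref, alt)
    },
    MNV = {
      len <- sample(2:3, 1L)
      ref <- random_allele(len)
      repeat {
        alt <- random_allele(len)
        if (alt != ref) break
      }
      c(ref, alt)
    },
    INS = {
      ins <- random_allele(sample(1:3, 1L))
      if (convention == "anchored") {
        anchor <- random_allele(1L)
        c(anchor, paste0(anchor, ins))
      } else c("-", ins)
    },
    DEL = {
      del <- random_allele(sample(1:3, 1L))
      if (convention == "anchored") {
        anchor <- random_allele(1L)
        c(paste0(anchor, del), anchor)
      } else c(del, "-")
    }
  )
}

fixture_file_name <- function(format) {
  switch(format, TSV = "variants.tsv", CSV = "variants.csv",
         MAF = "variants.maf", VCF = "variants.vcf")
}

write_fixture_file <- function(path, format, tab, gzip = FALSE) {
  lines <- switch(format,
    TSV = c(paste(c("CHROM", "POS", "REF", "ALT", "FILTER"), collapse = "\t"),
            do.call(paste, c(tab[c("chrom", "pos", "ref", "alt", "filter")],
                             sep = "\t"))),
    CSV = c("CHROM,POS,REF,ALT,FILTER",
            do.call(paste, c(tab[c("chrom", "pos", "ref", "alt", "filter")],
                             sep = ","))),
    MAF = c("#version 2.4",
            paste(c("Chromosome", "Start_Position", "Reference_Allele",
                    "Tumor_Seq_Allele2", "FILTER"), collapse = "\t"),
            do.call(paste, c(tab[c("chrom", "pos", "ref", "alt", "filter")],
                             sep = "\t"))),
    VCF = c("##fileformat=VCFv4.2",
            paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                "FILTER", "INFO"), collapse = "\t")),
            do.call(paste, c(list(tab$chrom, tab$pos, ".", tab$ref, tab$alt,
                                  tab$qual, tab$filter, "."), sep = "\t")))
  )
  if (gzip) {
    con <- gzfile(path, open = "wb")
    writeLines(lines, con)
    close(con)
  } else {
    writeLines(lines, path)
  }
}

fixture_annotation_doc <- function(dataset, exclude_lowqual, with_mapping) {
  defs <- list(
    list(type = "internal", name = "CHROM",
         aliases = list("CHROM", "Chromosome")),
    list(type = "internal", name = "POS",
         aliases = list("POS", "Start_Position")),
    list(type = "internal", name = "REF",
         aliases = list("REF", "Reference_Allele")),
    list(type = "internal", name = "ALT",
         aliases = list("ALT", "Tumor_Seq_Allele2")),
    list(type = "static", name = "DATASET", value = dataset),
    list(type = "dirname", name = "COHORT_DIR", regex = "(.*)"),
    list(type = "filename", name = "SOURCE_FILE",
         regex = "^(variants\\.[a-z.]+)$"),
    list(type = "plugin", name = "ALT_TYPE", plugin = "alteration_type")
  )
  columns <- list("CHROM", "POS", "REF", "ALT", "FILTER", "DATASET",
                  "COHORT_DIR", "SOURCE_FILE", "ALT_TYPE")
  if (with_mapping) {
    defs <- c(defs, list(list(
      type = "mapping", name = "CHROM_CLASS", aliases = list("CHROM",
                                                             "Chromosome"),
      mapping_file = "../chrom_class.mapping",
      key_column = "chrom", value_column = "class")))
    columns <- c(columns, list("CHROM_CLASS"))
  }
  doc <- list(pattern = list("variants.*"), recursive = TRUE,
              format = "tsv", columns = columns, annotation = defs)
  if (exclude_lowqual) {
    doc$exclude_rows <- list(list(field = "FILTER", value = "LowQual"))
  }
  doc
}

#' Generate deterministic multi-format toy cohorts
#'
#' Creates one directory per cohort, each holding one synthetic mutation
#' file per requested format (random chromosome in 1..22/X, position in
#' 1..1e8, REF/ALT drawn to cover SNV, MNV, insertion and deletion classes,
#' and a FILTER column with a fixed fraction of exactly-planted `LowQual`
#' rows), a matching annotation file per cohort, a shared chromosome-class
#' mapping table, and a ground-truth manifest recording every per-file,
#' per-type and per-filter count. The same seed reproduces a byte-identical
#' tree.
#'
#' Alleles follow each format's convention: VCF files use anchored indels
#' (`REF=A, ALT=AT`), the others use dash placeholders (`REF=-, ALT=T`);
#' header spellings differ per dialect (MAF uses `Chromosome`,
#' `Start_Position`, ...) so the fixtures exercise the alias mechanism the
#' way real cohorts do.
#'
#' @param out_dir Output directory (created; must be empty unless `force`).
#' @param n_cohorts Number of cohorts (max 26).
#' @param rows_per_file Data rows per generated file.
#' @param formats Subset of `c("TSV", "CSV", "MAF", "VCF")`.
#' @param seed Integer seed; the sole source of randomness.
#' @param lowqual_fraction Fraction of rows per file planted as
#'   `FILTER = "LowQual"` (exact count `round(fraction * rows)`).
#' @param gzip_fraction Fraction of data files written gzip-compressed.
#' @param exclude_lowqual Add an `exclude_rows` rule dropping LowQual rows
#'   to every generated annotation.
#' @param force Overwrite a non-empty `out_dir`.
#' @return The manifest, invisibly: a list with `seed`, per-file entries
#'   (`path`, `cohort`, `format`, `rows`, `lowqual`, `types`), and `totals`;
#'   also written to `fixture_manifest.yaml` under `out_dir`.
#' @export
generate_cohorts <- function(out_dir, n_cohorts = 3L, rows_per_file = 100L,
                             formats = c("TSV", "VCF"), seed = 42L,
                             lowqual_fraction = 0.15, gzip_fraction = 0,
                             exclude_lowqual = FALSE, force = FALSE) {
  formats <- match.arg(toupper(formats), c("TSV", "CSV", "MAF", "VCF"),
                       several.ok = TRUE)
  n_cohorts <- as.integer(n_cohorts)
  rows_per_file <- as.integer(rows_per_file)
  stopifnot(n_cohorts >= 1L, n_cohorts <= 26L, rows_per_file >= 1L)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    vc_abort(sprintf("output directory %s is not empty (use force)", out_dir),
             "varcat_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # keep the caller's RNG state untouched
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)

  chroms <- c(as.character(1:22), "X")
  types <- c("SNV", "MNV", "INS", "DEL")

  # shared mapping table: chromosome -> autosome/sex
  map_path <- file.path(out_dir, "chrom_class.mapping")
  writeLines(c("chrom\tclass",
               paste(chroms, ifelse(chroms == "X", "sex", "autosome"),
                     sep = "\t")), map_path)

  files <- list()
  for (ci in seq_len(n_cohorts)) {
    cohort <- paste0("cohort", LETTERS[ci])
    cdir <- file.path(out_dir, cohort)
    dir.create(cdir, showWarnings = FALSE)
    writeLines(yaml::as.yaml(
      fixture_annotation_doc(cohort, exclude_lowqual, with_mapping = TRUE)),
      file.path(cdir, "annotation.yaml"))
    for (fmt in formats) {
      n <- rows_per_file
      type <- sample(types, n, replace = TRUE)
      convention <- if (fmt == "VCF") "anchored" else "dash"
      alleles <- vapply(type, draw_alleles, character(2),
                        convention = convention)
      n_low <- round(lowqual_fraction * n)
      filter <- rep("PASS", n)
      if (n_low > 0) filter[sample.int(n, n_low)] <- "LowQual"
      tab <- list(
        chrom = sample(chroms, n, replace = TRUE),
        pos = sample.int(1e8L, n, replace = TRUE),
        ref = alleles[1, ], alt = alleles[2, ],
        qual = sample.int(99L, n, replace = TRUE),
        filter = filter
      )
      gz <- gzip_fraction > 0 && stats::runif(1) < gzip_fraction
      fname <- paste0(fixture_file_name(fmt), if (gz) ".gz" else "")
      fpath <- file.path(cdir, fname)
      write_fixture_file(fpath, fmt, tab, gzip = gz)
      files[[length(files) + 1L]] <- list(
        path = file.path(cohort, fname), cohort = cohort, format = fmt,
        gzip = gz, rows = n, lowqual = sum(filter == "LowQual"),
        types = as.list(stats::setNames(
          as.integer(table(factor(type, levels = types))), types))
      )
    }
  }

  type_totals <- stats::setNames(as.list(integer(length(types))), types)
  for (f in files) {
    for (t in types) type_totals[[t]] <- type_totals[[t]] + f$types[[t]]
  }
  manifest <- list(
    seed = as.integer(seed),
    n_cohorts = as.integer(n_cohorts),
    rows_per_file = as.integer(rows_per_file),
    formats = as.list(formats),
    exclude_lowqual = exclude_lowqual,
    files = files,
    totals = list(
      rows = sum(vapply(files, `[[`, integer(1), "rows")),
      lowqual = sum(vapply(files, `[[`, integer(1), "lowqual")),
      types = type_totals,
      per_cohort = as.list(vapply(split(
        vapply(files, `[[`, integer(1), "rows"),
        vapply(files, `[[`, character(1), "cohort")), sum, integer(1)))
    )
  )
  writeLines(yaml::as.yaml(manifest),
             file.path(out_dir, "fixture_manifest.yaml"))
  invisible(manifest)
}

#' Read back a fixture manifest
#'
#' @param out_dir Directory previously populated by [generate_cohorts()].
#' @return The manifest list.
#' @export
load_manifest <- function(out_dir) {
  p <- file.path(out_dir, "fixture_manifest.yaml")
  if (!file.exists(p)) {
    vc_abort(sprintf("no fixture manifest under %s", out_dir),
             "varcat_io_error")
  }
  yaml::read_yaml(p)
}
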