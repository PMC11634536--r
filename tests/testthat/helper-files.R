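# Small builders for hand-written inputs; all fixtures are constructed in
# code at test time.

tmp_tree <- function() {
  d <- tempfile("tree")
  dir.create(d, recursive = TRUE)
  d
}

write_tsv_file <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

write_csv_file <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, character(1), collapse = ",")), path)
  path
}

write_maf_file <- function(path, header, rows, pragma = "#version 2.4") {
  writeLines(c(pragma, paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

write_vcf_file <- function(path, rows,
                           header = c("CHROM", "POS", "ID", "REF", "ALT",
                                      "QUAL", "FILTER", "INFO")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#", paste(header, collapse = "\t")),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

write_annotation_file <- function(path, doc) {
  writeLines(yaml::as.yaml(doc), path)
  path
}

gzip_copy <- function(src, dst = paste0(src, ".gz")) {
  con <- gzfile(dst, "wb")
  writeLines(readLines(src), con)
  close(con)
  dst
}

# a minimal pass-through annotation document
passthrough_doc <- function(patterns, columns, ...) {
  c(list(pattern = as.list(patterns), columns = as.list(columns)), list(...))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
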