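# Deliberately naive reference implementations: read the whole file, loop
# over rows and fields, no streaming, no shared code with the engine paths
# they check.

oracle_read_lines <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else readLines(path)
}

oracle_split <- function(line, delim) {
  if (delim == ",") {
    # base read.csv as the independent CSV dialect authority
    unname(unlist(utils::read.csv(text = line, header = FALSE,
                                  colClasses = "character")))
  } else {
    out <- strsplit(paste0(line, "\x7f"), delim, fixed = TRUE)[[1]]
    out[length(out)] <- sub("\x7f$", "", out[length(out)])
    out
  }
}

oracle_table <- function(path) {
  lines <- oracle_read_lines(path)
  stripped <- sub("\\.gz$", "", path)
  delim <- if (grepl("\\.csv$", stripped)) "," else "\t"
  if (grepl("\\.vcf$", stripped)) {
    h <- which(startsWith(lines, "#CHROM"))[1]
    header <- oracle_split(sub("^#", "", lines[h]), delim)
    data <- if (h < length(lines)) lines[(h + 1):length(lines)] else character(0)
    data <- data[!startsWith(data, "#")]
  } else {
    body <- if (grepl("\\.maf$", stripped)) lines[!startsWith(lines, "#")] else lines
    body <- body[nzchar(trimws(body))]
    header <- oracle_split(body[1], delim)
    data <- if (length(body) > 1) body[-1] else character(0)
  }
  data <- data[nzchar(trimws(data))]
  list(header = make.unique(trimws(header), sep = "."),
       rows = lapply(data, oracle_split, delim = delim))
}

# literal restatement of the classification rule list
oracle_classify <- function(ref, alt) {
  r <- toupper(trimws(ref)); a <- toupper(trimws(alt))
  re <- r %in% c("", "-"); ae <- a %in% c("", "-")
  if (re && ae) return("UNKNOWN")
  if (re) return("INS")
  if (ae) return("DEL")
  if (!grepl("^[ACGTN]+$", r) || !grepl("^[ACGTN]+$", a)) return("UNKNOWN")
  if (r == a) return("UNKNOWN")
  if (nchar(r) == nchar(a)) {
    if (nchar(r) == 1) return("SNV") else return("MNV")
  }
  if (nchar(r) < nchar(a)) "INS" else "DEL"
}

oracle_find <- function(aliases, header, row) {
  hn <- tolower(trimws(header))
  for (al in aliases) {
    i <- which(hn == tolower(trimws(al)))
    if (length(i) && i[1] <= length(row)) return(row[i[1]])
  }
  NULL
}

# whole-file record-by-record parse: loops every field of every row
oracle_parse <- function(path, schema) {
  tab <- oracle_table(path)
  abs <- normalizePath(path, winslash = "/", mustWork = FALSE)
  fname <- basename(abs)
  dname <- basename(dirname(abs))
  sent <- schema$missing_sentinel
  defs <- schema$field_defs
  names(defs) <- tolower(trimws(vapply(defs, `[[`, character(1), "name")))

  records <- list()
  for (row in tab$rows) {
    if (length(row) != length(tab$header)) next  # ragged: skipped by policy
    rec <- character(0)
    for (col in schema$columns) {
      fd <- defs[[tolower(trimws(col))]]
      v <- if (is.null(fd)) {
        oracle_find(col, tab$header, row)
      } else if (fd$kind == "static") {
        fd$value
      } else if (fd$kind == "internal") {
        oracle_find(fd$aliases, tab$header, row)
      } else if (fd$kind == "filename") {
        m <- regmatches(fname, regexec(fd$regex, fname, perl = TRUE))[[1]]
        if (length(m) >= 2) m[2] else NULL
      } else if (fd$kind == "dirname") {
        m <- regmatches(dname, regexec(fd$regex, dname, perl = TRUE))[[1]]
        if (length(m) >= 2) m[2] else NULL
      } else if (fd$kind == "mapping") {
        key <- oracle_find(fd$aliases, tab$header, row)
        if (is.null(key) || !(key %in% names(fd$mapping))) NULL
        else unname(fd$mapping[[key]])
      } else if (fd$kind == "plugin" && fd$plugin == "alteration_type") {
        ref <- rec[["REF"]] %||% oracle_find(c("REF", "Reference_Allele"),
                                             tab$header, row)
        alt <- rec[["ALT"]] %||% oracle_find(c("ALT", "Tumor_Seq_Allele2"),
                                             tab$header, row)
        if (is.null(ref) || is.null(alt)) NULL else oracle_classify(ref, alt)
      } else NULL
      rec[[col]] <- v %||% sent
    }
    drop <- FALSE
    for (e in schema$exclusions) {
      if (identical(rec[[e$field]], e$value)) drop <- TRUE
    }
    if (!drop) records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) {
    return(as.data.frame(setNames(rep(list(character(0)),
                                      length(schema$columns)),
                                  schema$columns),
                         check.names = FALSE, optional = TRUE))
  }
  df <- as.data.frame(do.call(rbind, records), stringsAsFactors = FALSE,
                      check.names = FALSE, optional = TRUE)
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_where_keep <- function(df, field, op, literal) {
  vals <- df[[field]]
  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    v <- vals[i]
    vn <- suppressWarnings(as.numeric(v))
    ln <- suppressWarnings(as.numeric(literal))
    num <- !is.na(vn) && !is.na(ln)
    keep[i] <- switch(op,
      "==" = if (num) vn == ln else v == literal,
      "!=" = if (num) vn != ln else v != literal,
      "<"  = num && vn < ln,
      "<=" = num && vn <= ln,
      ">"  = num && vn > ln,
      ">=" = num && vn >= ln)
  }
  keep
}
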