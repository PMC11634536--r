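#' Detect the reading dialect of a variant file from its name
#'
#' The dialect is chosen by extension after stripping one optional `.gz`:
#' `.csv` (comma), `.tsv`/`.txt` (tab), `.maf` (tab, `#` pragma lines),
#' `.vcf` (tab, `##` meta lines, header at the `#CHROM` line). Anything else
#' is an unsupported-format error.
#'
#' @param path File path (the file need not exist; only the name is used).
#' @return A `vc_dialect`: format tag, delimiter, comment prefixes, header
#'   rule, and whether the file is gzip-compressed.
#' @export
#' @examples
#' detect_dialect("cohortA/muts.maf.gz")$format_tag
detect_dialect <- function(path) {
  name <- basename(path)
  gz <- grepl("\\.gz$", name, ignore.case = TRUE)
  if (gz) name <- sub("\\.gz$", "", name, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(name))
  d <- switch(ext,
    csv = list(format_tag = "CSV", delimiter = ",",
               comment_prefixes = character(0), header_rule = "first"),
    tsv = ,
    txt = list(format_tag = "TSV", delimiter = "\t",
               comment_prefixes = character(0), header_rule = "first"),
    maf = list(format_tag = "MAF", delimiter = "\t",
               comment_prefixes = "#", header_rule = "first"),
    vcf = list(format_tag = "VCF", delimiter = "\t",
               comment_prefixes = "##", header_rule = "#CHROM"),
    vc_abort(sprintf("unsupported input format: %s", path),
             "varcat_format_error")
  )
  d$gzip <- gz
  structure(d, class = "vc_dialect")
}

# no encoding= on the connection: declaring UTF-8 makes readLines truncate
# invalid lines silently; bytes pass through and check_utf8 validates them
open_text <- function(path, dialect) {
  if (dialect$gzip) gzfile(path, open = "rt")
  else file(path, open = "rt")
}

is_comment_line <- function(lines, dialect) {
  hit <- rep(FALSE, length(lines))
  for (p in dialect$comment_prefixes) hit <- hit | startsWith(lines, p)
  if (dialect$format_tag == "VCF") {
    # everything '#'-prefixed except the #CHROM header is meta
    hit <- hit | (startsWith(lines, "#") & !startsWith(lines, "#CHROM"))
  }
  hit
}

check_utf8 <- function(lines, path, first_line_no, lenient = FALSE) {
  ok <- validUTF8(lines)
  if (all(ok)) return(lines)
  if (!lenient) {
    vc_abort(sprintf("undecodable bytes in %s at line %d",
                     path, first_line_no + which(!ok)[1] - 1L),
             "varcat_parse_error")
  }
  lines[!ok] <- iconv(lines[!ok], "UTF-8", "UTF-8", sub = "?")
  lines
}

#' Read the header (column names) of a variant file
#'
#' Comment lines are skipped per dialect; for VCF the header is the line
#' starting `#CHROM` with the leading `#` stripped. Names are trimmed and
#' duplicates receive positional suffixes (`NAME`, `NAME.1`, ...).
#'
#' @param path File path.
#' @param dialect A `vc_dialect`; detected from `path` when omitted.
#' @return Ordered character vector of column names.
#' @export
read_header <- function(path, dialect = detect_dialect(path)) {
  con <- open_text(path, dialect)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) {
      vc_abort(sprintf("no header found in %s", path), "varcat_parse_error")
    }
    if (!nzchar(trimws(line)) || is_comment_line(line, dialect)) next
    if (dialect$header_rule == "#CHROM" && !startsWith(line, "#CHROM")) {
      vc_abort(sprintf("no #CHROM header found in %s", path),
               "varcat_parse_error")
    }
    break
  }
  line <- check_utf8(line, path, 1L)
  if (dialect$header_rule == "#CHROM") line <- sub("^#", "", line)
  fields <- split_line(line, dialect)
  make.unique(trimws(fields), sep = ".")
}

# split one physical/logical line into fields; CSV honours RFC 4180 quoting
split_line <- function(line, dialect) {
  if (dialect$delimiter == ",") {
    scan(text = line, what = "character", sep = ",", quote = "\"",
         quiet = TRUE, na.strings = character(0), strip.white = FALSE,
         blank.lines.skip = FALSE, multi.line = FALSE)
  } else {
    split_tab(line)[[1]]
  }
}

# strsplit drops trailing empty fields; pad with a sentinel to keep them
split_tab <- function(lines) {
  parts <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  lapply(parts, function(p) {
    n <- length(p)
    last <- p[n]
    p[n] <- substr(last, 1L, nchar(last) - 1L)
    p
  })
}

split_csv_many <- function(lines) {
  plain <- !grepl('"', lines, fixed = TRUE)
  out <- vector("list", length(lines))
  if (any(plain)) {
    simple <- strsplit(paste0(lines[plain], "\x01"), ",", fixed = TRUE)
    out[plain] <- lapply(simple, function(p) {
      n <- length(p)
      p[n] <- substr(p[n], 1L, nchar(p[n]) - 1L)
      p
    })
  }
  for (i in which(!plain)) {
    out[[i]] <- scan(text = lines[i], what = "character", sep = ",",
                     quote = "\"", quiet = TRUE, na.strings = character(0),
                     strip.white = FALSE, blank.lines.skip = FALSE,
                     multi.line = FALSE)
  }
  out
}

#' Open a streaming row reader over a variant file
#'
#' Returns a reader that yields batches of data rows (everything after the
#' header that is neither blank nor a comment line), split on the dialect
#' delimiter, in constant memory. Quoted CSV fields may span physical lines;
#' such continuations are joined before splitting. Row numbers are 1-based
#' over data rows.
#'
#' @param path File path.
#' @param dialect A `vc_dialect`; detected from `path` when omitted.
#' @param chunk_size Number of physical lines read per batch.
#' @param lenient_encoding Replace undecodable bytes instead of erroring.
#' @return A list with `header` (character vector), `next_batch()` (returns
#'   `NULL` at end of file, else `list(values = <list of character vectors>,
#'   row_numbers = <integer>)`), and `close()`.
#' @export
row_stream <- function(path, dialect = detect_dialect(path),
                       chunk_size = 4096L, lenient_encoding = FALSE) {
  header <- read_header(path, dialect)
  con <- open_text(path, dialect)
  # skip everything up to and including the header line
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) break
    if (!nzchar(trimws(line)) || is_comment_line(line, dialect)) next
    break
  }
  row_no <- 0L
  carry <- character(0)   # unfinished quoted CSV record
  done <- FALSE
  phys_line <- 0L

  next_batch <- function() {
    if (done) return(NULL)
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines) && !length(carry)) { done <<- TRUE; return(NULL) }
    if (!length(lines)) done <<- TRUE
    lines <- check_utf8(lines, path, phys_line + 1L, lenient_encoding)
    phys_line <<- phys_line + length(lines)

    if (dialect$delimiter == ",") {
      # join physical lines while an odd number of quotes leaves a field open
      if (length(carry)) { lines <- c(carry, lines); carry <<- character(0) }
      nq <- nchar(lines) - nchar(gsub('"', "", lines, fixed = TRUE))
      open <- cumsum(nq) %% 2L == 1L
      if (length(lines) && open[length(lines)]) {
        if (!done) {
          # hold the trailing incomplete record for the next batch
          closed <- which(!open)
          start <- if (length(closed)) max(closed) + 1L else 1L
          carry <<- paste(lines[start:length(lines)], collapse = "\n")
          lines <- if (start > 1L) lines[seq_len(start - 1L)] else character(0)
          nq <- nq[seq_along(lines)]
          open <- if (length(lines)) cumsum(nq) %% 2L == 1L else logical(0)
        }
        # at EOF an unterminated quote is parsed as-is (scan closes it)
      }
      if (length(lines)) {
        grp <- cumsum(c(TRUE, !open[-length(open)]))
        logical_lines <- vapply(split(lines, grp), paste,
                                character(1), collapse = "\n")
        names(logical_lines) <- NULL
      } else logical_lines <- character(0)
      keep <- nzchar(trimws(logical_lines))
      logical_lines <- logical_lines[keep]
      if (!length(logical_lines)) return(list(values = list(),
                                              row_numbers = integer(0)))
      values <- split_csv_many(logical_lines)
    } else {
      keep <- nzchar(trimws(lines)) & !is_comment_line(lines, dialect)
      lines <- lines[keep]
      if (!length(lines)) return(list(values = list(),
                                      row_numbers = integer(0)))
      values <- split_tab(lines)
    }
    rn <- row_no + seq_along(values)
    row_no <<- row_no + length(values)
    list(values = values, row_numbers = rn)
  }

  list(
    header = header,
    next_batch = next_batch,
    close = function() try(close(con), silent = TRUE)
  )
}

#' Read all data rows of a variant file
#'
#' Convenience wrapper around [row_stream()] that materialises every row.
#' Intended for inspection and testing; the parsing tasks stream instead.
#'
#' @inheritParams row_stream
#' @return A list with `header` and `rows`, where `rows` is a list of
#'   `list(values =, row_number =)` in source order.
#' @export
iter_rows <- function(path, dialect = detect_dialect(path)) {
  st <- row_stream(path, dialect)
  on.exit(st$close())
  rows <- list()
  repeat {
    b <- st$next_batch()
    if (is.null(b)) break
    if (!length(b$values)) next
    rows <- c(rows, Map(function(v, n) list(values = v, row_number = n),
                        b$values, b$row_numbers))
  }
  list(header = st$header, rows = rows)
}
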