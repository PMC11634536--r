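#' Build a parsing context for one input row
#'
#' The context is the per-row state handed to field resolution and to
#' plugins: where the row came from (source path, file name, immediate
#' parent directory name), the input header, the raw split values, the
#' 1-based data-row number, the part of the output record resolved so far,
#' and the field definition currently being resolved.
#'
#' @param source_path Path of the file being parsed.
#' @param header Character vector of input column names.
#' @param values Character vector of the row's raw values.
#' @param row_number 1-based index among data rows.
#' @param record Named character vector of already-resolved output fields
#'   (earlier columns only; read-only for plugins).
#' @param schema The governing `vc_annotation`, or `NULL`.
#' @param schema_field The `vc_field_def` being resolved, or `NULL`.
#' @return A `vc_context` list.
#' @export
new_context <- function(source_path, header, values, row_number,
                        record = character(0), schema = NULL,
                        schema_field = NULL) {
  abs <- normalizePath(source_path, winslash = "/", mustWork = FALSE)
  structure(list(
    source_path = source_path,
    file_name = basename(abs),
    dir_name = basename(dirname(abs)),
    header = header,
    header_norm = norm_name(header),
    raw_row = list(values = values, row_number = row_number),
    record = record,
    schema = schema,
    schema_field = schema_field,
    sentinel = if (is.null(schema)) "" else schema$missing_sentinel
  ), class = "vc_context")
}

# first alias present in the header, in alias order; NA if none
alias_index <- function(aliases, header_norm) {
  idx <- match(norm_name(aliases), header_norm)
  idx <- idx[!is.na(idx)]
  if (length(idx)) idx[1] else NA_integer_
}

regex_capture <- function(regex, text) {
  m <- regexec(regex, text, perl = TRUE)
  r <- regmatches(text, m)[[1]]
  if (length(r) < 2L) NA_character_ else r[2]
}

#' Resolve a single field definition against a context
#'
#' Applies one rule to one row: the reference semantics of the engine
#' (the streaming parser vectorises the same rules per file). Unresolvable
#' optional fields yield the schema sentinel; unresolvable required fields
#' raise an error carrying provenance.
#'
#' @param defn A [field_def()].
#' @param ctx A [new_context()] populated for the current row.
#' @param plugins Plugin registry, used for `plugin` fields.
#' @return A single string.
#' @export
resolve_field <- function(defn, ctx, plugins = plugin_registry()) {
  ctx$schema_field <- defn
  unresolved <- function(why) {
    if (isTRUE(defn$required)) {
      vc_abort(sprintf("required field '%s' unresolvable in %s (row %s): %s",
                       defn$name, ctx$source_path,
                       ctx$raw_row$row_number %||% "?", why),
               "varcat_parse_error")
    }
    ctx$sentinel
  }
  switch(defn$kind,
    static = defn$value,
    internal = {
      i <- alias_index(defn$aliases, ctx$header_norm)
      if (is.na(i) || i > length(ctx$raw_row$values)) {
        unresolved("no alias present in header")
      } else ctx$raw_row$values[i]
    },
    filename = {
      v <- regex_capture(defn$regex, ctx$file_name)
      if (is.na(v)) unresolved(sprintf("regex did not match file name '%s'",
                                       ctx$file_name)) else v
    },
    dirname = {
      v <- regex_capture(defn$regex, ctx$dir_name)
      if (is.na(v)) unresolved(sprintf("regex did not match directory name '%s'",
                                       ctx$dir_name)) else v
    },
    mapping = {
      i <- alias_index(defn$aliases, ctx$header_norm)
      if (is.na(i) || i > length(ctx$raw_row$values)) {
        return(unresolved("no alias present in header"))
      }
      key <- ctx$raw_row$values[i]
      if (!(key %in% names(defn$mapping))) {
        unresolved(sprintf("key '%s' absent from mapping table", key))
      } else unname(defn$mapping[[key]])
    },
    plugin = {
      p <- plugins[[defn$plugin]]
      if (is.null(p)) {
        vc_abort(sprintf("field '%s': no plugin named '%s' is registered",
                         defn$name, defn$plugin), "varcat_plugin_error")
      }
      v <- tryCatch(p$process(ctx), error = function(e) e)
      if (inherits(v, "error")) {
        unresolved(sprintf("plugin '%s' failed: %s",
                           defn$plugin, conditionMessage(v)))
      } else if (is.null(v) || is.na(v)) {
        unresolved(sprintf("plugin '%s' returned no value", defn$plugin))
      } else as.character(v)[1]
    }
  )
}

#' Row-drop decision for a resolved record
#'
#' A record is dropped iff any of the schema's `exclude_rows` rules matches
#' exactly (string equality on the named field).
#'
#' @param record Named character vector (one ParsedRecord).
#' @param schema A `vc_annotation`.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
apply_exclusions <- function(record, schema) {
  for (e in schema$exclusions) {
    i <- match(norm_name(e$field), norm_name(names(record)))
    if (!is.na(i) && record[[i]] == e$value) return(FALSE)
  }
  TRUE
}

#' Parse one variant file under an annotation schema
#'
#' The core transformation: streams the file's data rows and resolves every
#' output column per the schema — field definitions where present,
#' pass-through from the input header otherwise, the sentinel when neither
#' applies. Fields are resolved in schema column order, so a plugin may read
#' any earlier column of the record in progress. Row-exclusion rules are
#' applied after resolution.
#'
#' Rows whose field count differs from the header ("ragged" rows) are a hard
#' error with provenance by default; `skip_bad_rows = TRUE` demotes them to
#' a counted skip (reported in the `skipped` attribute).
#'
#' @param path Input file path (CSV/TSV/MAF/VCF, optionally gzipped).
#' @param schema A `vc_annotation`.
#' @param plugins Plugin registry (see [plugin_registry()]).
#' @param skip_bad_rows Skip-and-count ragged rows instead of erroring.
#' @param lenient_encoding Replace undecodable bytes instead of erroring.
#' @param chunk_size Lines per streamed batch.
#' @return A `data.frame` of character columns, one per schema column in
#'   schema order, one row per kept record, with attributes `provenance`
#'   (a data.frame of `source`, `row`) and `skipped` (ragged rows dropped).
#' @export
parse_file <- function(path, schema, plugins = plugin_registry(),
                       skip_bad_rows = FALSE, lenient_encoding = FALSE,
                       chunk_size = 4096L) {
  stopifnot(inherits(schema, "vc_annotation"))
  dialect <- detect_dialect(path)
  st <- row_stream(path, dialect, chunk_size = chunk_size,
                   lenient_encoding = lenient_encoding)
  on.exit(st$close())
  header <- st$header
  hnorm <- norm_name(header)
  ncol_in <- length(header)

  abs <- normalizePath(path, winslash = "/", mustWork = FALSE)
  file_name <- basename(abs)
  dir_name <- basename(dirname(abs))

  out_cols <- schema$columns
  def_at <- lapply(norm_name(out_cols), function(nm) {
    for (fd in schema$field_defs) if (norm_name(fd$name) == nm) return(fd)
    NULL
  })

  # per-file constants: filename/dirname captures and column indices
  plan <- vector("list", length(out_cols))
  for (j in seq_along(out_cols)) {
    fd <- def_at[[j]]
    if (is.null(fd)) {
      plan[[j]] <- list(mode = "passthrough",
                        idx = match(norm_name(out_cols[j]), hnorm))
    } else if (fd$kind == "static") {
      plan[[j]] <- list(mode = "const", value = fd$value)
    } else if (fd$kind %in% c("filename", "dirname")) {
      subject <- if (fd$kind == "filename") file_name else dir_name
      v <- regex_capture(fd$regex, subject)
      if (is.na(v)) {
        if (isTRUE(fd$required)) {
          vc_abort(sprintf(
            "required field '%s': regex '%s' did not match %s name '%s' (%s)",
            fd$name, fd$regex, fd$kind, subject, path),
            "varcat_parse_error")
        }
        v <- schema$missing_sentinel
      }
      plan[[j]] <- list(mode = "const", value = v)
    } else if (fd$kind %in% c("internal", "mapping")) {
      plan[[j]] <- list(mode = fd$kind, fd = fd,
                        idx = alias_index(fd$aliases, hnorm))
    } else {
      plan[[j]] <- list(mode = "plugin", fd = fd)
    }
  }

  chunks <- list()
  prov_rows <- list()
  skipped <- 0L

  repeat {
    b <- st$next_batch()
    if (is.null(b)) break
    if (!length(b$values)) next
    lens <- lengths(b$values)
    ragged <- lens != ncol_in
    if (any(ragged)) {
      if (!skip_bad_rows) {
        i <- which(ragged)[1]
        vc_abort(sprintf(
          "%s row %d: %d field(s) but header has %d (use skip_bad_rows to drop)",
          path, b$row_numbers[i], lens[i], ncol_in),
          "varcat_parse_error")
      }
      skipped <- skipped + sum(ragged)
      b$values <- b$values[!ragged]
      b$row_numbers <- b$row_numbers[!ragged]
      if (!length(b$values)) next
    }
    n <- length(b$values)
    m <- matrix(unlist(b$values, use.names = FALSE), nrow = ncol_in)

    rec <- vector("list", length(out_cols))
    names(rec) <- out_cols
    for (j in seq_along(out_cols)) {
      p <- plan[[j]]
      col <- switch(p$mode,
        const = rep(p$value, n),
        passthrough = {
          if (is.na(p$idx)) rep(schema$missing_sentinel, n) else m[p$idx, ]
        },
        internal = {
          fd <- p$fd
          if (is.na(p$idx)) {
            if (isTRUE(fd$required)) {
              vc_abort(sprintf(
                "required field '%s': no alias of %s present in header of %s",
                fd$name, paste0("'", fd$aliases, "'", collapse = ", "), path),
                "varcat_parse_error")
            }
            rep(schema$missing_sentinel, n)
          } else m[p$idx, ]
        },
        mapping = {
          fd <- p$fd
          if (is.na(p$idx)) {
            if (isTRUE(fd$required)) {
              vc_abort(sprintf(
                "required field '%s': no alias of %s present in header of %s",
                fd$name, paste0("'", fd$aliases, "'", collapse = ", "), path),
                "varcat_parse_error")
            }
            rep(schema$missing_sentinel, n)
          } else {
            keys <- m[p$idx, ]
            vals <- unname(fd$mapping[keys])
            miss <- is.na(vals) & !(keys %in% names(fd$mapping))
            if (any(miss) && isTRUE(fd$required)) {
              i <- which(miss)[1]
              vc_abort(sprintf(
                "required field '%s': key '%s' absent from mapping table (%s row %d)",
                fd$name, keys[i], path, b$row_numbers[i]),
                "varcat_parse_error")
            }
            vals[miss] <- schema$missing_sentinel
            vals
          }
        },
        plugin = {
          fd <- p$fd
          vapply(seq_len(n), function(i) {
            partial <- vapply(rec[seq_len(j - 1L)], `[`, character(1), i)
            ctx <- new_context(path, header, m[, i], b$row_numbers[i],
                               record = partial, schema = schema,
                               schema_field = fd)
            resolve_field(fd, ctx, plugins)
          }, character(1))
        }
      )
      rec[[j]] <- col
    }

    keep <- rep(TRUE, n)
    for (e in schema$exclusions) {
      ei <- match(norm_name(e$field), norm_name(out_cols))
      if (!is.na(ei)) keep <- keep & rec[[ei]] != e$value
    }
    if (!all(keep)) {
      rec <- lapply(rec, `[`, keep)
      b$row_numbers <- b$row_numbers[keep]
    }
    if (length(b$row_numbers)) {
      chunks[[length(chunks) + 1L]] <-
        as.data.frame(rec, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
      prov_rows[[length(prov_rows) + 1L]] <- b$row_numbers
    }
  }

  out <- if (length(chunks) == 1L) chunks[[1]] else if (length(chunks)) {
    do.call(rbind, chunks)
  } else {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(out_cols)), out_cols),
      check.names = FALSE, optional = TRUE)
    df
  }
  rownames(out) <- NULL
  rows <- if (length(prov_rows)) unlist(prov_rows, use.names = FALSE) else integer(0)
  attr(out, "provenance") <- data.frame(source = rep(path, length(rows)),
                                        row = rows,
                                        stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
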