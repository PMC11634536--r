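#' Field definitions: one rule for producing one output column
#'
#' A field definition states how a single output column obtains its value.
#' Six kinds are supported:
#' \describe{
#'   \item{static}{a literal value, identical on every row (e.g. a dataset
#'     label injected as cohort metadata).}
#'   \item{internal}{the value of the first input column, among an ordered
#'     list of header aliases, present in the file being parsed. Alias
#'     matching is case-insensitive after trimming whitespace.}
#'   \item{filename}{a regex with exactly one capture group applied to the
#'     input file's name.}
#'   \item{dirname}{the same, applied to the name of the input file's
#'     immediate parent directory.}
#'   \item{mapping}{the value of an aliased input column translated through a
#'     two-column lookup table (see [load_mapping_table()]).}
#'   \item{plugin}{the return value of a registered per-record plugin (see
#'     [plugin_registry()]).}
#' }
#'
#' A `required` field that cannot be resolved aborts the file with an error
#' carrying provenance; an optional one (the default) yields the schema's
#' missing-value sentinel.
#'
#' @param name Output column name.
#' @param kind One of `"static"`, `"internal"`, `"filename"`, `"dirname"`,
#'   `"mapping"`, `"plugin"`.
#' @param value Literal value (`static` only).
#' @param aliases Ordered character vector of input header names to try
#'   (`internal` and `mapping`).
#' @param regex Extraction pattern with exactly one capture group
#'   (`filename` and `dirname`).
#' @param mapping_file Path to the lookup table, resolved relative to the
#'   annotation file (`mapping` only).
#' @param key_column,value_column Column names inside the mapping table.
#' @param plugin Registered plugin identifier (`plugin` only).
#' @param required If `TRUE`, an unresolvable value is an error instead of
#'   the sentinel.
#' @return A `vc_field_def` object.
#' @export
#' @examples
#' field_def("DATASET", "static", value = "cohortA")
#' field_def("CHROM", "internal", aliases = c("Chromosome", "CHROM", "chr"))
field_def <- function(name, kind,
                      value = NULL, aliases = NULL, regex = NULL,
                      mapping_file = NULL, key_column = NULL,
                      value_column = NULL, plugin = NULL,
                      required = FALSE) {
  kinds <- c("static", "internal", "filename", "dirname", "mapping", "plugin")
  if (!is_string(name) || !nzchar(trimws(name))) {
    vc_abort("field definition needs a non-empty 'name'", "varcat_schema_error")
  }
  if (!is_string(kind) || !(kind %in% kinds)) {
    vc_abort(sprintf("field '%s': unknown kind '%s' (expected one of %s)",
                     name, as.character(kind)[1],
                     paste(kinds, collapse = ", ")),
             "varcat_schema_error")
  }
  bad <- function(what) {
    vc_abort(sprintf("field '%s' (kind %s): %s", name, kind, what),
             "varcat_schema_error")
  }
  # exactly the slots relevant to the kind may be set
  given <- c(value = !is.null(value), aliases = !is.null(aliases),
             regex = !is.null(regex), mapping_file = !is.null(mapping_file),
             plugin = !is.null(plugin))
  need <- switch(kind,
    static   = "value",
    internal = "aliases",
    filename = "regex",
    dirname  = "regex",
    mapping  = c("aliases", "mapping_file"),
    plugin   = "plugin")
  extra <- setdiff(names(given)[given], need)
  miss <- setdiff(need, names(given)[given])
  if (length(extra)) bad(paste0("unexpected key(s): ", paste(extra, collapse = ", ")))
  if (length(miss)) bad(paste0("missing key(s): ", paste(miss, collapse = ", ")))

  if (!is.null(value)) value <- as.character(value)[1]
  if (!is.null(aliases)) {
    aliases <- as_chr(aliases)
    if (!length(aliases)) bad("'aliases' must be non-empty")
  }
  if (!is.null(regex)) {
    if (!is_string(regex)) bad("'regex' must be a single string")
    ok <- tryCatch({ regexpr(regex, "x", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) bad(sprintf("regex '%s' does not compile", regex))
    if (capture_group_count(regex) != 1L) {
      bad(sprintf("regex '%s' must contain exactly one capture group", regex))
    }
  }
  if (kind == "mapping") {
    if (!is_string(mapping_file)) bad("'mapping_file' must be a single path")
    if (is.null(key_column) || is.null(value_column)) {
      bad("'key_column' and 'value_column' are required")
    }
  }
  if (!is.null(plugin) && !is_string(plugin)) bad("'plugin' must be a single name")

  structure(list(
    name = name, kind = kind, value = value, aliases = aliases,
    regex = regex, mapping_file = mapping_file,
    key_column = key_column, value_column = value_column,
    plugin = plugin, required = isTRUE(required),
    mapping = NULL  # filled at load time (fail-fast resolution)
  ), class = "vc_field_def")
}

# number of (non-escaped, non-shy) capture groups in a perl regex
capture_group_count <- function(regex) {
  stripped <- gsub("\\\\.", "", regex)           # drop escaped chars
  opens <- gregexpr("\\((?!\\?)", stripped, perl = TRUE)[[1]]
  if (opens[1] == -1L) 0L else length(opens)
}

#' Construct an annotation schema programmatically
#'
#' An annotation schema is the declarative rule set that governs parsing:
#' which input files to read (`patterns`), the ordered output columns, how
#' each column's value is obtained (field definitions or pass-through from
#' the input header), which rows to drop, and the output format. Most users
#' load schemas from YAML annotation files via [load_annotation()]; this
#' constructor serves programmatic use and testing.
#'
#' Output columns not covered by a field definition are pass-through: they
#' are filled from the input column of the same name (matched
#' case-insensitively after trimming) and fall back to `missing_sentinel`
#' when the input lacks that column.
#'
#' @param patterns Non-empty character vector of file-name glob patterns.
#' @param columns Ordered character vector of output column names.
#' @param field_defs List of [field_def()] objects; their names must appear
#'   in `columns`.
#' @param excluded_columns Input columns that must never pass through; may
#'   not overlap `columns`.
#' @param exclusions List of `list(field =, value =)` pairs: a record whose
#'   `field` equals `value` (exact string equality) is dropped.
#' @param recursive Should the schema govern files in subdirectories of its
#'   own directory during discovery?
#' @param output_format `"TSV"` or `"CSV"`.
#' @param missing_sentinel String emitted for unresolvable optional fields.
#' @param source_path Path of the annotation file itself (`NA` for
#'   programmatic schemas).
#' @return A validated `vc_annotation` object.
#' @seealso [load_annotation()], [serialize_annotation()]
#' @export
annotation_schema <- function(patterns, columns, field_defs = list(),
                              excluded_columns = character(0),
                              exclusions = list(),
                              recursive = TRUE,
                              output_format = c("TSV", "CSV"),
                              missing_sentinel = "",
                              source_path = NA_character_) {
  where <- if (is.na(source_path)) "annotation" else source_path
  patterns <- as_chr(patterns)
  if (!length(patterns)) {
    vc_abort(sprintf("'pattern' must list at least one glob in %s", where),
             "varcat_schema_error")
  }
  columns <- as_chr(columns)
  if (!length(columns)) {
    vc_abort(sprintf("'columns' must be non-empty in %s", where),
             "varcat_schema_error")
  }
  output_format <- toupper(match.arg(tolower(output_format), c("tsv", "csv")))
  if (!is_string(missing_sentinel)) {
    vc_abort(sprintf("'missing_value' must be a single string in %s", where),
             "varcat_schema_error")
  }
  excluded_columns <- as_chr(excluded_columns)

  dup <- unique(columns[duplicated(norm_name(columns))])
  if (length(dup)) {
    vc_abort(sprintf("duplicate output column(s) %s in %s",
                     paste0("'", dup, "'", collapse = ", "), where),
             "varcat_schema_error")
  }
  both <- intersect(norm_name(columns), norm_name(excluded_columns))
  if (length(both)) {
    vc_abort(sprintf("column(s) %s appear in both 'columns' and 'exclude_columns' in %s",
                     paste0("'", both, "'", collapse = ", "), where),
             "varcat_schema_error")
  }

  for (fd in field_defs) {
    if (!inherits(fd, "vc_field_def")) {
      vc_abort(sprintf("'annotation' entries must be field definitions in %s", where),
               "varcat_schema_error")
    }
  }
  def_names <- vapply(field_defs, `[[`, character(1), "name")
  dup <- unique(def_names[duplicated(norm_name(def_names))])
  if (length(dup)) {
    vc_abort(sprintf("field '%s' is defined more than once in %s", dup[1], where),
             "varcat_schema_error")
  }
  orphan <- setdiff(norm_name(def_names), norm_name(columns))
  if (length(orphan)) {
    vc_abort(sprintf("field definition(s) %s are not listed in 'columns' in %s",
                     paste0("'", def_names[norm_name(def_names) %in% orphan],
                            "'", collapse = ", "), where),
             "varcat_schema_error")
  }

  exclusions <- lapply(exclusions, function(e) {
    if (!is.list(e) || is.null(e$field) || is.null(e$value)) {
      vc_abort(sprintf("'exclude_rows' entries need 'field' and 'value' in %s", where),
               "varcat_schema_error")
    }
    list(field = as.character(e$field)[1], value = as.character(e$value)[1])
  })
  for (e in exclusions) {
    if (!(norm_name(e$field) %in% norm_name(columns))) {
      vc_abort(sprintf("'exclude_rows' names unknown field '%s' in %s",
                       e$field, where),
               "varcat_schema_error")
    }
  }

  structure(list(
    patterns = patterns,
    recursive = isTRUE(recursive),
    output_format = output_format,
    columns = columns,
    excluded_columns = excluded_columns,
    field_defs = field_defs,
    exclusions = exclusions,
    missing_sentinel = missing_sentinel,
    source_path = source_path
  ), class = "vc_annotation")
}

#' @export
print.vc_annotation <- function(x, ...) {
  cat("<varcat annotation schema>\n")
  cat("  source:  ", if (is.na(x$source_path)) "(programmatic)" else x$source_path, "\n")
  cat("  patterns:", paste(x$patterns, collapse = ", "), "\n")
  cat("  format:  ", x$output_format,
      if (x$recursive) "(recursive)" else "(non-recursive)", "\n")
  cat("  columns: ", paste(x$columns, collapse = ", "), "\n")
  kinds <- vapply(x$field_defs, `[[`, character(1), "kind")
  if (length(kinds)) {
    cat("  defs:    ", paste(sprintf("%s<%s>",
        vapply(x$field_defs, `[[`, character(1), "name"), kinds),
        collapse = ", "), "\n")
  }
  if (length(x$exclusions)) {
    cat("  drops:   ",
        paste(vapply(x$exclusions, function(e)
          sprintf("%s==%s", e$field, e$value), character(1)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Load and validate an annotation file
#'
#' Reads a YAML annotation document, validates it, applies defaults
#' (`recursive = TRUE`, `format = "TSV"`, `missing_value = ""`), resolves
#' every mapping table eagerly (a missing mapping file fails here, not at
#' parse time), and returns the schema.
#'
#' Recognised top-level keys: `pattern` (list of globs), `recursive`,
#' `format`, `columns`, `exclude_columns`, `exclude_rows` (list of
#' `{field, value}`), `missing_value`, and `annotation` (list of field
#' definitions keyed by `type`).
#'
#' @param path Path to a YAML annotation file.
#' @return A validated `vc_annotation` with `source_path` set.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "pattern: ['*.maf']",
#'   "columns: [CHROM, POS, REF, ALT, DATASET]",
#'   "annotation:",
#'   "  - type: static",
#'   "    name: DATASET",
#'   "    value: cohortA"), f)
#' sch <- load_annotation(f)
#' sch$columns
load_annotation <- function(path) {
  if (!file.exists(path)) {
    vc_abort(sprintf("annotation file not found: %s", path), "varcat_io_error")
  }
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    vc_abort(sprintf("malformed annotation %s: %s",
                                     path, conditionMessage(e)),
                             "varcat_schema_error")
                  })
  if (!is.list(doc)) {
    vc_abort(sprintf("annotation %s must be a YAML mapping", path),
             "varcat_schema_error")
  }
  known <- c("pattern", "recursive", "format", "columns", "exclude_columns",
             "exclude_rows", "missing_value", "annotation")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    vc_abort(sprintf("unknown key(s) %s in %s",
                     paste0("'", unknown, "'", collapse = ", "), path),
             "varcat_schema_error")
  }
  fmt <- doc[["format"]] %||% "TSV"
  if (!is_string(fmt) || !(toupper(fmt) %in% c("TSV", "CSV"))) {
    vc_abort(sprintf("'format' must be tsv or csv in %s", path),
             "varcat_schema_error")
  }

  defs <- lapply(doc[["annotation"]] %||% list(), function(d) {
    # [[ avoids $'s partial matching (e.g. d$value finding value_column)
    if (!is.list(d) || is.null(d[["type"]]) || is.null(d[["name"]])) {
      vc_abort(sprintf("'annotation' entries need 'type' and 'name' in %s", path),
               "varcat_schema_error")
    }
    field_def(
      name = as.character(d[["name"]]), kind = as.character(d[["type"]]),
      value = d[["value"]], aliases = d[["aliases"]], regex = d[["regex"]],
      mapping_file = d[["mapping_file"]], key_column = d[["key_column"]],
      value_column = d[["value_column"]], plugin = d[["plugin"]],
      required = as_flag(d[["required"]], FALSE, "required", path)
    )
  })

  sch <- annotation_schema(
    patterns = doc[["pattern"]],
    columns = doc[["columns"]],
    field_defs = defs,
    excluded_columns = doc[["exclude_columns"]] %||% character(0),
    exclusions = doc[["exclude_rows"]] %||% list(),
    recursive = as_flag(doc[["recursive"]], TRUE, "recursive", path),
    output_format = toupper(fmt),
    missing_sentinel = as.character(doc[["missing_value"]] %||% ""),
    source_path = normalizePath(path, winslash = "/")
  )
  resolve_mappings(sch)
}

# fail-fast: load every mapping table now, relative to the annotation file
resolve_mappings <- function(schema) {
  base_dir <- if (is.na(schema$source_path)) "." else dirname(schema$source_path)
  schema$field_defs <- lapply(schema$field_defs, function(fd) {
    if (fd$kind != "mapping" || !is.null(fd$mapping)) return(fd)
    mpath <- fd$mapping_file
    if (!file.exists(mpath)) mpath <- file.path(base_dir, fd$mapping_file)
    if (!file.exists(mpath)) {
      vc_abort(sprintf("field '%s': mapping file '%s' not found (annotation %s)",
                       fd$name, fd$mapping_file, schema$source_path),
               "varcat_schema_error")
    }
    fd$mapping <- load_mapping_table(mpath, fd$key_column, fd$value_column)
    fd
  })
  schema
}

#' Load a two-column mapping table
#'
#' Mapping tables translate source values during field resolution (e.g.
#' project codes to organ names). They are tab-delimited with a header row;
#' any columns beyond the two named ones are ignored.
#'
#' @param path Path to the TSV table.
#' @param key_column,value_column Header names of the key and value columns.
#' @return A named character vector: `lookup[key] -> value`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("code\torgan", "TCGA-OV\tOVARY", "TCGA-LUAD\tLUNG"), f)
#' load_mapping_table(f, "code", "organ")
load_mapping_table <- function(path, key_column, value_column) {
  if (!file.exists(path)) {
    vc_abort(sprintf("mapping table not found: %s", path), "varcat_io_error")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  for (cc in c(key_column, value_column)) {
    if (!(cc %in% names(tab))) {
      vc_abort(sprintf("mapping table %s lacks column '%s'", path, cc),
               "varcat_schema_error")
    }
  }
  if (nrow(tab) == 0L) {
    vc_abort(sprintf("mapping table %s is empty", path), "varcat_schema_error")
  }
  keys <- tab[[key_column]]
  dups <- unique(keys[duplicated(keys)])
  if (length(dups)) {
    vc_abort(sprintf("mapping table %s has duplicate key(s): %s",
                     path, paste0("'", dups, "'", collapse = ", ")),
             "varcat_schema_error")
  }
  stats::setNames(tab[[value_column]], keys)
}

#' Serialize an annotation schema back to YAML
#'
#' Emits a document that [load_annotation()] parses back to an equal schema
#' (load -> dump -> load is the identity on valid schemas).
#'
#' @param schema A `vc_annotation`.
#' @param path Optional file to write; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to `path`.
#' @export
serialize_annotation <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "vc_annotation"))
  txt <- yaml::as.yaml(schema_to_doc(schema))
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

# canonical document form; also the basis for structural equality
schema_to_doc <- function(schema) {
  doc <- list(
    pattern = as.list(schema$patterns),
    recursive = schema$recursive,
    format = tolower(schema$output_format),
    columns = as.list(schema$columns)
  )
  if (length(schema$excluded_columns)) {
    doc$exclude_columns <- as.list(schema$excluded_columns)
  }
  if (length(schema$exclusions)) {
    doc$exclude_rows <- lapply(schema$exclusions, function(e)
      list(field = e$field, value = e$value))
  }
  if (nzchar(schema$missing_sentinel)) {
    doc$missing_value <- schema$missing_sentinel
  }
  if (length(schema$field_defs)) {
    doc$annotation <- lapply(schema$field_defs, function(fd) {
      d <- list(type = fd$kind, name = fd$name)
      if (!is.null(fd$value)) d$value <- fd$value
      if (!is.null(fd$aliases)) d$aliases <- as.list(fd$aliases)
      if (!is.null(fd$regex)) d$regex <- fd$regex
      if (!is.null(fd$mapping_file)) {
        d$mapping_file <- fd$mapping_file
        d$key_column <- fd$key_column
        d$value_column <- fd$value_column
      }
      if (!is.null(fd$plugin)) d$plugin <- fd$plugin
      if (isTRUE(fd$required)) d$required <- TRUE
      d
    })
  }
  doc
}

#' Structural equality of two annotation schemas
#'
#' Compares the canonical document forms; `source_path` is ignored so a
#' schema equals its own load -> dump -> load round trip.
#'
#' @param a,b `vc_annotation` objects.
#' @return `TRUE` or `FALSE`.
#' @export
schemas_equal <- function(a, b) {
  identical(schema_to_doc(a), schema_to_doc(b))
}
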