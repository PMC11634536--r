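supported_input <- function(path) {
  tryCatch({ detect_dialect(path); TRUE },
           error = function(e) FALSE)
}

# annotation cache: path -> schema, or NA when the YAML is not an annotation
load_annotation_soft <- function(path, cache) {
  key <- path
  if (!is.null(cache[[key]])) return(cache[[key]])
  sch <- tryCatch(load_annotation(path), varcat_error = function(e) {
    vc_warn(sprintf("skipping %s during discovery: %s",
                    path, conditionMessage(e)))
    NA
  })
  cache[[key]] <- sch
  sch
}

#' Discover input files and their governing annotations
#'
#' Walks a directory tree, pairing every input file with the nearest
#' applicable annotation: annotation files are `*.yaml` documents, and the
#' closest ancestor directory (starting with the file's own) containing an
#' annotation whose `pattern` globs match the file name governs it. An
#' annotation with `recursive: false` only governs files in its own
#' directory. Two applicable annotations in the same directory are an error;
#' a directory holding supported input files that no annotation governs
#' produces a warning and those files are skipped. YAML files that do not
#' parse as annotations (e.g. manifests) are skipped with a warning when
#' encountered.
#'
#' @param root Directory to search.
#' @param name_filter Optional file-name filter: a glob when it contains
#'   glob metacharacters, otherwise a fixed substring.
#' @param annotation Optional path to an annotation file that overrides
#'   discovery: every file under `root` matching its patterns is paired
#'   with it.
#' @return A `data.frame` with columns `path` and `annotation`, in
#'   lexicographic path order, with the loaded schemas in the `schemas`
#'   attribute (a named list keyed by annotation path).
#' @export
find_files <- function(root, name_filter = NULL, annotation = NULL) {
  if (!dir.exists(root)) {
    vc_abort(sprintf("input directory not found: %s", root), "varcat_io_error")
  }
  all_files <- lex_sort(list.files(root, recursive = TRUE, full.names = TRUE))
  is_yaml <- grepl("\\.ya?ml$", all_files, ignore.case = TRUE)
  # only readable dialects participate; auxiliary files (mapping tables,
  # manifests) never trigger annotation lookups
  data_files <- all_files[!is_yaml]
  data_files <- data_files[vapply(data_files, supported_input, logical(1))]
  if (!is.null(name_filter)) {
    pat <- if (grepl("[*?[]", name_filter)) {
      utils::glob2rx(name_filter)
    } else NULL
    keep <- if (is.null(pat)) {
      grepl(name_filter, basename(data_files), fixed = TRUE)
    } else grepl(pat, basename(data_files))
    data_files <- data_files[keep]
  }

  schemas <- list()
  empty_result <- function() {
    res <- data.frame(path = character(0), annotation = character(0),
                      stringsAsFactors = FALSE)
    attr(res, "schemas") <- schemas
    res
  }

  if (!is.null(annotation)) {
    sch <- load_annotation(annotation)
    hit <- glob_match(basename(data_files), sch$patterns)
    files <- data_files[hit]
    if (!length(files)) return(empty_result())
    schemas[[annotation]] <- sch
    res <- data.frame(path = files,
                      annotation = rep(annotation, length(files)),
                      stringsAsFactors = FALSE)
    attr(res, "schemas") <- schemas
    return(res)
  }

  cache <- new.env(parent = emptyenv())
  root_norm <- normalizePath(root, winslash = "/")
  ann_by_dir <- split(all_files[is_yaml], dirname(all_files[is_yaml]))

  pair_one <- function(path) {
    d <- dirname(path)
    file_dir <- normalizePath(d, winslash = "/")
    repeat {
      anns <- ann_by_dir[[d]] %||% character(0)
      applicable <- character(0)
      for (a in anns) {
        sch <- load_annotation_soft(a, cache)
        if (!inherits(sch, "vc_annotation")) next
        here <- identical(normalizePath(d, winslash = "/"), file_dir)
        if (!here && !sch$recursive) next
        if (any(glob_match(basename(path), sch$patterns))) {
          applicable <- c(applicable, a)
        }
      }
      if (length(applicable) > 1L) {
        vc_abort(sprintf(
          "ambiguous annotations for %s: %s both apply in %s",
          path, paste(applicable, collapse = " and "), d),
          "varcat_schema_error")
      }
      if (length(applicable) == 1L) return(applicable)
      if (identical(normalizePath(d, winslash = "/"), root_norm)) {
        return(NA_character_)
      }
      parent <- dirname(d)
      if (identical(parent, d)) return(NA_character_)
      d <- parent
    }
  }

  ann_of <- vapply(data_files, pair_one, character(1), USE.NAMES = FALSE)
  unpaired <- data_files[is.na(ann_of) & vapply(data_files, supported_input,
                                                logical(1))]
  for (d in unique(dirname(unpaired))) {
    vc_warn(sprintf("no applicable annotation for input file(s) in %s; skipped", d))
  }
  keep <- !is.na(ann_of)
  files <- data_files[keep]
  anns <- ann_of[keep]
  for (a in unique(anns)) schemas[[a]] <- get(a, envir = cache)

  res <- data.frame(path = files, annotation = anns, stringsAsFactors = FALSE)
  attr(res, "schemas") <- schemas
  res
}

# one unified schema per run: differing column lists (or output formats)
# across the discovered annotations are a hard error
unified_schema <- function(pairs) {
  schemas <- attr(pairs, "schemas")
  used <- schemas[unique(pairs$annotation)]
  if (!length(used)) return(NULL)
  ref <- used[[1]]
  for (s in used[-1]) {
    if (!identical(s$columns, ref$columns) ||
        !identical(s$output_format, ref$output_format)) {
      vc_abort(sprintf(
        "column mismatch: annotations %s and %s define different outputs; one unified schema per run",
        ref$source_path, s$source_path), "varcat_schema_error")
    }
  }
  ref
}

# parse every (file, schema) pair — in parallel when workers > 1, one file
# per unit of work, results merged back in lexicographic path order so the
# worker count never changes any output byte
process_pairs <- function(pairs, where = NULL, workers = 1L,
                          skip_bad_rows = FALSE, lenient_where = FALSE,
                          plugins = plugin_registry()) {
  schemas <- attr(pairs, "schemas")
  where <- as_where(where)
  one <- function(i) {
    sch <- schemas[[pairs$annotation[i]]]
    df <- parse_file(pairs$path[i], sch, plugins = plugins,
                     skip_bad_rows = skip_bad_rows)
    misses <- 0L
    if (!is.null(where)) {
      wi <- match(norm_name(where$field), norm_name(names(df)))
      if (is.na(wi)) {
        vc_abort(sprintf("where clause names unknown field '%s'", where$field),
                 "varcat_where_error")
      }
      sel <- eval_where(where, df[[wi]], lenient = lenient_where,
                        provenance = attr(df, "provenance"))
      misses <- attr(sel, "lenient_misses") %||% 0L
      prov <- attr(df, "provenance")[as.logical(sel), , drop = FALSE]
      df <- df[as.logical(sel), , drop = FALSE]
      rownames(df) <- NULL
      attr(df, "provenance") <- prov
    }
    list(df = df, skipped = attr(df, "skipped") %||% 0L, misses = misses)
  }
  n <- nrow(pairs)
  idx <- seq_len(n)
  results <- if (workers > 1L && n > 1L &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, one)
  }
  for (r in results) {
    if (inherits(r, "try-error") || inherits(r, "error")) {
      vc_abort(conditionMessage(attr(r, "condition") %||%
                                  simpleCondition(as.character(r))),
               "varcat_parse_error")
    }
  }
  results
}

serialize_records <- function(df, format) {
  if (!nrow(df)) return(character(0))
  cols <- lapply(df, as.character)
  if (identical(format, "CSV")) {
    cols <- lapply(cols, csv_escape)
    do.call(paste, c(cols, sep = ","))
  } else {
    do.call(paste, c(cols, sep = "\t"))
  }
}

csv_escape <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need], fixed = TRUE), '"')
  x
}

header_line <- function(columns, format) {
  if (identical(format, "CSV")) paste(csv_escape(columns), collapse = ",")
  else paste(columns, collapse = "\t")
}

#' Concatenate cohorts into one unified table
#'
#' Parses every discovered input file under one unified schema and returns
#' the serialized output lines (TSV or CSV per the schema), files in
#' lexicographic order, rows in source order. All discovered annotations
#' must agree on the output columns; a mismatch is an error.
#'
#' @param root Input directory.
#' @param annotation Optional annotation path overriding discovery.
#' @param header Emit the column-name line first?
#' @param where Optional filter: a condition string or [parse_where()]
#'   result.
#' @param workers Worker processes; never changes the output.
#' @param skip_bad_rows,lenient_where Error-policy toggles (see
#'   [parse_file()] and [parse_where()]).
#' @param plugins Plugin registry.
#' @param name_filter Optional file-name filter (see [find_files()]).
#' @param format Optional serialization override (`"TSV"` or `"CSV"`);
#'   defaults to the schema's output format.
#' @return Character vector of output lines, with a `stats` attribute
#'   (files, rows kept, rows skipped, lenient where misses).
#' @export
#' @examples
#' \dontrun{
#' writeLines(cat_variants("cohorts/", header = TRUE))
#' }
cat_variants <- function(root, annotation = NULL, header = TRUE,
                         where = NULL, workers = 1L,
                         skip_bad_rows = FALSE, lenient_where = FALSE,
                         plugins = plugin_registry(), name_filter = NULL,
                         format = NULL) {
  pairs <- find_files(root, name_filter = name_filter,
                      annotation = annotation)
  if (!nrow(pairs)) {
    vc_warn(sprintf("no input files matched under %s", root))
    return(structure(character(0),
                     stats = c(files = 0L, kept = 0L, skipped = 0L,
                               misses = 0L)))
  }
  sch <- unified_schema(pairs)
  fmt <- if (is.null(format)) sch$output_format else {
    toupper(match.arg(tolower(format), c("tsv", "csv")))
  }
  res <- process_pairs(pairs, where = where, workers = workers,
                       skip_bad_rows = skip_bad_rows,
                       lenient_where = lenient_where, plugins = plugins)
  lines <- unlist(lapply(res, function(r)
    serialize_records(r$df, fmt)), use.names = FALSE)
  if (header) lines <- c(header_line(sch$columns, fmt), lines)
  structure(lines, stats = c(
    files = nrow(pairs),
    kept = sum(vapply(res, function(r) nrow(r$df), integer(1))),
    skipped = sum(vapply(res, function(r) r$skipped, integer(1))),
    misses = sum(vapply(res, function(r) r$misses, integer(1)))
  ))
}

# shared core of group_by_variants / count_variants
grouped_records <- function(root, key_field, where, workers, annotation,
                            skip_bad_rows, lenient_where, plugins,
                            name_filter = NULL) {
  pairs <- find_files(root, name_filter = name_filter,
                      annotation = annotation)
  if (!nrow(pairs)) {
    vc_warn(sprintf("no input files matched under %s", root))
    return(list(schema = NULL, dfs = list(), key_idx = NA_integer_))
  }
  sch <- unified_schema(pairs)
  key_idx <- NA_integer_
  if (!is.null(key_field)) {
    key_idx <- match(norm_name(key_field), norm_name(sch$columns))
    if (is.na(key_idx)) {
      vc_abort(sprintf("unknown group key '%s' (schema columns: %s)",
                       key_field, paste(sch$columns, collapse = ", ")),
               "varcat_schema_error")
    }
  }
  res <- process_pairs(pairs, where = where, workers = workers,
                       skip_bad_rows = skip_bad_rows,
                       lenient_where = lenient_where, plugins = plugins)
  list(schema = sch, dfs = lapply(res, `[[`, "df"), key_idx = key_idx)
}

#' Group parsed records by the distinct values of a field
#'
#' Partitions all kept (and filter-surviving) records by the value of
#' `key_field`. Groups are returned sorted by key; within a group, records
#' keep (file lexicographic, source row) order. Records whose key is
#' unresolvable fall into the group labelled with the schema sentinel —
#' rows are never silently lost. Output is identical for any number of
#' workers.
#'
#' @inheritParams cat_variants
#' @param key_field Output column to group on; must be a schema column
#'   (checked before any parsing starts).
#' @return Named list of `data.frame`s, one per distinct key, sorted by key.
#' @export
group_by_variants <- function(root, key_field, where = NULL, workers = 1L,
                              annotation = NULL, skip_bad_rows = FALSE,
                              lenient_where = FALSE,
                              plugins = plugin_registry(),
                              name_filter = NULL) {
  g <- grouped_records(root, key_field, where, workers, annotation,
                       skip_bad_rows, lenient_where, plugins, name_filter)
  if (!length(g$dfs)) return(stats::setNames(list(), character(0)))
  all <- do.call(rbind, g$dfs)
  rownames(all) <- NULL
  keys <- all[[g$key_idx]]
  lv <- lex_sort(unique(keys))
  out <- split(all, factor(keys, levels = lv))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Count parsed records, optionally per group
#'
#' Returns the number of kept records satisfying the optional where clause;
#' with `group_by`, also the per-group totals (which sum to the total).
#' Output is identical for any number of workers.
#'
#' @inheritParams cat_variants
#' @param group_by Optional column name for per-group totals.
#' @return A `vc_count`: list with `total` and (possibly `NULL`) `groups`,
#'   a named integer vector sorted by key.
#' @export
count_variants <- function(root, where = NULL, group_by = NULL,
                           workers = 1L, annotation = NULL,
                           skip_bad_rows = FALSE, lenient_where = FALSE,
                           plugins = plugin_registry(), name_filter = NULL) {
  g <- grouped_records(root, group_by, where, workers, annotation,
                       skip_bad_rows, lenient_where, plugins, name_filter)
  counts <- vapply(g$dfs, nrow, integer(1))
  total <- if (length(counts)) sum(counts) else 0L
  groups <- NULL
  if (!is.null(group_by) && !is.na(g$key_idx)) {
    keys <- unlist(lapply(g$dfs, `[[`, g$key_idx), use.names = FALSE)
    if (is.null(keys)) keys <- character(0)
    tab <- table(factor(keys, levels = lex_sort(unique(keys))))
    groups <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(total = total, groups = groups), class = "vc_count")
}

#' @export
print.vc_count <- function(x, ...) {
  if (!is.null(x$groups)) {
    for (k in names(x$groups)) cat(sprintf("%s\t%d\n", k, x$groups[[k]]))
  }
  cat(sprintf("TOTAL\t%d\n", x$total))
  invisible(x)
}
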