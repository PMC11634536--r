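# Internal helpers: typed conditions, name normalization, locale-stable sort.

vc_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "varcat_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  ))
}

vc_warn <- function(msg) warning(msg, call. = FALSE)

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Header matching is case-insensitive after trimming surrounding whitespace;
# MAF dialects disagree on casing so exact matches are a trap.
norm_name <- function(x) tolower(trimws(x))

# Locale-independent lexicographic sort: task outputs must be byte-identical
# across machines, so never rely on the collation locale.
lex_sort <- function(x) sort(x, method = "radix")

# Glob -> regex on a single path component (file or directory name).
glob_match <- function(names, patterns) {
  hit <- rep(FALSE, length(names))
  for (p in patterns) {
    hit <- hit | grepl(utils::glob2rx(p), names)
  }
  hit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# yaml collapses singleton lists to scalars; always come back to character.
as_chr <- function(x) {
  if (is.null(x)) return(character(0))
  vapply(x, as.character, character(1), USE.NAMES = FALSE)
}

as_flag <- function(x, default, key, where) {
  if (is.null(x)) return(default)
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    vc_abort(sprintf("key '%s' must be true or false in %s", key, where),
             "varcat_schema_error")
  }
  x
}
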