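#' Parse a where-clause condition
#'
#' The grammar is a single comparison, `FIELD OP LITERAL`, with
#' `OP` one of `==`, `!=`, `<`, `<=`, `>`, `>=`. The literal may be
#' double-quoted to embed spaces. Ordering operators compare numerically and
#' require both sides to parse as decimal numbers at evaluation time;
#' `==`/`!=` compare numerically when both sides are numeric and as strings
#' otherwise.
#'
#' @param text Condition string, e.g. `'REF == "A"'` or `"POS >= 1000"`.
#' @return A `vc_where` with `field`, `op` (one of EQ, NE, LT, LE, GT, GE)
#'   and `literal`.
#' @export
#' @examples
#' parse_where('DATASET == "cohortB"')
parse_where <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    vc_abort("where clause must be a non-empty string", "varcat_where_error")
  }
  m <- regexec("^\\s*([^!=<>\\s]+)\\s*(==|!=|<=|>=|<|>)\\s*(.*?)\\s*$",
               text, perl = TRUE)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L || !nzchar(parts[4])) {
    vc_abort(sprintf(
      "cannot parse where clause '%s': expected FIELD OP LITERAL with OP in ==, !=, <, <=, >, >=",
      text), "varcat_where_error")
  }
  lit <- parts[4]
  if (grepl('^".*"$', lit)) {
    lit <- substr(lit, 2L, nchar(lit) - 1L)
  } else if (grepl("[=<>!]", lit)) {
    vc_abort(sprintf("where clause '%s': unexpected token '%s' (one comparison only)",
                     text, lit), "varcat_where_error")
  }
  op <- c("==" = "EQ", "!=" = "NE", "<" = "LT", "<=" = "LE",
          ">" = "GT", ">=" = "GE")[[parts[3]]]
  structure(list(field = parts[2], op = op, literal = lit),
            class = "vc_where")
}

#' @export
print.vc_where <- function(x, ...) {
  cat(sprintf("<where: %s %s %s>\n", x$field, x$op, x$literal))
  invisible(x)
}

as_where <- function(where) {
  if (is.null(where) || inherits(where, "vc_where")) return(where)
  if (is_string(where)) return(parse_where(where))
  vc_abort("'where' must be a string or a parsed clause", "varcat_where_error")
}

# Vectorized evaluation over a character column. Ordering operators on a
# non-numeric cell are a hard error unless `lenient` (then FALSE, counted by
# the caller via the "lenient_misses" attribute).
eval_where <- function(clause, values, lenient = FALSE,
                       provenance = NULL) {
  lit_num <- suppressWarnings(as.numeric(clause$literal))
  val_num <- suppressWarnings(as.numeric(values))
  numeric_pair <- !is.na(lit_num) & !is.na(val_num)

  if (clause$op %in% c("LT", "LE", "GT", "GE")) {
    bad <- !numeric_pair
    if (any(bad) && !lenient) {
      i <- which(bad)[1]
      ctx <- if (is.null(provenance)) "" else
        sprintf(" (%s row %d)", provenance$source[i], provenance$row[i])
      vc_abort(sprintf(
        "numeric comparison %s %s %s against non-numeric value '%s'%s",
        clause$field, clause$op, clause$literal, values[i], ctx),
        "varcat_where_error")
    }
    res <- switch(clause$op,
      LT = val_num < lit_num, LE = val_num <= lit_num,
      GT = val_num > lit_num, GE = val_num >= lit_num)
    res[bad] <- FALSE
    attr(res, "lenient_misses") <- sum(bad)
    return(res)
  }
  eq <- ifelse(numeric_pair, val_num == lit_num, values == clause$literal)
  res <- if (clause$op == "EQ") eq else !eq
  attr(res, "lenient_misses") <- 0L
  res
}
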