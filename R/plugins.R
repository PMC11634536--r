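#' Classify an alteration from its reference and alternate alleles
#'
#' Assigns one of `SNV`, `MNV`, `INS`, `DEL`, `UNKNOWN` to each ref/alt
#' pair, handling both encoding conventions found in cohort data: MAF-style
#' dash placeholders (`REF = "-"`, `ALT = "T"` for an insertion) and
#' VCF-style anchored alleles (`REF = "A"`, `ALT = "AT"`), which are
#' classified by raw length comparison without trimming the shared anchor
#' base — classification never rewrites alleles.
#'
#' Rules, in order (after upper-casing and trimming): both alleles empty or
#' `"-"` yields `UNKNOWN`; an empty/dash ref is `INS`; an empty/dash alt is
#' `DEL`; any character outside `A,C,G,T,N` is `UNKNOWN`; identical alleles
#' are `UNKNOWN`; equal lengths give `SNV` (length 1) or `MNV`; otherwise a
#' shorter ref is `INS` and a longer ref is `DEL`. Swapping ref and alt maps
#' `INS` to `DEL` and back while fixing the other classes.
#'
#' @param ref,alt Character vectors of equal length (or length 1, recycled).
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_alteration(c("A", "A", "ACT", "AT", "-"),
#'                     c("C", "ACT", "A", "GC", "T"))
classify_alteration <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  r <- toupper(trimws(rep_len(as.character(ref), n)))
  a <- toupper(trimws(rep_len(as.character(alt), n)))
  r_empty <- r == "" | r == "-"
  a_empty <- a == "" | a == "-"
  valid <- grepl("^[ACGTN]+$", r) | r_empty
  valid <- valid & (grepl("^[ACGTN]+$", a) | a_empty)

  out <- rep("UNKNOWN", n)
  nr <- nchar(r); na_ <- nchar(a)
  eqlen <- !r_empty & !a_empty & valid & r != a & nr == na_
  out[eqlen & nr == 1L] <- "SNV"
  out[eqlen & nr > 1L] <- "MNV"
  out[!r_empty & !a_empty & valid & nr < na_] <- "INS"
  out[!r_empty & !a_empty & valid & nr > na_] <- "DEL"
  out[r_empty & !a_empty] <- "INS"
  out[a_empty & !r_empty] <- "DEL"
  # both alleles absent: no event to classify (keeps the swap symmetry
  # INS <-> DEL exact)
  out[r_empty & a_empty] <- "UNKNOWN"
  out
}

# look a value up in the record under construction first (earlier columns),
# then in the raw input row through header aliases
ctx_value <- function(ctx, aliases) {
  i <- match(norm_name(aliases), norm_name(names(ctx$record)))
  i <- i[!is.na(i)]
  if (length(i)) return(ctx$record[[i[1]]])
  j <- alias_index(aliases, ctx$header_norm)
  if (!is.na(j) && j <= length(ctx$raw_row$values)) {
    return(ctx$raw_row$values[j])
  }
  NULL
}

builtin_plugins <- function() {
  list(
    alteration_type = structure(list(
      name = "alteration_type",
      version = "1.0",
      description = "Classify REF/ALT pairs as SNV, MNV, INS, DEL or UNKNOWN",
      process = function(ctx) {
        ref <- ctx_value(ctx, c("REF", "Reference_Allele", "ref"))
        alt <- ctx_value(ctx, c("ALT", "Tumor_Seq_Allele2", "Alternate_Allele",
                                "alt"))
        if (is.null(ref) || is.null(alt)) {
          stop("alteration_type: no REF/ALT alleles found in record or header")
        }
        classify_alteration(ref, alt)
      }
    ), class = "vc_plugin")
  )
}

#' Build the plugin registry
#'
#' Combines the built-in plugins (currently `alteration_type`) with any user
#' plugins discovered under `user_dir`. A user plugin lives in its own
#' subdirectory holding a `plugin.yaml` descriptor (`name`, optionally
#' `version` and `description`) and a `plugin.R` file defining a function
#' `process(ctx)` that returns the field's string value for one row. On a
#' name collision the user plugin wins, with a warning.
#'
#' @param user_dir Optional directory of user plugins; the `VARCAT_PLUGINS`
#'   environment variable is consulted when unset.
#' @return Named list of plugins.
#' @export
plugin_registry <- function(user_dir = NULL) {
  reg <- builtin_plugins()
  if (is.null(user_dir)) {
    env <- Sys.getenv("VARCAT_PLUGINS", "")
    if (nzchar(env)) user_dir <- env
  }
  if (is.null(user_dir)) return(reg)
  if (!dir.exists(user_dir)) {
    vc_abort(sprintf("plugin directory not found: %s", user_dir),
             "varcat_plugin_error")
  }
  for (d in lex_sort(list.dirs(user_dir, recursive = FALSE))) {
    p <- load_user_plugin(d)
    if (p$name %in% names(reg)) {
      vc_warn(sprintf("user plugin '%s' (%s) overrides a registered plugin",
                      p$name, d))
    }
    reg[[p$name]] <- p
  }
  reg
}

load_user_plugin <- function(dir) {
  desc_path <- file.path(dir, "plugin.yaml")
  impl_path <- file.path(dir, "plugin.R")
  if (!file.exists(desc_path) || !file.exists(impl_path)) {
    vc_abort(sprintf("plugin entry %s lacks plugin.yaml or plugin.R", dir),
             "varcat_plugin_error")
  }
  desc <- tryCatch(yaml::read_yaml(desc_path), error = function(e) {
    vc_abort(sprintf("malformed descriptor in %s: %s", dir,
                     conditionMessage(e)), "varcat_plugin_error")
  })
  if (!is.list(desc) || !is_string(desc$name)) {
    vc_abort(sprintf("descriptor in %s must declare a 'name'", dir),
             "varcat_plugin_error")
  }
  env <- new.env(parent = asNamespace("varcat"))
  tryCatch(sys.source(impl_path, envir = env),
           error = function(e) {
             vc_abort(sprintf("plugin '%s' failed to load (%s): %s",
                              desc$name, impl_path, conditionMessage(e)),
                      "varcat_plugin_error")
           })
  fn <- env$process
  if (!is.function(fn)) {
    vc_abort(sprintf("plugin '%s' (%s) does not define a function 'process'",
                     desc$name, impl_path), "varcat_plugin_error")
  }
  structure(list(
    name = desc$name,
    version = as.character(desc$version %||% "0.0"),
    description = as.character(desc$description %||% ""),
    process = fn
  ), class = "vc_plugin")
}

#' Generate a plugin template
#'
#' Writes a ready-to-edit plugin skeleton — a `plugin.yaml` descriptor and a
#' `plugin.R` stub whose `process(ctx)` returns the schema sentinel — that
#' loads through [plugin_registry()] unmodified.
#'
#' @param name Plugin identifier (letters, digits, `_`; must not start with
#'   a digit).
#' @param target_dir Plugin directory the template is created under.
#' @param force Overwrite an existing plugin of the same name.
#' @return Invisibly, the paths of the created files.
#' @export
scaffold_plugin <- function(name, target_dir, force = FALSE) {
  if (!is_string(name) || !grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    vc_abort(sprintf("'%s' is not a valid plugin identifier", name),
             "varcat_plugin_error")
  }
  dir <- file.path(target_dir, name)
  if (dir.exists(dir) && !force) {
    vc_abort(sprintf("plugin '%s' already exists under %s (use force to overwrite)",
                     name, target_dir), "varcat_plugin_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  desc <- file.path(dir, "plugin.yaml")
  impl <- file.path(dir, "plugin.R")
  writeLines(yaml::as.yaml(list(
    name = name, version = "0.1",
    description = "Describe the value this plugin computes per record."
  )), desc)
  writeLines(c(
    sprintf("# Plugin '%s': return one string value per input row.", name),
    "#",
    "# `ctx` carries: source_path, file_name, dir_name, header,",
    "# raw_row$values / raw_row$row_number, and `record` — the output",
    "# fields resolved so far (earlier schema columns; read-only).",
    "process <- function(ctx) {",
    "  # TODO: compute a value from ctx; the sentinel marks 'no value'.",
    "  ctx$sentinel",
    "}"
  ), impl)
  invisible(c(descriptor = desc, implementation = impl))
}
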