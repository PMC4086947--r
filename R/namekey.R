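#' The four contexts a taxonomic name can be used in
#'
#' Every name-usage record is classified into exactly one of four context
#' categories: reference to a museum specimen, reference to a geographic
#' location, reference to (a name in) an earlier publication, or use
#' without any determinable context.
#'
#' @return Character vector of the four context tokens, in canonical order:
#'   `"specimen"`, `"location"`, `"citation"`, `"none"`.
#' @examples
#' context_kinds()
#' @export
context_kinds <- function() {
  c("specimen", "location", "citation", "none")
}

new_name_key <- function(base, context, raw) {
  structure(
    list(base = base, context = context, raw = raw),
    class = "name_key"
  )
}

#' Parse a name-usage key
#'
#' Within one publication every distinct name receives a positive integer
#' base key; when the name is used in several contexts each context gets a
#' decimal index appended (`"3.1"`, `"3.2"`, ...). Two reserved forms exist:
#' `"0"` marks a general citation to a publication with no internal name
#' context, and `"."` marks missing data (e.g. the cited work has not been
#' recorded yet).
#'
#' Keys are parsed by splitting on the dot into two integers, never through
#' floating point: `"3.10"` is context 10 of base 3 and is distinct from
#' `"3.1"`. Leading zeros are rejected so that parsing and serialisation
#' round-trip losslessly.
#'
#' @param raw Single key string, e.g. `"3"`, `"3.1"`, `"0"`, or `"."`.
#' @return A `name_key` object: list with integer `base`, integer `context`
#'   (`NA` when the key addresses all contexts of the name), and the
#'   verbatim `raw` string. For `"."` both `base` and `context` are `NA`.
#' @examples
#' parse_name_key("3.1")
#' parse_name_key("0")    # general citation sentinel
#' parse_name_key(".")    # missing-data sentinel
#' @seealso [format_name_key()]
#' @export
parse_name_key <- function(raw) {
  stopifnot_scalar_chr(raw, "name key")
  if (!nzchar(raw)) fail("name key must be non-empty")
  if (raw == ".") {
    return(new_name_key(NA_integer_, NA_integer_, "."))
  }
  if (!grepl("^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))?$", raw)) {
    fail("malformed name key: '%s'", raw)
  }
  parts <- strsplit(raw, ".", fixed = TRUE)[[1L]]
  base <- as.integer(parts[[1L]])
  context <- if (length(parts) == 2L) as.integer(parts[[2L]]) else NA_integer_
  if (!is.na(context)) {
    if (base < 1L) fail("context index on the zero key is not allowed: '%s'", raw)
    if (context < 1L) fail("context index must be >= 1: '%s'", raw)
  }
  new_name_key(base, context, raw)
}

#' Serialise a name key back to its string form
#'
#' Inverse of [parse_name_key()]: `format_name_key(parse_name_key(x))`
#' equals `x` for every well-formed key string.
#'
#' @param key A `name_key` object.
#' @return The key as a string.
#' @export
format_name_key <- function(key) {
  if (!inherits(key, "name_key")) fail("not a name_key object")
  if (is.na(key$base)) return(".")
  if (is.na(key$context)) {
    as.character(key$base)
  } else {
    paste0(key$base, ".", key$context)
  }
}

#' @export
print.name_key <- function(x, ...) {
  if (is.na(x$base)) {
    cat("<name key: missing>\n")
  } else if (x$base == 0L) {
    cat("<name key: 0 (general citation)>\n")
  } else if (is.na(x$context)) {
    cat(sprintf("<name key: %d (all contexts)>\n", x$base))
  } else {
    cat(sprintf("<name key: %d.%d>\n", x$base, x$context))
  }
  invisible(x)
}

# vectorised parse used internally; returns data.frame(base, context)
parse_keys_df <- function(raws) {
  n <- length(raws)
  base <- integer(n)
  context <- integer(n)
  for (i in seq_len(n)) {
    k <- parse_name_key(raws[[i]])
    base[i] <- k$base
    context[i] <- k$context
  }
  data.frame(base = base, context = context)
}
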