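#' Build a spelling-variant table
#'
#' Maps variant epithets — gender-agreement forms, typographic errors,
#' orthographic alternatives — to their canonical spelling (e.g.
#' *coarctatus*, *coartatus* and *corctata* all map to *coarctata*). The
#' mapping must be functional (no variant with two different canonicals)
#' and is closed on construction: if a canonical is itself listed as a
#' variant, chains are followed to their fixed point so that
#' [canonical_epithet()] is idempotent.
#'
#' @param variant Character vector of variant epithets.
#' @param canonical Character vector of the same length with the accepted
#'   spellings.
#' @param class Optional character vector tagging each variant
#'   (`"gender-agreement"`, `"typographic"`, `"orthographic"`, ...).
#' @return A `variant_table` object.
#' @export
variant_table <- function(variant = character(0), canonical = character(0),
                          class = NULL) {
  variant <- tolower(as.character(variant))
  canonical <- tolower(as.character(canonical))
  if (length(variant) != length(canonical)) {
    fail("variant and canonical vectors differ in length")
  }
  class <- if (is.null(class)) rep(NA_character_, length(variant)) else as.character(class)

  tab <- data.frame(variant = variant, canonical = canonical, class = class)
  # drop identity rows, they are implicit
  tab <- tab[tab$variant != tab$canonical, , drop = FALSE]
  amb <- tapply(tab$canonical, tab$variant, function(x) length(unique(x)))
  if (any(amb > 1L)) {
    fail("ambiguous variant(s) mapped to multiple canonicals: %s",
         paste(names(amb)[amb > 1L], collapse = ", "))
  }
  tab <- tab[!duplicated(tab$variant), , drop = FALSE]
  map <- stats::setNames(tab$canonical, tab$variant)

  # close chains variant -> canonical -> canonical', detecting cycles
  follow <- function(v) {
    seen <- v
    cur <- unname(map[[v]])
    while (cur %in% names(map)) {
      if (cur %in% seen) fail("cycle in variant table involving '%s'", v)
      seen <- c(seen, cur)
      cur <- unname(map[[cur]])
    }
    cur
  }
  if (length(map)) {
    map <- stats::setNames(vapply(names(map), follow, character(1)), names(map))
  }
  tab$canonical <- unname(map[tab$variant])
  rownames(tab) <- NULL
  structure(list(map = map, table = tab), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table: %d variant spellings -> %d canonical epithets>\n",
              nrow(x$table), length(unique(x$table$canonical))))
  invisible(x)
}

#' Canonical spelling of an epithet
#'
#' Looks the epithet up (case-insensitively) in the variant table and
#' returns the canonical spelling; epithets not in the table pass through
#' lowercased, because the database deliberately stores misspellings that
#' may not have been tabled yet. The function is total and idempotent.
#'
#' @param epithet A single epithet string.
#' @param table A [variant_table()].
#' @return The canonical epithet, lowercase.
#' @examples
#' vt <- variant_table(c("coarctatus", "corctata"), c("coarctata", "coarctata"))
#' canonical_epithet("coarctatus", vt)
#' @export
canonical_epithet <- function(epithet, table = variant_table()) {
  stopifnot_scalar_chr(epithet, "epithet")
  key <- tolower(epithet)
  if (key %in% names(table$map)) unname(table$map[[key]]) else key
}

QUALIFIER_WORDS <- c("sp", "spp", "ssp", "var", "cf", "aff", "f", "forma",
                     "unnamed", "indet", "nov", "gen", "n")

# tokens: parenthesised runs stay together ("(pink claw)")
tokenize_name <- function(verbatim) {
  m <- gregexpr("\\([^)]*\\)|[^[:space:]]+", verbatim)
  regmatches(verbatim, m)[[1L]]
}

is_qualifier_token <- function(tok) {
  if (grepl("^\\(", tok)) return(TRUE)          # parenthesised (non-subgenus position)
  if (grepl("[0-9?]", tok)) return(TRUE)
  core <- tolower(sub("\\.+$", "", tok))
  if (grepl("\\.", tok) || core %in% QUALIFIER_WORDS) return(TRUE)
  FALSE
}

#' Split a compound scientific name into its parts
#'
#' Classifies the tokens of a verbatim compound name by position and
#' bracketing convention: the first capitalised token is the genus, a
#' parenthesised token immediately after it the subgenus, and subsequent
#' plain tokens fill the specific then subspecific epithets. Tokens that
#' cannot be classified (abbreviations such as `"sp."`, `"var."`,
#' `"unnamed"`, parenthesised annotations away from the subgenus position)
#' are collected in `qualifiers` in their original order. Original
#' capitalisation is preserved in the parts; comparison is the job of
#' [names_match()].
#'
#' @param verbatim Compound name exactly as printed.
#' @return A `parsed_name` list: `genus`, `subgenus`, `specific`,
#'   `subspecific` (each `NA` when absent), `qualifiers` (character
#'   vector), and the `verbatim` input.
#' @examples
#' parse_compound_name("Uca (Minuca) pugnax")
#' parse_compound_name("Uca unnamed sp. (pink claw)")
#' @export
parse_compound_name <- function(verbatim) {
  stopifnot_scalar_chr(verbatim, "name")
  toks <- tokenize_name(verbatim)
  if (length(toks) == 0L) fail("name contains no tokens: '%s'", verbatim)

  genus <- subgenus <- specific <- subspecific <- NA_character_
  qualifiers <- character(0)
  i <- 1L

  if (grepl("^[A-Z][A-Za-z-]*$", toks[[1L]])) {
    genus <- toks[[1L]]
    i <- 2L
    if (i <= length(toks) && grepl("^\\([A-Z][A-Za-z-]*\\)$", toks[[i]])) {
      subgenus <- sub("^\\((.*)\\)$", "\\1", toks[[i]])
      i <- i + 1L
    }
  }

  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (!is_qualifier_token(tok) && grepl("^[A-Za-z][A-Za-z-]*$", tok)) {
      if (is.na(specific)) {
        specific <- tok
      } else if (is.na(subspecific)) {
        subspecific <- tok
      } else {
        qualifiers <- c(qualifiers, tok)
      }
    } else {
      qualifiers <- c(qualifiers, tok)
    }
    i <- i + 1L
  }

  structure(
    list(genus = genus, subgenus = subgenus, specific = specific,
         subspecific = subspecific, qualifiers = qualifiers,
         verbatim = verbatim),
    class = "parsed_name"
  )
}

#' @export
print.parsed_name <- function(x, ...) {
  part <- function(v) if (is.na(v)) "-" else v
  cat(sprintf("<parsed name '%s': genus=%s subgenus=%s specific=%s subspecific=%s%s>\n",
              x$verbatim, part(x$genus), part(x$subgenus), part(x$specific),
              part(x$subspecific),
              if (length(x$qualifiers)) paste0(" qualifiers=[", paste(x$qualifiers, collapse = " "), "]") else ""))
  invisible(x)
}

#' Compare two names modulo spelling variation
#'
#' Two names match when the canonical spellings of their specific epithets
#' agree (case-insensitively), and — if both carry a subspecific epithet —
#' those agree as well. Differences in genus placement alone never block a
#' match: the wholesale migration of fiddler-crab epithets from *Gelasimus*
#' to *Uca* makes the genus uninformative for identity. Names without a
#' specific epithet (bare genus discussions) match on the canonical genus
#' instead.
#'
#' @param a,b Verbatim name strings.
#' @param table A [variant_table()] of epithet spellings.
#' @return `TRUE` or `FALSE`.
#' @examples
#' vt <- variant_table("coarctatus", "coarctata")
#' names_match("Gelasimus coarctatus", "Uca coarctata", vt)
#' @export
names_match <- function(a, b, table = variant_table()) {
  pa <- parse_compound_name(a)
  pb <- parse_compound_name(b)
  if (!is.na(pa$specific) && !is.na(pb$specific)) {
    if (canonical_epithet(pa$specific, table) != canonical_epithet(pb$specific, table)) {
      return(FALSE)
    }
    if (!is.na(pa$subspecific) && !is.na(pb$subspecific)) {
      return(canonical_epithet(pa$subspecific, table) ==
               canonical_epithet(pb$subspecific, table))
    }
    return(TRUE)
  }
  if (is.na(pa$specific) && is.na(pb$specific) &&
      !is.na(pa$genus) && !is.na(pb$genus)) {
    return(canonical_epithet(pa$genus, table) == canonical_epithet(pb$genus, table))
  }
  FALSE
}
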