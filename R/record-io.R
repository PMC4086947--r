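USAGE_FILE_COLUMNS <- c("pub_key", "name_key", "name", "locus", "context",
                        "detail1", "detail2", "accepted", "notes", "common_name")

#' Flat-file dialect for the record tables
#'
#' The canonical on-disk form is tab-delimited UTF-8 with a header row and
#' no quoting; a period in any cell marks missing data, because columns
#' are never left blank. A comma delimiter is available for CSV
#' interchange; since no quoting is performed, cells may not contain the
#' delimiter or line breaks (the writer refuses them).
#'
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @param missing Missing-data marker, default `"."`.
#' @return A `record_dialect` object.
#' @export
record_dialect <- function(delimiter = "\t", missing = ".") {
  stopifnot_scalar_chr(delimiter, "delimiter")
  stopifnot_scalar_chr(missing, "missing marker")
  structure(list(delimiter = delimiter, missing = missing),
            class = "record_dialect")
}

# -- low-level line-oriented reader/writer -------------------------------
# no quoting: verbatim cells must round-trip byte-for-byte, and row-level
# errors need line numbers

read_flat_table <- function(path, dialect, required, optional = character(0)) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) fail("empty file (no header): %s", path)
  header <- strsplit(lines[[1L]], dialect$delimiter, fixed = TRUE)[[1L]]
  miss <- setdiff(required, header)
  if (length(miss)) {
    fail("%s: header lacks column(s): %s", path, paste(miss, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ncols <- length(header)
  cells <- vector("list", length(body))
  for (i in seq_along(body)) {
    row <- strsplit(body[[i]], dialect$delimiter, fixed = TRUE)[[1L]]
    # a trailing missing cell is dropped by strsplit; repair it
    if (length(row) == ncols - 1L && endsWith(body[[i]], dialect$delimiter)) {
      row <- c(row, "")
    }
    if (length(row) != ncols) {
      fail("%s line %d: expected %d columns, found %d",
           path, i + 1L, ncols, length(row))
    }
    cells[[i]] <- row
  }
  mat <- if (length(cells)) do.call(rbind, cells) else matrix(character(0), 0, ncols)
  df <- as.data.frame(mat)
  names(df) <- header
  for (col in names(df)) {
    v <- df[[col]]
    v[v == dialect$missing] <- NA_character_
    df[[col]] <- v
  }
  df
}

write_flat_table <- function(df, path, dialect) {
  for (col in names(df)) {
    v <- as.character(df[[col]])
    v[is.na(v) | !nzchar(v)] <- dialect$missing
    bad <- grepl(dialect$delimiter, v, fixed = TRUE) | grepl("[\r\n]", v)
    if (any(bad)) {
      fail("cell in column '%s' contains the delimiter or a line break; cannot write without quoting", col)
    }
    df[[col]] <- v
  }
  lines <- c(paste(names(df), collapse = dialect$delimiter),
             apply(df, 1L, paste, collapse = dialect$delimiter))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# -- usages ---------------------------------------------------------------

#' Read name-usage records
#'
#' Reads the record table in the flat layout: publication key, name key,
#' verbatim name, locus (pages/plates/figures), context, two context-detail
#' columns, accepted species, notes, and an optional common-name column.
#' The detail columns are interpreted per context kind — geographic place
#' and specimen id for specimen/location records, cited publication key and
#' cited name key for citation records. An `"="` in the accepted-species
#' column marks the species for computational determination via the
#' citation; `"?"` (or a missing cell) marks it unknown/indeterminate.
#' Verbatim names are never altered: spelling, capitalisation, internal
#' whitespace and diacritics all survive.
#'
#' @param path File path.
#' @param dialect A [record_dialect()].
#' @return Data frame of normalised usage rows (see [taxon_dataset()]).
#' @export
read_usages <- function(path, dialect = record_dialect()) {
  raw <- read_flat_table(path, dialect, required = USAGE_FILE_COLUMNS[1:9],
                         optional = "common_name")
  n <- nrow(raw)
  if (is.null(raw$common_name)) raw$common_name <- rep(NA_character_, n)

  ctx <- tolower(ifelse(is.na(raw$context), "", raw$context))
  bad <- which(!(ctx %in% context_kinds()))
  if (length(bad)) {
    fail("%s line %d: unknown context token '%s'", path, bad[1L] + 1L,
         raw$context[bad[1L]] %||% ".")
  }
  for (i in seq_len(n)) {
    k <- tryCatch(parse_name_key(raw$name_key[i]), error = function(e) e)
    if (inherits(k, "error")) {
      fail("%s line %d: %s", path, i + 1L, conditionMessage(k))
    }
  }

  acc <- raw$accepted
  mode <- ifelse(is.na(acc) | acc == "?" | tolower(acc) == "unknown", "unknown",
                 ifelse(acc == "=", "compute", "explicit"))
  species <- ifelse(mode == "explicit", acc, NA_character_)

  is_cit <- ctx == "citation"
  out <- data.frame(
    pub_key = raw$pub_key,
    name_key = raw$name_key,
    name = raw$name,
    common_name = raw$common_name,
    locus = raw$locus,
    context = ctx,
    place = ifelse(is_cit, NA_character_, raw$detail1),
    specimen_id = ifelse(is_cit, NA_character_, raw$detail2),
    cited_pub = ifelse(is_cit, raw$detail1, NA_character_),
    cited_key = ifelse(is_cit, raw$detail2, NA_character_),
    accepted_mode = mode,
    accepted_species = species,
    notes = raw$notes
  )
  out
}

#' Write name-usage records
#'
#' Inverse of [read_usages()]; missing cells are emitted as the dialect's
#' missing marker so that no column is ever blank. Files produced by this
#' writer round-trip byte-identically through read and write.
#'
#' @param usages Normalised usage data frame.
#' @param path Output file path.
#' @param dialect A [record_dialect()].
#' @return The path, invisibly.
#' @export
write_usages <- function(usages, path, dialect = record_dialect()) {
  u <- as.data.frame(usages)
  is_cit <- u$context == "citation"
  acc <- ifelse(u$accepted_mode == "compute", "=",
                ifelse(u$accepted_mode == "unknown", "?", u$accepted_species))
  df <- data.frame(
    pub_key = u$pub_key,
    name_key = u$name_key,
    name = u$name,
    locus = u$locus,
    context = u$context,
    detail1 = ifelse(is_cit, u$cited_pub, u$place),
    detail2 = ifelse(is_cit, u$cited_key, u$specimen_id),
    accepted = acc,
    notes = u$notes,
    common_name = u$common_name
  )
  write_flat_table(df, path, dialect)
}

# -- publications, variants, species -------------------------------------

#' Read and write the publication table
#'
#' Columns: `key` (opaque author+year identifier), `year`, `citation`
#' (free-form bibliographic string), `recorded` (1/0 — whether the
#' publication's name records have been entered in the database).
#'
#' @param path File path.
#' @param dialect A [record_dialect()].
#' @return Data frame with columns `key`, `year`, `citation_text`,
#'   `recorded`.
#' @export
read_publications <- function(path, dialect = record_dialect()) {
  raw <- read_flat_table(path, dialect, required = c("key", "year", "citation", "recorded"))
  bad_year <- !is.na(raw$year) & !grepl("^-?[0-9]+$", raw$year)
  if (any(bad_year)) {
    fail("%s line %d: unparseable year '%s'", path,
         which(bad_year)[1L] + 1L, raw$year[which(bad_year)[1L]])
  }
  data.frame(
    key = raw$key,
    year = as.integer(raw$year),
    citation_text = raw$citation,
    recorded = is.na(raw$recorded) | raw$recorded %in% c("1", "true", "TRUE", "yes")
  )
}

#' @rdname read_publications
#' @param publications Publication data frame.
#' @export
write_publications <- function(publications, path, dialect = record_dialect()) {
  df <- data.frame(
    key = publications$key,
    year = as.character(publications$year),
    citation = publications$citation_text,
    recorded = ifelse(publications$recorded, "1", "0")
  )
  write_flat_table(df, path, dialect)
}

#' Read and write the spelling-variant table
#'
#' Two columns `variant`, `canonical`, plus an optional `class` column
#' tagging the kind of variation. A variant listed with two different
#' canonicals is an error (the mapping must be functional).
#'
#' @param path File path.
#' @param dialect A [record_dialect()].
#' @return A [variant_table()].
#' @export
read_variants <- function(path, dialect = record_dialect()) {
  raw <- read_flat_table(path, dialect, required = c("variant", "canonical"))
  variant_table(raw$variant %||% character(0),
                raw$canonical %||% character(0),
                raw$class)
}

#' @rdname read_variants
#' @param variants A [variant_table()].
#' @export
write_variants <- function(variants, path, dialect = record_dialect()) {
  write_flat_table(variants$table, path, dialect)
}

#' Read and write the accepted-species table
#'
#' Columns: `species_id`, `binomial` (currently accepted name), `status`
#' (`extant`, `extinct`, `invalid`, or `uncertain`), and optional
#' `etymology` free text.
#'
#' @param path File path.
#' @param dialect A [record_dialect()].
#' @return Species data frame.
#' @export
read_species <- function(path, dialect = record_dialect()) {
  raw <- read_flat_table(path, dialect, required = c("species_id", "binomial", "status"))
  if (is.null(raw$etymology)) raw$etymology <- rep(NA_character_, nrow(raw))
  raw[c("species_id", "binomial", "status", "etymology")]
}

#' @rdname read_species
#' @param species Species data frame.
#' @export
write_species <- function(species, path, dialect = record_dialect()) {
  df <- species[c("species_id", "binomial", "status", "etymology")]
  write_flat_table(df, path, dialect)
}

# -- whole-dataset convenience -------------------------------------------

DATASET_FILES <- c(usages = "usages.tsv", publications = "publications.tsv",
                   variants = "variants.tsv", species = "species.tsv")

#' Read or write a whole dataset directory
#'
#' A dataset directory holds the four tables as `usages.tsv`,
#' `publications.tsv`, `variants.tsv`, and `species.tsv`. The variant and
#' species files are optional on read (an empty table is substituted).
#'
#' @param dir Directory path.
#' @param dialect A [record_dialect()].
#' @return `read_dataset()` returns a [taxon_dataset()];
#'   `write_dataset()` returns `dir` invisibly.
#' @export
read_dataset <- function(dir, dialect = record_dialect()) {
  p <- function(f) file.path(dir, f)
  usages <- read_usages(p(DATASET_FILES[["usages"]]), dialect)
  publications <- read_publications(p(DATASET_FILES[["publications"]]), dialect)
  variants <- if (file.exists(p(DATASET_FILES[["variants"]]))) {
    read_variants(p(DATASET_FILES[["variants"]]), dialect)
  } else NULL
  species <- if (file.exists(p(DATASET_FILES[["species"]]))) {
    read_species(p(DATASET_FILES[["species"]]), dialect)
  } else NULL
  taxon_dataset(usages, publications, species, variants)
}

#' @rdname read_dataset
#' @param dataset A [taxon_dataset()].
#' @export
write_dataset <- function(dataset, dir, dialect = record_dialect()) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_usages(dataset$usages, p(DATASET_FILES[["usages"]]), dialect)
  write_publications(dataset$publications, p(DATASET_FILES[["publications"]]), dialect)
  write_variants(dataset$variants, p(DATASET_FILES[["variants"]]), dialect)
  write_species(dataset$species, p(DATASET_FILES[["species"]]), dialect)
  invisible(dir)
}

#' Export a dataset as one JSON document
#'
#' Serialises all four tables (usages in normalised column form) into a
#' single JSON object for downstream tooling.
#'
#' @param dataset A [taxon_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_dataset_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  doc <- list(
    usages = dataset$usages,
    publications = dataset$publications,
    variants = dataset$variants$table,
    species = dataset$species
  )
  jsonlite::write_json(doc, path, dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
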