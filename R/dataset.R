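USAGE_COLUMNS <- c(
  "pub_key", "name_key", "name", "common_name", "locus", "context",
  "place", "specimen_id", "cited_pub", "cited_key",
  "accepted_mode", "accepted_species", "notes"
)

#' Assemble a contextual name-usage dataset
#'
#' Bundles the four tables of a contextual chresonymy database into one
#' object: the name-usage records, the publication table, the accepted
#' species table, and the spelling-variant table. Most users will load a
#' dataset from disk with [read_dataset()] instead of calling this
#' directly.
#'
#' The usage table is held in a normalised form: the two context-detail
#' columns of the flat file are split into `place`/`specimen_id` (specimen
#' and location contexts) and `cited_pub`/`cited_key` (citation contexts),
#' and the accepted-species column is split into `accepted_mode` (one of
#' `"explicit"`, `"compute"`, `"unknown"`) plus the species id itself.
#'
#' @param usages Data frame of name-usage records (see [read_usages()]).
#' @param publications Data frame with columns `key`, `year`,
#'   `citation_text`, `recorded`.
#' @param species Data frame with columns `species_id`, `binomial`,
#'   `status` (and optional `etymology`); may be `NULL`.
#' @param variants A [variant_table()] (or `NULL` for the identity table).
#' @return An object of class `taxon_dataset`.
#' @seealso [validate_dataset()], [read_dataset()], [example_dataset()]
#' @export
taxon_dataset <- function(usages, publications, species = NULL, variants = NULL) {
  usages <- as.data.frame(usages)
  missing_cols <- setdiff(USAGE_COLUMNS, names(usages))
  if (length(missing_cols)) {
    fail("usage table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  usages <- usages[USAGE_COLUMNS]
  for (col in USAGE_COLUMNS) usages[[col]] <- as.character(usages[[col]])
  rownames(usages) <- NULL

  publications <- as.data.frame(publications)
  for (col in c("key", "citation_text")) {
    if (is.null(publications[[col]])) publications[[col]] <- NA_character_
    publications[[col]] <- as.character(publications[[col]])
  }
  if (is.null(publications$year)) publications$year <- NA_integer_
  publications$year <- as.integer(publications$year)
  if (is.null(publications$recorded)) publications$recorded <- TRUE
  publications$recorded <- as.logical(publications$recorded)
  if (anyDuplicated(publications$key)) {
    fail("duplicate publication key(s): %s",
         paste(unique(publications$key[duplicated(publications$key)]), collapse = ", "))
  }
  rownames(publications) <- NULL

  if (is.null(species)) {
    species <- data.frame(species_id = character(0), binomial = character(0),
                          status = character(0), etymology = character(0))
  }
  species <- as.data.frame(species)
  for (col in c("species_id", "binomial", "status", "etymology")) {
    if (is.null(species[[col]])) species[[col]] <- rep(NA_character_, nrow(species))
    species[[col]] <- as.character(species[[col]])
  }
  if (anyDuplicated(species$species_id)) {
    fail("duplicate species id(s): %s",
         paste(unique(species$species_id[duplicated(species$species_id)]), collapse = ", "))
  }
  rownames(species) <- NULL

  if (is.null(variants)) variants <- variant_table()
  if (!inherits(variants, "variant_table")) fail("variants must be a variant_table")

  bad_mode <- setdiff(unique(usages$accepted_mode), c("explicit", "compute", "unknown"))
  if (length(bad_mode)) fail("unknown accepted_mode token(s): %s", paste(bad_mode, collapse = ", "))
  bad_ctx <- setdiff(unique(usages$context), context_kinds())
  if (length(bad_ctx)) fail("unknown context token(s): %s", paste(bad_ctx, collapse = ", "))

  structure(
    list(usages = usages, publications = publications,
         species = species, variants = variants),
    class = "taxon_dataset"
  )
}

#' @export
print.taxon_dataset <- function(x, ...) {
  cat(sprintf(
    "<taxon_dataset: %d usage records, %d publications, %d species, %d spelling variants>\n",
    nrow(x$usages), nrow(x$publications), nrow(x$species), nrow(x$variants$table)
  ))
  tab <- table(factor(x$usages$context, levels = context_kinds()))
  cat("  contexts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

issue_df <- function(code = character(0), severity = character(0),
                     pub_key = character(0), name_key = character(0),
                     message = character(0)) {
  data.frame(code = code, severity = severity, pub_key = pub_key,
              name_key = name_key, message = message)
}

add_issue <- function(issues, code, severity, pub_key, name_key, message) {
  rbind(issues, issue_df(code, severity, as.character(pub_key),
                         as.character(name_key), message))
}

#' Validate a dataset and report structural issues
#'
#' Runs all dataset-level consistency checks and returns a table of issues;
#' validation reports, it never throws. Errors are violations of the record
#' model (a compute marker on a non-citation record, duplicated keys without
#' distinct species ids, citation keys that match nothing in a recorded
#' publication, missing locations); warnings flag conditions the resolver
#' tolerates (dangling cited publications, same-year or anachronistic
#' citations, species ids absent from the species table).
#'
#' @param dataset A [taxon_dataset()].
#' @return Data frame with columns `code`, `severity` (`"error"` or
#'   `"warning"`), `pub_key`, `name_key`, `message`; zero rows when clean.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  u <- dataset$usages
  pubs <- dataset$publications
  issues <- issue_df()
  if (nrow(u) == 0L) return(issues)

  keyinfo <- tryCatch(parse_keys_df(u$name_key), error = function(e) NULL)
  if (is.null(keyinfo)) {
    for (i in seq_len(nrow(u))) {
      ok <- tryCatch({ parse_name_key(u$name_key[i]); TRUE }, error = function(e) FALSE)
      if (!ok) {
        issues <- add_issue(issues, "malformed_key", "error", u$pub_key[i],
                            u$name_key[i], sprintf("unparseable name key '%s'", u$name_key[i]))
      }
    }
    return(issues)
  }

  pub_year <- stats::setNames(pubs$year, pubs$key)

  for (i in seq_len(nrow(u))) {
    ctx <- u$context[i]
    is_cit <- identical(ctx, "citation")
    has_cit <- !is.na(u$cited_pub[i])

    if (is_cit && !has_cit) {
      issues <- add_issue(issues, "citation_without_target", "error",
                          u$pub_key[i], u$name_key[i],
                          "citation-context record has no cited publication")
    }
    if (!is_cit && has_cit) {
      issues <- add_issue(issues, "target_on_noncitation", "error",
                          u$pub_key[i], u$name_key[i],
                          sprintf("%s-context record carries a citation target", ctx))
    }
    if (ctx %in% c("specimen", "location") && is.na(u$place[i])) {
      issues <- add_issue(issues, "missing_place", "error",
                          u$pub_key[i], u$name_key[i],
                          sprintf("%s-context record lacks a geographic place", ctx))
    }
    if (identical(u$accepted_mode[i], "compute") && !is_cit) {
      issues <- add_issue(issues, "compute_on_noncitation", "error",
                          u$pub_key[i], u$name_key[i],
                          sprintf("accepted-species marker '=' on a %s-context record", ctx))
    }
    if (identical(u$accepted_mode[i], "explicit") && nrow(dataset$species) > 0L &&
        !(u$accepted_species[i] %in% dataset$species$species_id)) {
      issues <- add_issue(issues, "unknown_species", "warning",
                          u$pub_key[i], u$name_key[i],
                          sprintf("species id '%s' not in the species table", u$accepted_species[i]))
    }

    if (is_cit && has_cit) {
      cp <- u$cited_pub[i]
      if (!(cp %in% pubs$key)) {
        issues <- add_issue(issues, "dangling_pub", "warning",
                            u$pub_key[i], u$name_key[i],
                            sprintf("cited publication '%s' is not in the publication table", cp))
      } else {
        cy <- pub_year[[cp]]
        yy <- pub_year[u$pub_key[i]]
        yy <- if (length(yy)) yy[[1]] else NA_integer_
        if (is.na(cy)) {
          issues <- add_issue(issues, "missing_year", "error",
                              u$pub_key[i], u$name_key[i],
                              sprintf("cited publication '%s' has no year (needed for chronology)", cp))
        } else if (!is.na(yy) && cy > yy) {
          issues <- add_issue(issues, "anachronistic_citation", "warning",
                              u$pub_key[i], u$name_key[i],
                              sprintf("cites '%s' (%d) from a %d publication", cp, cy, yy))
        } else if (!is.na(yy) && cy == yy) {
          issues <- add_issue(issues, "same_year_citation", "warning",
                              u$pub_key[i], u$name_key[i],
                              sprintf("cites '%s' published in the same year (%d)", cp, cy))
        }
        ck <- u$cited_key[i]
        if (!is.na(ck) && ck != ".") {
          k <- tryCatch(parse_name_key(ck), error = function(e) NULL)
          if (is.null(k)) {
            issues <- add_issue(issues, "malformed_key", "error",
                                u$pub_key[i], u$name_key[i],
                                sprintf("unparseable cited key '%s'", ck))
          } else if (!is.na(k$base) && k$base > 0L) {
            rec <- pubs$recorded[pubs$key == cp]
            if (length(rec) && isTRUE(rec[[1]])) {
              hits <- which(u$pub_key == cp & keyinfo$base == k$base &
                              (is.na(k$context) | (!is.na(keyinfo$context) & keyinfo$context == k$context)))
              if (length(hits) == 0L) {
                issues <- add_issue(issues, "dangling_target", "error",
                                    u$pub_key[i], u$name_key[i],
                                    sprintf("cited key '%s' matches no usage in recorded publication '%s'", ck, cp))
              }
            }
          }
        }
      }
    }
  }

  # duplicated (publication, key) rows: legal only as a grouped set of
  # citation entries, or as a multi-species duplicate with distinct
  # explicit species ids
  dup_key <- paste(u$pub_key, u$name_key, sep = "\r")
  for (k in unique(dup_key[duplicated(dup_key)])) {
    rows <- which(dup_key == k)
    all_cit <- all(u$context[rows] == "citation" & u$accepted_mode[rows] == "compute")
    all_expl <- all(u$accepted_mode[rows] == "explicit")
    distinct_sp <- all_expl && !anyDuplicated(u$accepted_species[rows])
    if (!all_cit && !distinct_sp) {
      issues <- add_issue(issues, "duplicate_key", "error",
                          u$pub_key[rows[1]], u$name_key[rows[1]],
                          sprintf("%d rows share this key without distinct explicit species ids", length(rows)))
    }
  }

  rownames(issues) <- NULL
  issues
}

#' Worked-example datasets shipped with the package
#'
#' Two miniature datasets built from classic fiddler-crab literature
#' examples, stored as plain tab-delimited files under `inst/extdata` and
#' loaded through the normal file readers.
#'
#' `"fiddler"` holds three publications: Macnae 1966 (six records for five
#' names, among them *Uca bellator* used both for an Eastern Queensland
#' location and as a citation of name #2 in Hess 1865, *Gelasimus
#' signatus*), Hess 1865 (two location records), and a contextless
#' laboratory study. `"inversus"` holds the *Gelasimus inversus* example:
#' Alcock 1900 uses the name both for an East African location record
#' (today *Uca inversa*) and as a citation of Kingsley 1880's *Gelasimus
#' smithii* (today *Uca chlorophthalmus*), so one compound name maps to two
#' accepted species.
#'
#' @param which `"fiddler"` or `"inversus"`.
#' @return A [taxon_dataset()].
#' @examples
#' d <- example_dataset("fiddler")
#' nrow(d$usages)
#' @export
example_dataset <- function(which = c("fiddler", "inversus")) {
  which <- match.arg(which)
  dir <- system.file("extdata", which, package = "chresonym", mustWork = TRUE)
  read_dataset(dir)
}
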