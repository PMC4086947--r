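# Derived cross-reference structures: the two name indices, per-publication
# and per-species entries. Everything is computed from the usage table plus
# the resolved accepted species, and ordered deterministically (lowercased
# radix sort) so that repeated site builds are byte-identical.

usage_epithet <- function(name, variants) {
  p <- tryCatch(parse_compound_name(name), error = function(e) NULL)
  if (is.null(p) || is.na(p$specific)) return(NA_character_)
  canonical_epithet(p$specific, variants)
}

# one-line human summary of a record's context, used on binomial and
# publication pages; citations display the cited paper's verbatim names
context_summary <- function(dataset, i) {
  u <- dataset$usages
  switch(u$context[i],
    specimen = paste0("specimen: ", u$place[i],
                      if (!is.na(u$specimen_id[i])) paste0(" (", u$specimen_id[i], ")") else ""),
    location = paste0("location: ", u$place[i]),
    citation = {
      tg <- tryCatch(expand_citation_target(dataset, u$cited_pub[i], u$cited_key[i]),
                     error = function(e) integer(0))
      cited_names <- unique(u$name[tg])
      if (length(cited_names)) {
        paste0("citation: ", u$cited_pub[i], " [", paste(cited_names, collapse = "; "), "]")
      } else {
        paste0("citation: ", u$cited_pub[i], " | ", u$cited_key[i] %||% ".")
      }
    },
    none = "no context"
  )
}

check_resolution <- function(dataset, resolved) {
  if (!inherits(resolved, "resolved_usages") ||
      nrow(resolved) != nrow(dataset$usages)) {
    fail("resolved must be the resolve_all() output for this dataset")
  }
}

#' Build the specific-name index
#'
#' One entry per distinct canonical specific epithet occurring in the
#' dataset (the index never lists variant spellings as their own entries).
#' Each entry carries: the accepted species the epithet's usages resolve
#' to; the original source — the earliest publication using the epithet —
#' with the spelling it used; an etymology note passed through from the
#' species table; the list of all distinct compound names built on the
#' epithet (every variant spelling and genus placement); and notes on
#' homonymy (the epithet introduced as a new name more than once, detected
#' from type-description notes) and junior synonymy (the epithet's usages
#' resolve to species whose accepted binomial uses a different epithet).
#'
#' @param dataset A [taxon_dataset()].
#' @param resolved Output of [resolve_all()] on `dataset`.
#' @return Named list of entries, alphabetical by epithet; class
#'   `specific_index`.
#' @export
build_specific_index <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  u <- dataset$usages
  if (nrow(u) == 0L) return(structure(list(), class = "specific_index"))
  vt <- dataset$variants

  eps <- vapply(u$name, usage_epithet, character(1), variants = vt, USE.NAMES = FALSE)
  pub_year <- stats::setNames(dataset$publications$year, dataset$publications$key)
  sp_epithet <- vapply(dataset$species$binomial, function(b) {
    if (is.na(b)) NA_character_ else usage_epithet(b, vt)
  }, character(1), USE.NAMES = FALSE)

  out <- list()
  for (ep in c_sort(unique(eps[!is.na(eps)]))) {
    rows <- which(!is.na(eps) & eps == ep)
    species_ids <- c_sort(unique(stats::na.omit(resolved$accepted_species[rows])))
    binomials <- c_sort(unique(u$name[rows]))

    yrs <- unname(pub_year[u$pub_key[rows]])
    ord <- c_order(ifelse(is.na(yrs), .Machine$integer.max, yrs), u$pub_key[rows])
    first <- rows[ord[1L]]
    spelling <- parse_compound_name(u$name[first])$specific

    type_rows <- rows[!is.na(u$notes[rows]) &
                        grepl("type description", u$notes[rows], ignore.case = TRUE)]
    notes <- character(0)
    if (length(type_rows)) {
      intro <- unique(stats::na.omit(resolved$accepted_species[type_rows]))
      if (length(unique(u$pub_key[type_rows])) > 1L && length(intro) > 1L) {
        notes <- c(notes, sprintf("homonym: introduced as a new name in %s",
                                  paste(c_sort(unique(u$pub_key[type_rows])), collapse = " and ")))
      }
    }
    senior <- setdiff(species_ids, dataset$species$species_id[!is.na(sp_epithet) & sp_epithet == ep])
    if (length(senior)) {
      binom <- dataset$species$binomial[match(senior, dataset$species$species_id)]
      binom[is.na(binom)] <- senior[is.na(binom)]
      notes <- c(notes, sprintf("junior synonym of %s", paste(binom, collapse = ", ")))
    }

    etym <- dataset$species$etymology[match(species_ids, dataset$species$species_id)]
    etym <- etym[!is.na(etym)]

    out[[ep]] <- list(
      epithet = ep,
      species_ids = species_ids,
      original_spelling = spelling,
      original_source = u$pub_key[first],
      etymology = if (length(etym)) etym[[1L]] else NA_character_,
      binomials = binomials,
      notes = notes
    )
  }
  structure(out, class = "specific_index")
}

#' Build the compound/binomial-name index
#'
#' One entry per distinct verbatim compound name, where only variation in
#' capitalisation is ignored — every other spelling variant gets its own
#' entry. Each entry lists the usage rows bearing the name (publication,
#' locus, context summary, resolved accepted species with in-part flag)
#' and the set of distinct accepted species the name has been applied to,
#' derived from the resolved usages only.
#'
#' @inheritParams build_specific_index
#' @return Named list of entries (keyed by lowercased name), alphabetical;
#'   class `binomial_index`.
#' @export
build_binomial_index <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  u <- dataset$usages
  if (nrow(u) == 0L) return(structure(list(), class = "binomial_index"))
  pub_year <- stats::setNames(dataset$publications$year, dataset$publications$key)

  fold <- tolower(u$name)
  out <- list()
  for (key in c_sort(unique(fold))) {
    rows <- which(fold == key)
    yrs <- unname(pub_year[u$pub_key[rows]])
    ord <- c_order(ifelse(is.na(yrs), .Machine$integer.max, yrs), u$pub_key[rows], rows)
    rows <- rows[ord]
    display <- u$name[rows[1L]]
    tab <- data.frame(
      pub_key = u$pub_key[rows],
      name_key = u$name_key[rows],
      verbatim = u$name[rows],
      locus = u$locus[rows],
      context = u$context[rows],
      summary = vapply(rows, function(i) context_summary(dataset, i), character(1)),
      accepted_species = resolved$accepted_species[rows],
      in_part = resolved$in_part[rows],
      accepted_label = render_accepted(resolved$accepted_species[rows],
                                       resolved$in_part[rows])
    )
    out[[key]] <- list(
      name = display,
      rows = tab,
      species_ids = c_sort(unique(stats::na.omit(tab$accepted_species)))
    )
  }
  structure(out, class = "binomial_index")
}

#' Build per-publication entries
#'
#' One entry per publication in the publication table (recorded or not):
#' the bibliographic text, the usage rows it contains, and the cited-by
#' list — publications whose *name records* cite one of its names. Only
#' taxonomic name citations count: general citations to the publication
#' (zero-key targets) are excluded, so this is not a bibliometric citation
#' list.
#'
#' @inheritParams build_specific_index
#' @return Named list of entries keyed by publication key, sorted; class
#'   `publication_entries`.
#' @export
build_publication_entries <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  u <- dataset$usages
  pubs <- dataset$publications
  out <- list()
  for (pk in c_sort(pubs$key)) {
    rows <- which(u$pub_key == pk)
    tab <- data.frame(
      name = u$name[rows],
      name_key = u$name_key[rows],
      locus = u$locus[rows],
      context = u$context[rows],
      summary = vapply(rows, function(i) context_summary(dataset, i), character(1)),
      accepted_species = resolved$accepted_species[rows],
      in_part = resolved$in_part[rows],
      accepted_label = render_accepted(resolved$accepted_species[rows],
                                       resolved$in_part[rows])
    )
    citers <- u$pub_key[u$context == "citation" & !is.na(u$cited_pub) &
                          u$cited_pub == pk & !is.na(u$cited_key) &
                          u$cited_key != "0" & u$cited_key != "."]
    i <- match(pk, pubs$key)
    out[[pk]] <- list(
      key = pk,
      year = pubs$year[i],
      citation_text = pubs$citation_text[i],
      recorded = pubs$recorded[i],
      rows = tab,
      cited_by = c_sort(unique(citers))
    )
  }
  structure(out, class = "publication_entries")
}

#' Build per-species entries
#'
#' One entry per species in the species table: its accepted binomial and
#' status, an auto-generated synonym list (every distinct verbatim name,
#' capitalisation-folded, whose usages resolve to the species, minus the
#' accepted binomial itself), and the list of publications whose resolved
#' usages refer to the species — based on the estimated species the author
#' actually meant, not the name printed — together with how each
#' publication referenced it.
#'
#' @inheritParams build_specific_index
#' @return Named list keyed by species id, sorted; class `species_entries`.
#' @export
build_species_entries <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  u <- dataset$usages
  out <- list()
  for (sid in c_sort(dataset$species$species_id)) {
    i <- match(sid, dataset$species$species_id)
    binom <- dataset$species$binomial[i]
    rows <- which(!is.na(resolved$accepted_species) &
                    resolved$accepted_species == sid)
    names_used <- u$name[rows]
    syn <- names_used[is.na(binom) | tolower(names_used) != tolower(binom)]
    syn <- syn[!duplicated(tolower(syn))]

    pub_rows <- split(rows, u$pub_key[rows])
    publications <- lapply(pub_rows[c_sort(names(pub_rows))], function(rr) {
      list(pub_key = u$pub_key[rr[1L]],
           names_used = c_sort(unique(u$name[rr])),
           in_part = any(resolved$in_part[rr]))
    })
    out[[sid]] <- list(
      species_id = sid,
      binomial = binom,
      status = dataset$species$status[i],
      etymology = dataset$species$etymology[i],
      synonyms = c_sort(syn),
      publications = unname(publications)
    )
  }
  structure(out, class = "species_entries")
}

#' Build every cross-reference structure at once
#'
#' Convenience wrapper bundling the four entry collections plus the
#' dataset and resolution they were derived from; this is what
#' [generate_site()] consumes.
#'
#' @inheritParams build_specific_index
#' @return List of class `crossref_entries` with elements `specific`,
#'   `binomial`, `publications`, `species`, `dataset`, `resolved`.
#' @export
build_crossref <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  structure(
    list(
      specific = build_specific_index(dataset, resolved),
      binomial = build_binomial_index(dataset, resolved),
      publications = build_publication_entries(dataset, resolved),
      species = build_species_entries(dataset, resolved),
      dataset = dataset,
      resolved = resolved
    ),
    class = "crossref_entries"
  )
}

#' @export
print.crossref_entries <- function(x, ...) {
  cat(sprintf("<crossref_entries: %d specific names, %d compound names, %d publications, %d species>\n",
              length(x$specific), length(x$binomial),
              length(x$publications), length(x$species)))
  invisible(x)
}

#' Export the cross-reference entries as JSON
#'
#' @param entries A `crossref_entries` object from [build_crossref()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_crossref_json <- function(entries, path) {
  stopifnot(inherits(entries, "crossref_entries"))
  doc <- list(
    specific = unclass(entries$specific),
    binomial = unclass(entries$binomial),
    publications = unclass(entries$publications),
    species = unclass(entries$species)
  )
  jsonlite::write_json(doc, path, dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Summary statistics of a dataset
#'
#' Counts the quantities a curator watches: usage records and their
#' context-kind breakdown, publications per year, distinct canonical
#' epithets, distinct compound-name spellings (capitalisation-folded),
#' genera with and without variant folding, and accepted species.
#'
#' @inheritParams build_specific_index
#' @return A list of class `dataset_summary`.
#' @export
summarize_dataset <- function(dataset, resolved = resolve_all(dataset)) {
  check_resolution(dataset, resolved)
  u <- dataset$usages
  vt <- dataset$variants
  ctx <- table(factor(u$context, levels = context_kinds()))
  genera <- vapply(u$name, function(nm) {
    p <- tryCatch(parse_compound_name(nm), error = function(e) NULL)
    if (is.null(p)) NA_character_ else p$genus
  }, character(1), USE.NAMES = FALSE)
  genera <- genera[!is.na(genera)]
  eps <- vapply(u$name, usage_epithet, character(1), variants = vt, USE.NAMES = FALSE)

  structure(list(
    n_usages = nrow(u),
    n_publications = nrow(dataset$publications),
    n_recorded_publications = sum(dataset$publications$recorded),
    n_accepted_species = nrow(dataset$species),
    n_distinct_epithets = length(unique(eps[!is.na(eps)])),
    n_compound_names = length(unique(tolower(u$name))),
    n_genera_verbatim = length(unique(genera)),
    n_genera_folded = length(unique(vapply(genera, canonical_epithet,
                                           character(1), table = vt))),
    context_counts = as.list(ctx),
    context_proportions = if (nrow(u)) as.list(ctx / nrow(u)) else as.list(ctx),
    publications_per_year = as.list(table(dataset$publications$year)),
    n_resolved_unknown = sum(is.na(resolved$accepted_species)),
    n_in_part = sum(resolved$in_part)
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Dataset summary\n")
  cat(sprintf("  usage records:        %d\n", x$n_usages))
  cat(sprintf("  publications:         %d (%d recorded)\n",
              x$n_publications, x$n_recorded_publications))
  cat(sprintf("  accepted species:     %d\n", x$n_accepted_species))
  cat(sprintf("  specific epithets:    %d canonical\n", x$n_distinct_epithets))
  cat(sprintf("  compound names:       %d distinct spellings\n", x$n_compound_names))
  cat(sprintf("  genera:               %d verbatim, %d folded\n",
              x$n_genera_verbatim, x$n_genera_folded))
  for (k in names(x$context_counts)) {
    cat(sprintf("  context %-10s    %d (%.1f%%)\n", paste0(k, ":"),
                x$context_counts[[k]], 100 * x$context_proportions[[k]]))
  }
  cat(sprintf("  resolved unknown:     %d\n", x$n_resolved_unknown))
  cat(sprintf("  flagged in part:      %d\n", x$n_in_part))
  invisible(x)
}
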