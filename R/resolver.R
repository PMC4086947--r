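# Chronological propagation of accepted species through citation chains.
#
# Non-citation records carry their accepted species explicitly (or are
# marked unknown). Citation records are resolved from the records they
# cite, publication by publication in chronological order, so a single
# pass suffices: by the time a publication is processed, everything it can
# legitimately cite has already been resolved.

#' Expand a citation target into the cited usage rows
#'
#' A citation target addresses name contexts in an earlier publication.
#' A base-only key (`"3"`) expands to every usage of that name in the
#' cited publication; a full key (`"3.1"`) to the single matching context;
#' the zero key is a general citation to the publication and expands to
#' nothing; `"."` means the cited work has not been recorded. A specific
#' key that matches nothing in a recorded publication is an error
#' (dangling target).
#'
#' @param dataset A [taxon_dataset()].
#' @param cited_pub Cited publication key.
#' @param cited_key Cited name key string (`"3"`, `"3.1"`, `"0"`, `"."`).
#' @return Integer vector of row indices into `dataset$usages`, with
#'   attribute `reason`: `"ok"`, `"general"` (zero key), `"missing"`
#'   (`"."`), `"dangling_pub"` (publication not in the table), or
#'   `"unrecorded"` (publication known but its records not yet entered).
#' @export
expand_citation_target <- function(dataset, cited_pub, cited_key) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  stopifnot_scalar_chr(cited_pub, "cited publication key")
  res <- function(idx, reason) structure(idx, reason = reason)

  if (is.na(cited_key) || cited_key == ".") {
    return(res(integer(0), "missing"))
  }
  key <- parse_name_key(cited_key)
  if (!is.na(key$base) && key$base == 0L) {
    return(res(integer(0), "general"))
  }
  prow <- match(cited_pub, dataset$publications$key)
  if (is.na(prow)) {
    return(res(integer(0), "dangling_pub"))
  }
  if (!isTRUE(dataset$publications$recorded[prow])) {
    return(res(integer(0), "unrecorded"))
  }
  rows <- which(dataset$usages$pub_key == cited_pub)
  if (length(rows)) {
    ki <- parse_keys_df(dataset$usages$name_key[rows])
    hit <- !is.na(ki$base) & ki$base == key$base
    if (!is.na(key$context)) {
      hit <- hit & !is.na(ki$context) & ki$context == key$context
    }
    rows <- rows[hit]
  }
  if (length(rows) == 0L) {
    fail("dangling citation target: key '%s' matches no usage in recorded publication '%s'",
         cited_key, cited_pub)
  }
  res(rows, "ok")
}

# Pool the accepted names of everything a citing usage group cites and
# apply the plurality rules:
#   1. collect the accepted names over all cited contexts;
#   2. one name covers all     -> that name, not "in part";
#   3-4. unique plurality      -> that name, "in part";
#   5. tie -> a tied name matching the citing verbatim name (modulo
#      spelling variants)      -> that name, "in part";
#   6. otherwise the first tied name in order of first appearance among
#      the cited contexts      -> "in part".
# Unknown accepted names are left out of the count unless the whole pool
# is unknown. An empty pool (zero-key, unrecorded, or missing targets)
# resolves to unknown.
resolve_citation_group <- function(dataset, rows, accepted, resolved_flag,
                                   variants, lenient = FALSE, log = NULL) {
  u <- dataset$usages
  pub_year <- stats::setNames(dataset$publications$year, dataset$publications$key)
  pool <- character(0)
  prov_pub <- character(0)
  prov_key <- character(0)

  for (r in rows) {
    # anti-anachronism: a resolution may never consult a publication
    # later than the citing one, even if the cited record is explicit
    cy <- pub_year[u$cited_pub[r]]
    yy <- pub_year[u$pub_key[r]]
    if (length(cy) && length(yy) && !is.na(cy) && !is.na(yy) && cy > yy) {
      fail("chronology violation: '%s | %s' (%d) cites the later publication '%s' (%d)",
           u$pub_key[r], u$name_key[r], yy, u$cited_pub[r], cy)
    }
    targets <- tryCatch(
      expand_citation_target(dataset, u$cited_pub[r], u$cited_key[r]),
      error = function(e) e
    )
    if (inherits(targets, "error")) stop(targets)
    reason <- attr(targets, "reason")
    if (reason %in% c("general", "missing")) next
    if (reason %in% c("dangling_pub", "unrecorded")) {
      if (!is.null(log)) {
        log$push(u$pub_key[r], u$name_key[r], reason,
                 sprintf("citation to '%s' contributes nothing (%s)",
                         u$cited_pub[r], reason))
      }
      next
    }
    for (t in targets) {
      if (!resolved_flag[t]) {
        if (lenient) next
        fail("chronology violation: '%s | %s' cites '%s | %s', which is not yet resolved",
             u$pub_key[r], u$name_key[r], u$pub_key[t], u$name_key[t])
      }
      pool <- c(pool, accepted[t])
      prov_pub <- c(prov_pub, u$pub_key[t])
      prov_key <- c(prov_key, u$name_key[t])
    }
  }

  provenance <- data.frame(cited_pub = prov_pub, cited_key = prov_key,
                           species = pool)
  known <- pool[!is.na(pool)]
  if (length(known) == 0L) {
    return(list(accepted = NA_character_, in_part = FALSE, provenance = provenance))
  }
  distinct <- unique(known)             # first-appearance order
  if (length(distinct) == 1L) {
    return(list(accepted = distinct, in_part = FALSE, provenance = provenance))
  }
  counts <- vapply(distinct, function(s) sum(known == s), integer(1))
  tied <- distinct[counts == max(counts)]
  if (length(tied) == 1L) {
    return(list(accepted = tied, in_part = TRUE, provenance = provenance))
  }
  citing_name <- u$name[rows[1L]]
  binom <- dataset$species$binomial[match(tied, dataset$species$species_id)]
  binom[is.na(binom)] <- tied[is.na(binom)]
  for (j in seq_along(tied)) {
    ok <- tryCatch(names_match(citing_name, binom[[j]], variants),
                   error = function(e) FALSE)
    if (isTRUE(ok)) {
      return(list(accepted = tied[[j]], in_part = TRUE, provenance = provenance))
    }
  }
  list(accepted = tied[[1L]], in_part = TRUE, provenance = provenance)
}

make_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$push <- function(pub_key, name_key, code, message) {
    env$rows[[length(env$rows) + 1L]] <-
      data.frame(pub_key = pub_key, name_key = name_key,
                 code = code, message = message)
  }
  env$df <- function() {
    if (length(env$rows) == 0L) {
      data.frame(pub_key = character(0), name_key = character(0),
                 code = character(0), message = character(0))
    } else {
      do.call(rbind, env$rows)
    }
  }
  env
}

#' Chronological processing order of the publications
#'
#' Publications are ordered by ascending year, ties broken by publication
#' key — except that when publications within one year cite each other,
#' the within-year order is a topological order of those citation links
#' (deterministically tie-broken by key). A citation cycle within a year
#' group cannot be ordered and is an error listing the members.
#' Publications appearing in the usage table but absent from the
#' publication table sort last.
#'
#' @param dataset A [taxon_dataset()].
#' @return Character vector of publication keys.
#' @export
chronological_order <- function(dataset) {
  pubs <- dataset$publications
  u <- dataset$usages
  extra <- setdiff(unique(u$pub_key), pubs$key)
  keys <- c(pubs$key, extra)
  years <- c(pubs$year, rep(NA_integer_, length(extra)))

  out <- character(0)
  yr_sorted <- sort(unique(years[!is.na(years)]))
  groups <- c(as.list(yr_sorted), if (anyNA(years)) list(NA_integer_))
  for (y in groups) {
    members <- if (is.na(y)) keys[is.na(years)] else keys[!is.na(years) & years == y]
    members <- c_sort(members)
    if (length(members) <= 1L) {
      out <- c(out, members)
      next
    }
    # intra-group citation edges: cited -> citing
    cit <- u$context == "citation" & u$pub_key %in% members &
      !is.na(u$cited_pub) & u$cited_pub %in% members & u$cited_pub != u$pub_key
    deps <- unique(data.frame(citing = u$pub_key[cit], cited = u$cited_pub[cit]))
    remaining <- members
    while (length(remaining)) {
      free <- remaining[!(remaining %in% deps$citing[deps$cited %in% remaining])]
      if (length(free) == 0L) {
        fail("citation cycle among same-year publications: %s",
             paste(c_sort(remaining), collapse = ", "))
      }
      nxt <- free[[1L]]       # members already key-sorted
      out <- c(out, nxt)
      remaining <- setdiff(remaining, nxt)
    }
  }
  out
}

new_resolved <- function(dataset) {
  u <- dataset$usages
  n <- nrow(u)
  res <- data.frame(
    pub_key = u$pub_key,
    name_key = u$name_key,
    name = u$name,
    context = u$context,
    accepted_species = rep(NA_character_, n),
    in_part = logical(n)
  )
  res$provenance <- rep(list(NULL), n)
  res
}

finish_resolved <- function(res, log_df) {
  rownames(res) <- NULL
  attr(res, "log") <- log_df
  class(res) <- c("resolved_usages", class(res))
  res
}

#' Resolve accepted species for every record in a dataset
#'
#' Explicit and unknown assignments are copied through unchanged. Citation
#' records (accepted-species marker `"="`) are resolved with the
#' chronological plurality rules (see [resolve_citation()]), processing
#' publications in [chronological_order()] so that every cited context is
#' already resolved when it is consulted — the algorithm fills in all
#' species identities in a single pass, with no recursive drill-down
#' through transitive citations. Citation entries that share one
#' (publication, name key) pair are one logical citing usage and are
#' pooled together.
#'
#' @param dataset A [taxon_dataset()], ideally validated first.
#' @param variants Variant table used for the tie-match step; defaults to
#'   the dataset's own.
#' @param pub_order Optional explicit processing order (publication keys);
#'   any linear extension of the citation partial order yields identical
#'   output. Intended for testing.
#' @return A `resolved_usages` data frame, one row per usage row (same
#'   order): `accepted_species` (`NA` = unknown), `in_part`, and a
#'   `provenance` list column of (cited_pub, cited_key, species) tables
#'   for resolved citations. Attribute `"log"` holds a table of
#'   dangling/unrecorded citation events.
#' @examples
#' d <- example_dataset("fiddler")
#' r <- resolve_all(d)
#' subset(as.data.frame(r[1:6]), context == "citation")
#' @export
resolve_all <- function(dataset, variants = dataset$variants, pub_order = NULL) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  u <- dataset$usages
  res <- new_resolved(dataset)
  resolved_flag <- logical(nrow(u))
  log <- make_log()

  expl <- u$accepted_mode == "explicit"
  res$accepted_species[expl] <- u$accepted_species[expl]
  resolved_flag[expl | u$accepted_mode == "unknown"] <- TRUE

  order_keys <- pub_order %||% chronological_order(dataset)
  for (pk in order_keys) {
    rows <- which(u$pub_key == pk & u$accepted_mode == "compute")
    if (length(rows) == 0L) next
    groups <- split(rows, u$name_key[rows])
    for (g in groups[c_sort(names(groups))]) {
      out <- resolve_citation_group(dataset, g, res$accepted_species,
                                    resolved_flag, variants, log = log)
      res$accepted_species[g] <- out$accepted
      res$in_part[g] <- out$in_part
      for (r in g) res$provenance[[r]] <- out$provenance
      resolved_flag[g] <- TRUE
      if (is.na(out$accepted)) {
        log$push(pk, u$name_key[g[1L]], "unknown",
                 "citation record resolved to unknown (empty accepted-name pool)")
      }
    }
  }

  left <- which(!resolved_flag)
  if (length(left)) {
    fail("internal error: %d usage rows never resolved (first: %s | %s)",
         length(left), u$pub_key[left[1L]], u$name_key[left[1L]])
  }
  finish_resolved(res, log$df())
}

#' Resolve a single citation usage against already-resolved records
#'
#' Applies the plurality rules to one logical citing usage — all citation
#' entries in `dataset` sharing the given publication and name key — using
#' the accepted species already present in `resolved`. Exposed mainly for
#' inspection and for the fixed-point reference resolver
#' ([oracle_resolve()]); [resolve_all()] is the normal entry point.
#'
#' @param dataset A [taxon_dataset()].
#' @param pub_key,name_key Identify the citing usage group.
#' @param resolved A `resolved_usages` table covering the cited records.
#' @param variants Variant table for the tie-match step.
#' @return List with `accepted` (species id or `NA`), `in_part`, and
#'   `provenance`.
#' @export
resolve_citation <- function(dataset, pub_key, name_key, resolved,
                             variants = dataset$variants) {
  u <- dataset$usages
  rows <- which(u$pub_key == pub_key & u$name_key == name_key &
                  u$accepted_mode == "compute")
  if (length(rows) == 0L) {
    fail("no citation record '%s | %s'", pub_key, name_key)
  }
  # a compute row counts as resolved once resolve_all/oracle_resolve has
  # attached its provenance table (possibly empty); explicit and unknown
  # rows are always usable
  resolved_flag <- u$accepted_mode != "compute" |
    !vapply(resolved$provenance, is.null, logical(1))
  resolve_citation_group(dataset, rows, resolved$accepted_species,
                         resolved_flag, variants, lenient = FALSE)
}

#' Edit base records and recompute all resolutions
#'
#' Applies curatorial edits — changes to the explicit accepted species of
#' non-citation records, e.g. reassigning Red Sea *Uca annulipes* records
#' to *U. albimana* once the species is recognised — and re-runs
#' [resolve_all()], so every downstream citation record picks up the new
#' identity automatically.
#'
#' @param dataset A [taxon_dataset()].
#' @param edits Data frame with columns `pub_key`, `name_key`,
#'   `species_id`.
#' @param variants Variant table passed to [resolve_all()].
#' @return The new `resolved_usages` table; the edited dataset is attached
#'   as attribute `"dataset"`.
#' @export
update_and_repropagate <- function(dataset, edits, variants = dataset$variants) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  edits <- as.data.frame(edits)
  u <- dataset$usages
  for (i in seq_len(nrow(edits))) {
    rows <- which(u$pub_key == edits$pub_key[i] & u$name_key == edits$name_key[i])
    if (length(rows) == 0L) {
      fail("edit target '%s | %s' not found", edits$pub_key[i], edits$name_key[i])
    }
    if (any(u$context[rows] == "citation")) {
      fail("edit target '%s | %s' is a citation record; only base (non-citation) records may be edited",
           edits$pub_key[i], edits$name_key[i])
    }
    if (any(u$accepted_mode[rows] != "explicit")) {
      fail("edit target '%s | %s' has no explicit species assignment",
           edits$pub_key[i], edits$name_key[i])
    }
    u$accepted_species[rows] <- as.character(edits$species_id[i])
  }
  edited <- dataset
  edited$usages <- u
  out <- resolve_all(edited, variants)
  attr(out, "dataset") <- edited
  out
}

#' @export
print.resolved_usages <- function(x, ...) {
  n_unknown <- sum(is.na(x$accepted_species))
  cat(sprintf("<resolved_usages: %d records, %d in part, %d unknown>\n",
              nrow(x), sum(x$in_part), n_unknown))
  invisible(x)
}

#' Write resolved records to a flat file
#'
#' One row per usage: publication key, name key, verbatim name, accepted
#' species (with the literal suffix `" in part"` when flagged), and the
#' provenance triples as a JSON cell.
#'
#' @param resolved A `resolved_usages` table.
#' @param path Output path.
#' @param dialect A [record_dialect()].
#' @return The path, invisibly.
#' @export
write_resolved <- function(resolved, path, dialect = record_dialect()) {
  prov <- vapply(resolved$provenance, function(p) {
    if (is.null(p) || nrow(p) == 0L) return(".")
    as.character(jsonlite::toJSON(p, dataframe = "rows", na = "null"))
  }, character(1))
  df <- data.frame(
    pub_key = resolved$pub_key,
    name_key = resolved$name_key,
    name = resolved$name,
    accepted = render_accepted(resolved$accepted_species, resolved$in_part),
    in_part = ifelse(resolved$in_part, "1", "0"),
    provenance = prov
  )
  write_flat_table(df, path, dialect)
}

# "in part" is stored as a flag and becomes the literal suffix only at
# output time, keeping species identifiers clean for joins
render_accepted <- function(species, in_part) {
  out <- ifelse(is.na(species), "unknown", species)
  ifelse(!is.na(species) & in_part, paste0(out, " in part"), out)
}
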