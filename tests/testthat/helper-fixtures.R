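# in-code dataset builders used across the suite

usage_row <- function(pub, key, name, context, species = NA_character_,
                      cited_pub = NA_character_, cited_key = NA_character_,
                      place = "Somewhere", specimen_id = NA_character_,
                      locus = "p. 1", notes = NA_character_, mode = NULL) {
  if (is.null(mode)) {
    mode <- if (context == "citation") "compute"
            else if (is.na(species)) "unknown" else "explicit"
  }
  data.frame(
    pub_key = pub, name_key = key, name = name,
    common_name = NA_character_, locus = locus, context = context,
    place = if (context %in% c("specimen", "location")) place else NA_character_,
    specimen_id = if (context == "specimen") specimen_id else NA_character_,
    cited_pub = if (context == "citation") cited_pub else NA_character_,
    cited_key = if (context == "citation") cited_key else NA_character_,
    accepted_mode = mode,
    accepted_species = if (mode == "explicit") species else NA_character_,
    notes = notes
  )
}

make_pubs <- function(keys, years) {
  data.frame(key = keys, year = as.integer(years),
             citation_text = paste("Citation for", keys), recorded = TRUE)
}

make_species <- function(ids, binomials = paste("Uca", ids)) {
  data.frame(species_id = ids, binomial = binomials,
             status = "extant", etymology = NA_character_)
}

make_dataset <- function(rows, pubs, species = NULL, variants = NULL) {
  taxon_dataset(do.call(rbind, rows), pubs, species, variants)
}

# three-publication chain: 1930 location record (species X) cited by 1940,
# whose citation is in turn cited by 1950
chain_dataset <- function() {
  make_dataset(
    list(
      usage_row("C1930", "1", "Uca alpha", "location", species = "alpha"),
      usage_row("B1940", "1", "Uca alpha", "citation",
                cited_pub = "C1930", cited_key = "1"),
      usage_row("A1950", "1", "Uca alpha", "citation",
                cited_pub = "B1940", cited_key = "1")
    ),
    make_pubs(c("C1930", "B1940", "A1950"), c(1930, 1940, 1950)),
    make_species("alpha")
  )
}

resolved_lookup <- function(resolved, pub, key) {
  i <- which(resolved$pub_key == pub & resolved$name_key == key)
  resolved[i[1L], ]
}

# join resolver output against a synthetic ground-truth table
truth_check <- function(resolved, truth) {
  key <- paste(resolved$pub_key, resolved$name_key)
  got_species <- tapply(resolved$accepted_species, key, function(x) x[1L])
  got_in_part <- tapply(resolved$in_part, key, any)
  tkey <- paste(truth$pub_key, truth$name_key)
  list(
    species_ok = identical(as.character(got_species[tkey]), truth$expected_species),
    in_part_ok = identical(as.logical(got_in_part[tkey]), truth$expected_in_part)
  )
}

# a random linear extension of the publication-level citation partial order
random_linear_extension <- function(dataset) {
  u <- dataset$usages
  keys <- unique(c(dataset$publications$key, u$pub_key))
  cit <- u$context == "citation" & !is.na(u$cited_pub) & u$cited_pub != u$pub_key
  deps <- unique(data.frame(citing = u$pub_key[cit], cited = u$cited_pub[cit]))
  out <- character(0)
  remaining <- keys
  while (length(remaining)) {
    free <- remaining[!(remaining %in% deps$citing[deps$cited %in% remaining])]
    nxt <- free[[sample.int(length(free), 1L)]]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

site_tree_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  vapply(files, function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  }, character(1))
}
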