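fiddler <- example_dataset("fiddler")
fiddler_res <- resolve_all(fiddler)

test_that("the specific index folds variants into one entry per canonical epithet", {
  rows <- list(
    usage_row("A1850", "1", "Uca coarctata", "location", species = "coarctata"),
    usage_row("B1860", "1", "Gelasimus coarctatus", "location", species = "coarctata"),
    usage_row("C1870", "1", "Uca coartatus", "location", species = "coarctata"),
    usage_row("D1880", "1", "Uca corctata", "location", species = "coarctata")
  )
  vt <- variant_table(c("coarctatus", "coartatus", "corctata"),
                      rep("coarctata", 3))
  d <- make_dataset(rows, make_pubs(c("A1850", "B1860", "C1870", "D1880"),
                                    c(1850, 1860, 1870, 1880)),
                    make_species("coarctata"), vt)
  idx <- build_specific_index(d)
  expect_length(idx, 1L)
  expect_identical(idx[["coarctata"]]$epithet, "coarctata")
  expect_length(idx[["coarctata"]]$binomials, 4L)
  expect_identical(idx[["coarctata"]]$original_source, "A1850")
  expect_identical(idx[["coarctata"]]$species_ids, "coarctata")
})

test_that("empty datasets give empty indices and an all-zero summary", {
  d <- taxon_dataset(
    data.frame(pub_key = character(0), name_key = character(0),
               name = character(0), common_name = character(0),
               locus = character(0), context = character(0),
               place = character(0), specimen_id = character(0),
               cited_pub = character(0), cited_key = character(0),
               accepted_mode = character(0), accepted_species = character(0),
               notes = character(0)),
    data.frame(key = character(0), year = integer(0),
               citation_text = character(0), recorded = logical(0)))
  r <- resolve_all(d)
  expect_length(build_specific_index(d, r), 0L)
  expect_length(build_binomial_index(d, r), 0L)
  s <- summarize_dataset(d, r)
  expect_identical(s$n_usages, 0L)
  expect_identical(s$n_distinct_epithets, 0L)
  expect_identical(s$n_compound_names, 0L)
})

test_that("homonymy and junior-synonymy notes appear on specific entries", {
  rows <- list(
    usage_row("A1850", "1", "Gelasimus affinis", "location", species = "sp_one",
              notes = "type description"),
    usage_row("B1880", "1", "Uca affinis", "location", species = "sp_two",
              notes = "type description")
  )
  d <- make_dataset(rows, make_pubs(c("A1850", "B1880"), c(1850, 1880)),
                    make_species(c("sp_one", "sp_two"),
                                 c("Uca unica", "Uca secunda")))
  e <- build_specific_index(d)[["affinis"]]
  expect_true(any(grepl("homonym", e$notes)))
  expect_true(any(grepl("junior synonym", e$notes)))
})

test_that("the binomial index ignores only capitalization", {
  rows <- list(
    usage_row("A1850", "1", "Uca pugnax", "location", species = "pugnax"),
    usage_row("B1860", "1", "UCA PUGNAX", "location", species = "pugnax"),
    usage_row("C1870", "1", "Uca pugnax rapax", "location", species = "rapax")
  )
  d <- make_dataset(rows, make_pubs(c("A1850", "B1860", "C1870"),
                                    c(1850, 1860, 1870)),
                    make_species(c("pugnax", "rapax")))
  idx <- build_binomial_index(d)
  expect_length(idx, 2L)   # spelling variants are NOT folded, case is
  expect_identical(nrow(idx[["uca pugnax"]]$rows), 2L)
  expect_identical(idx[["uca pugnax"]]$name, "Uca pugnax")
})

test_that("Gelasimus inversus maps to the two recognized species", {
  d <- example_dataset("inversus")
  r <- resolve_all(d)
  e <- build_binomial_index(d, r)[["gelasimus inversus"]]
  expect_identical(e$species_ids, c("chlorophthalmus", "inversa"))
  # the citation row displays the cited paper's name, not its key
  expect_true(any(grepl("Gelasimus smithii", e$rows$summary)))
})

test_that("publication entries list names and name-record citers only", {
  entries <- build_publication_entries(fiddler, fiddler_res)
  mac <- entries[["Macnae1966"]]
  expect_setequal(unique(mac$rows$name),
                  c("Uca dussumieri", "Uca longidigitum", "Uca bellator",
                    "Uca unnamed sp. (pink claw)", "Uca unnamed sp. (red legs)"))
  expect_identical(entries[["Hess1865"]]$cited_by, "Macnae1966")
  expect_length(mac$cited_by, 0L)

  # zero-key (general) citations are not name citations
  d <- make_dataset(
    list(usage_row("P1880", "1", "Uca alpha", "location", species = "alpha"),
         usage_row("Q1900", "1", "Uca alpha", "citation",
                   cited_pub = "P1880", cited_key = "0")),
    make_pubs(c("P1880", "Q1900"), c(1880, 1900)), make_species("alpha"))
  expect_length(build_publication_entries(d)[["P1880"]]$cited_by, 0L)
})

test_that("species entries derive from resolved identities, not verbatim names", {
  entries <- build_species_entries(fiddler, fiddler_res)
  sig <- entries[["signata"]]
  pubs <- vapply(sig$publications, `[[`, character(1), "pub_key")
  expect_setequal(pubs, c("Hess1865", "Macnae1966"))
  # Macnae referred to signata as "Uca bellator"
  mac <- sig$publications[[which(pubs == "Macnae1966")]]
  expect_true("Uca bellator" %in% mac$names_used)
  # bellator appears in the synonym list, the accepted binomial does not
  expect_true("Uca bellator" %in% sig$synonyms)
  expect_false("Uca signata" %in% sig$synonyms)
})

test_that("every usage row lands in exactly one publication and one binomial entry", {
  for (seed in c(2, 9)) {
    g <- generate_synthetic_dataset(synth_params(n_publications = 10,
                                                 n_splits = 1, seed = seed))
    r <- resolve_all(g$dataset)
    bi <- build_binomial_index(g$dataset, r)
    pe <- build_publication_entries(g$dataset, r)
    n_bi <- sum(vapply(bi, function(e) nrow(e$rows), integer(1)))
    n_pe <- sum(vapply(pe, function(e) nrow(e$rows), integer(1)))
    expect_identical(n_bi, nrow(g$dataset$usages), label = paste("seed", seed))
    expect_identical(n_pe, nrow(g$dataset$usages), label = paste("seed", seed))
    # specific index is a coarsening of the binomial index
    expect_lte(length(build_specific_index(g$dataset, r)), length(bi))
  }
})

test_that("internal references in entries all target existing entries", {
  entries <- build_crossref(fiddler, fiddler_res)
  for (e in entries$specific) {
    expect_true(all(e$species_ids %in% names(entries$species)))
    expect_true(all(tolower(e$binomials) %in% names(entries$binomial)))
    expect_true(e$original_source %in% names(entries$publications))
  }
  for (e in entries$binomial) {
    expect_true(all(e$rows$pub_key %in% names(entries$publications)))
    expect_true(all(e$species_ids %in% names(entries$species)))
  }
  for (e in entries$species) {
    for (p in e$publications) {
      expect_true(p$pub_key %in% names(entries$publications))
    }
  }
})

test_that("the dataset summary counts match direct counts on the fixture", {
  s <- summarize_dataset(fiddler, fiddler_res)
  u <- fiddler$usages
  expect_identical(s$n_usages, 9L)
  expect_identical(s$context_counts$citation, sum(u$context == "citation"))
  expect_identical(s$context_counts$citation, 1L)
  expect_equal(s$context_proportions$citation, 1 / 9)
  expect_identical(s$n_compound_names, length(unique(tolower(u$name))))
  expect_identical(s$n_genera_verbatim, 2L)   # Uca, Gelasimus
  expect_identical(s$n_accepted_species, 7L)
})

test_that("summary recovers the generator's citation fraction", {
  g <- generate_synthetic_dataset(synth_params(n_publications = 80,
                                               records_per_pub = 4,
                                               citation_fraction = 0.7,
                                               n_species = 8, seed = 30))
  s <- summarize_dataset(g$dataset, resolve_all(g$dataset))
  expect_lt(abs(s$context_proportions$citation - 0.7), 0.06)
})

test_that("crossref JSON export is well formed", {
  f <- tempfile(fileext = ".json")
  export_crossref_json(build_crossref(fiddler, fiddler_res), f)
  doc <- jsonlite::read_json(f)
  expect_named(doc, c("specific", "binomial", "publications", "species"))
  expect_true("signata" %in% names(doc$species))
})
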