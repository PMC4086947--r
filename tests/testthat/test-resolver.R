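test_that("citation targets expand per key form", {
  d <- example_dataset("fiddler")
  both <- expand_citation_target(d, "Macnae1966", "3")
  expect_length(both, 2L)
  expect_setequal(d$usages$name_key[both], c("3.1", "3.2"))
  one <- expand_citation_target(d, "Macnae1966", "3.1")
  expect_length(one, 1L)
  expect_identical(d$usages$context[one], "location")
  expect_length(expand_citation_target(d, "Macnae1966", "0"), 0L)
  expect_identical(attr(expand_citation_target(d, "Macnae1966", "0"), "reason"), "general")
  expect_length(expand_citation_target(d, "Macnae1966", "."), 0L)
  expect_identical(attr(expand_citation_target(d, "Nowhere1800", "1"), "reason"), "dangling_pub")
  expect_error(expand_citation_target(d, "Macnae1966", "9"), "dangling")
  expect_error(expand_citation_target(d, "Macnae1966", "3.7"), "dangling")
})

test_that("the Macnae/Hess worked example resolves through the citation", {
  d <- example_dataset("fiddler")
  r <- resolve_all(d)
  b <- resolved_lookup(r, "Macnae1966", "3.2")
  expect_identical(b$accepted_species, "signata")
  expect_false(b$in_part)
  expect_identical(b$provenance[[1]]$cited_pub, "Hess1865")
  expect_identical(b$provenance[[1]]$species, "signata")
  # explicit assignments pass through with no in-part flag
  expl <- r[r$context != "citation", ]
  expect_identical(expl$accepted_species, d$usages$accepted_species[d$usages$context != "citation"])
  expect_false(any(expl$in_part))
})

test_that("a 1950 <- 1940 <- 1930 chain fills in from the base record", {
  r <- resolve_all(chain_dataset())
  expect_identical(resolved_lookup(r, "B1940", "1")$accepted_species, "alpha")
  expect_identical(resolved_lookup(r, "A1950", "1")$accepted_species, "alpha")
  expect_false(any(r$in_part))
})

test_that("a dataset with no citation records resolves to its own assignments", {
  d <- make_dataset(
    list(usage_row("P1900", "1", "Uca alpha", "location", species = "alpha"),
         usage_row("P1900", "2", "Uca beta", "specimen", species = "beta",
                   specimen_id = "MUS-1"),
         usage_row("P1900", "3", "Uca gamma", "none", species = NA_character_)),
    make_pubs("P1900", 1900), make_species(c("alpha", "beta")))
  r <- resolve_all(d)
  expect_identical(r$accepted_species, c("alpha", "beta", NA_character_))
  expect_false(any(r$in_part))
  expect_true(all(vapply(r$provenance, is.null, logical(1))))
})

make_plurality_dataset <- function(citing_name = "Uca alpha",
                                   variants = NULL) {
  # P1880 name 1 has three contexts: alpha, alpha, beta
  make_dataset(
    list(
      usage_row("P1880", "1.1", "Uca alpha", "location", species = "alpha"),
      usage_row("P1880", "1.2", "Uca alpha", "location", species = "alpha"),
      usage_row("P1880", "1.3", "Uca alpha", "location", species = "beta"),
      usage_row("Q1900", "1", citing_name, "citation",
                cited_pub = "P1880", cited_key = "1")
    ),
    make_pubs(c("P1880", "Q1900"), c(1880, 1900)),
    make_species(c("alpha", "beta")), variants)
}

test_that("plurality pooling: {alpha, alpha, beta} yields alpha in part", {
  r <- resolve_all(make_plurality_dataset())
  q <- resolved_lookup(r, "Q1900", "1")
  expect_identical(q$accepted_species, "alpha")
  expect_true(q$in_part)
  expect_identical(nrow(q$provenance[[1]]), 3L)
})

test_that("single covering name is not flagged in part; unknowns don't defeat it", {
  d <- make_dataset(
    list(
      usage_row("P1880", "1.1", "Uca alpha", "location", species = "alpha"),
      usage_row("P1880", "1.2", "Uca alpha", "none", species = NA_character_),
      usage_row("Q1900", "1", "Uca alpha", "citation",
                cited_pub = "P1880", cited_key = "1")
    ),
    make_pubs(c("P1880", "Q1900"), c(1880, 1900)), make_species("alpha"))
  q <- resolved_lookup(resolve_all(d), "Q1900", "1")
  expect_identical(q$accepted_species, "alpha")
  expect_false(q$in_part)
})

tie_dataset <- function(citing_name) {
  vt <- variant_table("betta", "beta")
  make_dataset(
    list(
      usage_row("P1880", "1", "Uca alpha", "location", species = "sp_alpha"),
      usage_row("P1885", "1", "Uca beta", "location", species = "sp_beta"),
      usage_row("Q1900", "1", citing_name, "citation",
                cited_pub = "P1880", cited_key = "1"),
      usage_row("Q1900", "1", citing_name, "citation",
                cited_pub = "P1885", cited_key = "1")
    ),
    make_pubs(c("P1880", "P1885", "Q1900"), c(1880, 1885, 1900)),
    make_species(c("sp_alpha", "sp_beta"), c("Uca alpha", "Uca beta")), vt)
}

test_that("ties defer to a spelling-variant match with the citing name", {
  q <- resolved_lookup(resolve_all(tie_dataset("Uca betta")), "Q1900", "1")
  expect_identical(q$accepted_species, "sp_beta")
  expect_true(q$in_part)
})

test_that("unmatched ties fall back to first appearance among cited contexts", {
  q <- resolved_lookup(resolve_all(tie_dataset("Uca gamma")), "Q1900", "1")
  expect_identical(q$accepted_species, "sp_alpha")
  expect_true(q$in_part)
})

test_that("a multi-species duplicate cited as a whole produces a tie", {
  d <- make_dataset(
    list(
      usage_row("Gould1841", "1", "Gelasimus vocans", "location", species = "pugilator"),
      usage_row("Gould1841", "1", "Gelasimus vocans", "location", species = "pugnax"),
      usage_row("Smith1870", "1", "Gelasimus pugnax", "citation",
                cited_pub = "Gould1841", cited_key = "1")
    ),
    make_pubs(c("Gould1841", "Smith1870"), c(1841, 1870)),
    make_species(c("pugilator", "pugnax")))
  q <- resolved_lookup(resolve_all(d), "Smith1870", "1")
  expect_identical(q$accepted_species, "pugnax")  # step 5: citing name matches
  expect_true(q$in_part)
})

test_that("zero-key and unrecorded citations resolve to unknown", {
  d <- make_dataset(
    list(
      usage_row("P1880", "1", "Uca alpha", "location", species = "alpha"),
      usage_row("Q1900", "1", "Uca alpha", "citation",
                cited_pub = "P1880", cited_key = "0"),
      usage_row("Q1900", "2", "Uca alpha", "citation",
                cited_pub = "P1880", cited_key = "."),
      usage_row("Q1900", "3", "Uca alpha", "citation",
                cited_pub = "Ghost1700", cited_key = "2")
    ),
    make_pubs(c("P1880", "Q1900"), c(1880, 1900)), make_species("alpha"))
  r <- resolve_all(d)
  for (k in c("1", "2", "3")) {
    q <- resolved_lookup(r, "Q1900", k)
    expect_true(is.na(q$accepted_species), label = k)
    expect_false(q$in_part, label = k)
  }
  log <- attr(r, "log")
  expect_true("dangling_pub" %in% log$code)
  expect_true("unknown" %in% log$code)
})

test_that("anachronistic citations are a chronology error", {
  d <- make_dataset(
    list(
      usage_row("A1950", "1", "Uca alpha", "location", species = "alpha"),
      usage_row("B1900", "1", "Uca alpha", "citation",
                cited_pub = "A1950", cited_key = "1")
    ),
    make_pubs(c("A1950", "B1900"), c(1950, 1900)), make_species("alpha"))
  expect_error(resolve_all(d), "chronology violation")
})

test_that("same-year citations order topologically; cycles are an error", {
  ok <- make_dataset(
    list(
      usage_row("Zfirst1900", "1", "Uca alpha", "location", species = "alpha"),
      usage_row("Asecond1900", "1", "Uca alpha", "citation",
                cited_pub = "Zfirst1900", cited_key = "1"),
      usage_row("Later1910", "1", "Uca alpha", "citation",
                cited_pub = "Asecond1900", cited_key = "1")
    ),
    make_pubs(c("Zfirst1900", "Asecond1900", "Later1910"), c(1900, 1900, 1910)),
    make_species("alpha"))
  r <- resolve_all(ok)
  expect_identical(resolved_lookup(r, "Later1910", "1")$accepted_species, "alpha")
  # key order alone would process Asecond1900 before Zfirst1900
  expect_identical(chronological_order(ok)[1], "Zfirst1900")

  cyc <- make_dataset(
    list(
      usage_row("A1900", "1", "Uca alpha", "citation",
                cited_pub = "B1900", cited_key = "1"),
      usage_row("B1900", "1", "Uca alpha", "citation",
                cited_pub = "A1900", cited_key = "1")
    ),
    make_pubs(c("A1900", "B1900"), c(1900, 1900)), make_species("alpha"))
  expect_error(resolve_all(cyc), "cycle")
})

test_that("editing base records repropagates through all citation levels", {
  d <- chain_dataset()
  r1 <- update_and_repropagate(d, data.frame(pub_key = "C1930", name_key = "1",
                                             species_id = "albimana"))
  expect_identical(resolved_lookup(r1, "A1950", "1")$accepted_species, "albimana")
  expect_identical(resolved_lookup(r1, "B1940", "1")$accepted_species, "albimana")

  # empty edit list is the identity
  r0 <- update_and_repropagate(d, data.frame(pub_key = character(0),
                                             name_key = character(0),
                                             species_id = character(0)))
  base <- resolve_all(d)
  expect_identical(r0$accepted_species, base$accepted_species)

  # edit then revert restores the original output
  d1 <- attr(r1, "dataset")
  r2 <- update_and_repropagate(d1, data.frame(pub_key = "C1930", name_key = "1",
                                              species_id = "alpha"))
  expect_identical(r2$accepted_species, base$accepted_species)
  expect_identical(r2$in_part, base$in_part)

  # citation records may not be edited
  expect_error(
    update_and_repropagate(d, data.frame(pub_key = "B1940", name_key = "1",
                                         species_id = "alpha")),
    "citation record")
})

test_that("in_part is true exactly when the pooled known names exceed one", {
  for (seed in 1:10) {
    g <- generate_synthetic_dataset(synth_params(n_publications = 12,
                                                 n_splits = seed %% 3,
                                                 seed = seed))
    r <- resolve_all(g$dataset)
    for (i in which(r$context == "citation")) {
      prov <- r$provenance[[i]]
      known <- unique(prov$species[!is.na(prov$species)])
      expect_identical(r$in_part[i], length(known) >= 2L,
                       label = sprintf("seed %d row %d", seed, i))
    }
    expect_false(any(r$in_part[r$context != "citation"]))
  }
})

test_that("resolution never consults later publications", {
  for (seed in 1:10) {
    g <- generate_synthetic_dataset(synth_params(n_publications = 12,
                                                 n_splits = 1, seed = seed))
    d <- g$dataset
    r <- resolve_all(d)
    yr <- stats::setNames(d$publications$year, d$publications$key)
    for (i in which(r$context == "citation")) {
      prov <- r$provenance[[i]]
      if (is.null(prov) || nrow(prov) == 0) next
      expect_true(all(yr[prov$cited_pub] <= yr[[r$pub_key[i]]]),
                  label = sprintf("seed %d row %d", seed, i))
    }
  }
})
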