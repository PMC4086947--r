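fiddler_dir <- system.file("extdata", "fiddler", package = "chresonym")

test_that("the fiddler usage file loads with the narrated structure", {
  u <- read_usages(file.path(fiddler_dir, "usages.tsv"))
  mac <- u[u$pub_key == "Macnae1966", ]
  expect_identical(nrow(mac), 6L)
  expect_identical(sum(mac$context == "citation"), 1L)
  expect_identical(sum(mac$context == "location"), 5L)
  cit <- mac[mac$context == "citation", ]
  expect_identical(cit$cited_pub, "Hess1865")
  expect_identical(cit$cited_key, "2")
  expect_identical(cit$accepted_mode, "compute")
})

test_that("read/write round-trips preserve every field and are byte-stable", {
  u <- read_usages(file.path(fiddler_dir, "usages.tsv"))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_usages(u, f1)
  u2 <- read_usages(f1)
  expect_identical(u2, u)
  write_usages(u2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("verbatim names survive untouched: case, diacritics, inner spacing", {
  rows <- list(
    usage_row("P1900", "1", "GELASIMUS Vocans", "location", species = "vocans"),
    usage_row("P1900", "2", "Uca güntheri", "location", species = "vocans"),
    usage_row("P1900", "3", "Uca  vocans  vocans", "location", species = "vocans")
  )
  d <- make_dataset(rows, make_pubs("P1900", 1900), make_species("vocans"))
  f <- tempfile(fileext = ".tsv")
  write_usages(d$usages, f)
  u2 <- read_usages(f)
  expect_identical(u2$name, d$usages$name)
})

test_that("missing cells are emitted as the period marker", {
  d <- make_dataset(list(usage_row("P1900", "1", "Uca vocans", "none")),
                    make_pubs("P1900", 1900))
  f <- tempfile(fileext = ".tsv")
  write_usages(d$usages, f)
  line <- readLines(f)[2]
  cells <- strsplit(line, "\t")[[1]]
  expect_identical(cells[6], ".")   # detail1
  expect_identical(cells[10], ".")  # common_name
  expect_identical(cells[8], "?")   # unknown accepted species
})

test_that("row-level problems error with line numbers and tokens", {
  f <- tempfile(fileext = ".tsv")
  hdr <- "pub_key\tname_key\tname\tlocus\tcontext\tdetail1\tdetail2\taccepted\tnotes"
  writeLines(c(hdr, "P1\t1\tUca x\tp. 1\tlocation\there\t.\tx\t.",
               "P1\t2\tUca y\tp. 2\tlocation\there\t.\tx"), f)
  expect_error(read_usages(f), "line 3")
  writeLines(c(hdr, "P1\t1\tUca x\tp. 1\tholotype\there\t.\tx\t."), f)
  expect_error(read_usages(f), "holotype")
  writeLines("", f)
  expect_error(read_usages(f), "header")
})

test_that("an empty file with header yields an empty table", {
  f <- tempfile(fileext = ".tsv")
  writeLines("pub_key\tname_key\tname\tlocus\tcontext\tdetail1\tdetail2\taccepted\tnotes", f)
  expect_identical(nrow(read_usages(f)), 0L)
})

test_that("'=' on a location record parses but validation flags it", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("pub_key\tname_key\tname\tlocus\tcontext\tdetail1\tdetail2\taccepted\tnotes",
               "P1\t1\tUca x\tp. 1\tlocation\there\t.\t=\t."), f)
  u <- read_usages(f)
  expect_identical(u$accepted_mode, "compute")
  d <- taxon_dataset(u, make_pubs("P1", 1900))
  expect_true("compute_on_noncitation" %in% validate_dataset(d)$code)
})

test_that("variant tables load, reject ambiguity, and default to identity", {
  vt <- read_variants(file.path(fiddler_dir, "variants.tsv"))
  expect_identical(canonical_epithet("coarctatus", vt), "coarctata")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("variant\tcanonical", "smithi\tsmithii", "smithi\tsmithae"), f)
  expect_error(read_variants(f), "ambiguous")

  writeLines("variant\tcanonical", f)
  vt0 <- read_variants(f)
  expect_identical(canonical_epithet("Anything", vt0), "anything")
})

test_that("publication and species tables round-trip", {
  p <- read_publications(file.path(fiddler_dir, "publications.tsv"))
  expect_identical(p$year[p$key == "Hess1865"], 1865L)
  s <- read_species(file.path(fiddler_dir, "species.tsv"))
  expect_true("signata" %in% s$species_id)
  fp <- tempfile(); fs <- tempfile()
  write_publications(p, fp); write_species(s, fs)
  expect_identical(read_publications(fp), p)
  expect_identical(read_species(fs), s)
})

test_that("the CSV dialect round-trips and unquotable cells are refused", {
  csv <- record_dialect(delimiter = ",")
  d <- example_dataset("inversus")
  f <- tempfile(fileext = ".csv")
  write_usages(d$usages, f, csv)
  expect_identical(read_usages(f, csv), d$usages)
  bad <- d$usages
  bad$notes[1] <- "contains, a comma"
  expect_error(write_usages(bad, f, csv), "delimiter")
})

test_that("whole-dataset directory and JSON exports work", {
  d <- example_dataset("fiddler")
  dir <- tempfile()
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_identical(d2$usages, d$usages)
  expect_identical(d2$publications, d$publications)
  expect_identical(d2$species, d$species)
  expect_identical(d2$variants$map, d$variants$map)
  jf <- tempfile(fileext = ".json")
  export_dataset_json(d, jf)
  doc <- jsonlite::read_json(jf)
  expect_length(doc$usages, nrow(d$usages))
  expect_length(doc$publications, 3L)
})

test_that("random synthetic datasets survive write/read round trips", {
  for (seed in 1:5) {
    g <- generate_synthetic_dataset(synth_params(n_publications = 10, seed = seed))
    dir <- tempfile()
    write_dataset(g$dataset, dir)
    d2 <- read_dataset(dir)
    expect_identical(d2$usages, g$dataset$usages, label = paste("seed", seed))
  }
})
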