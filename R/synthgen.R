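# Synthetic literature networks with planted ground truth.
#
# The generator emulates the structure of a contextual chresonymy
# database — publications over a span of years, each containing name-usage
# records in the four context classes, citation targets always pointing to
# strictly earlier publications — while keeping the expected resolution of
# every citation record derivable at construction time, independent of the
# resolver: every cited name group holds contexts of a single planted
# species, except for deliberately planted taxonomic splits whose mixed
# groups are built with an unambiguous 2-vs-1 plurality.

#' Parameters for the synthetic dataset generator
#'
#' @param n_publications Number of publications (>= 1).
#' @param years Length-2 integer vector, inclusive year range. Years are
#'   sampled without replacement when the range allows, minimising
#'   same-year ties.
#' @param n_species Number of planted species.
#' @param citation_fraction Proportion of records (in publications that
#'   have something earlier to cite) that are citations; the literature
#'   this emulates runs at roughly 0.7.
#' @param p_general_citation Probability that a citation to a
#'   multi-context name is base-only (all contexts) rather than to one
#'   specific context.
#' @param n_splits Number of planted taxonomic split events. Each creates
#'   a name group whose location records carry two explicit species (the
#'   original and a newly recognised segregate, 2-vs-1), plus a later
#'   base-only citation to it — a citation whose expected resolution is
#'   "in part".
#' @param variant_rate Probability that a record's verbatim epithet is a
#'   generated misspelling; every generated misspelling is registered in
#'   the emitted variant table.
#' @param records_per_pub Name records per publication.
#' @param force_year_ties If `TRUE`, years are drawn from a deliberately
#'   narrow range so that same-year citation ties occur and exercise the
#'   within-year ordering policy.
#' @param seed Integer seed; identical parameters and seed yield a
#'   byte-identical dataset.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_publications = 30L, years = c(1850L, 1980L),
                         n_species = 6L, citation_fraction = 0.7,
                         p_general_citation = 0.5, n_splits = 0L,
                         variant_rate = 0.1, records_per_pub = 3L,
                         force_year_ties = FALSE, seed = 1L) {
  p <- list(n_publications = as.integer(n_publications),
            years = as.integer(years), n_species = as.integer(n_species),
            citation_fraction = citation_fraction,
            p_general_citation = p_general_citation,
            n_splits = as.integer(n_splits), variant_rate = variant_rate,
            records_per_pub = as.integer(records_per_pub),
            force_year_ties = isTRUE(force_year_ties), seed = as.integer(seed))
  if (p$n_publications < 1L) fail("n_publications must be >= 1")
  if (length(p$years) != 2L || p$years[1] > p$years[2]) fail("years must be an increasing range")
  for (f in c("citation_fraction", "p_general_citation", "variant_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) fail("%s must be in [0, 1]", f)
  }
  if (p$n_publications == 1L && p$citation_fraction > 0) {
    fail("citations requested but n_publications = 1: nothing can be cited")
  }
  if (p$n_splits > 0L && p$n_publications < 3L) {
    fail("a planted split needs at least 3 publications")
  }
  structure(p, class = "synth_params")
}

rand_epithet <- function(n_chars = sample(5:8, 1L)) {
  paste(sample(letters, n_chars, replace = TRUE), collapse = "")
}

# sample() treats a length-1 numeric vector as 1:n; never do that
pick1 <- function(x) x[[sample.int(length(x), 1L)]]

# single-character edit, guaranteed different from the input
misspell <- function(epithet) {
  ch <- strsplit(epithet, "")[[1L]]
  repeat {
    i <- sample(length(ch), 1L)
    if (stats::runif(1) < 0.5 && length(ch) > 3L) {
      out <- paste(ch[-i], collapse = "")            # deletion
    } else {
      repl <- sample(letters, 1L)
      out <- ch; out[i] <- repl
      out <- paste(out, collapse = "")               # substitution
    }
    if (out != epithet) return(out)
  }
}

#' Generate a synthetic contextual name-usage dataset
#'
#' Builds a citation network of publications with planted ground truth
#' (see [synth_params()]). Citation targets always point to strictly
#' earlier publications in generation order, so the dataset is acyclic by
#' construction. All randomness is driven by `params$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param params A [synth_params()] object.
#' @param out_dir Optional directory; when given, the dataset files (in
#'   [read_dataset()] layout) and a `ground_truth.json` are written there.
#' @return List with `dataset` (a [taxon_dataset()]) and `truth`, a data
#'   frame with one row per logical record (citation entries sharing one
#'   key collapse to a single row): `pub_key`, `name_key`,
#'   `planted_species`, `expected_species` and `expected_in_part` (the
#'   resolution every citation record must reach; equal to the planted
#'   values for non-citation rows).
#' @export
generate_synthetic_dataset <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(params$seed)

  n_pub <- params$n_publications
  # species pool; split segregates are appended below
  epithets <- character(0)
  while (length(epithets) < params$n_species) {
    epithets <- unique(c(epithets, rand_epithet()))
  }
  species <- data.frame(species_id = epithets,
                        binomial = paste("Uca", epithets),
                        status = "extant", etymology = NA_character_)

  yr_lo <- params$years[1]; yr_hi <- params$years[2]
  if (params$force_year_ties) {
    yr_hi <- min(yr_hi, yr_lo + max(1L, n_pub %/% 3L))
  }
  span <- yr_hi - yr_lo + 1L
  years <- if (span >= n_pub && !params$force_year_ties) {
    sort(sample(yr_lo:yr_hi, n_pub))
  } else {
    sort(sample(yr_lo:yr_hi, n_pub, replace = TRUE))
  }
  pub_keys <- sprintf("Synth%03d", seq_len(n_pub))
  publications <- data.frame(key = pub_keys, year = years,
                             citation_text = sprintf("Synthetic author %03d (%d). A study.",
                                                     seq_len(n_pub), years),
                             recorded = TRUE)

  var_from <- character(0); var_to <- character(0)
  register_variant <- function(bad, good) {
    if (!(bad %in% var_from)) {
      var_from <<- c(var_from, bad); var_to <<- c(var_to, good)
    }
  }
  render_name <- function(sp) {
    ep <- sp
    if (stats::runif(1) < params$variant_rate) {
      bad <- misspell(ep)
      if (!(bad %in% species$species_id)) {
        register_variant(bad, ep)
        ep <- bad
      }
    }
    genus <- if (stats::runif(1) < 0.3) "Gelasimus" else "Uca"
    paste(genus, ep)
  }

  rows <- list()
  truth <- list()
  # per publication: groups[[pub]] = list(list(base, keys(raw per row),
  # species(per row), name)) — what later citations may target
  groups <- stats::setNames(vector("list", n_pub), pub_keys)
  next_base <- stats::setNames(integer(n_pub), pub_keys)

  add_pub_rows <- function(pub_i, specs) {
    # specs: list of group specs; each either
    #   list(kind="primary", species=chr vec (one per context), name=chr)
    #   list(kind="citation", cited_pub, cited_keys=chr vec, name, expected, expected_in_part)
    pk <- pub_keys[pub_i]
    for (g in specs) {
      base <- next_base[[pk]] + 1L
      next_base[[pk]] <<- base
      if (g$kind == "primary") {
        n_ctx <- length(g$species)
        keys <- if (n_ctx == 1L) as.character(base) else paste0(base, ".", seq_len(n_ctx))
        for (j in seq_len(n_ctx)) {
          ctx <- sample(c("location", "specimen", "none"), 1L, prob = c(0.6, 0.25, 0.15))
          rows[[length(rows) + 1L]] <<- data.frame(
            pub_key = pk, name_key = keys[j], name = g$name,
            common_name = NA_character_,
            locus = sprintf("p. %d", sample(1:400, 1L)),
            context = ctx,
            place = if (ctx == "none") NA_character_ else sprintf("Region %s", sample(LETTERS[1:6], 1L)),
            specimen_id = if (ctx == "specimen") sprintf("MUS-%04d", sample(1:9999, 1L)) else NA_character_,
            cited_pub = NA_character_, cited_key = NA_character_,
            accepted_mode = "explicit", accepted_species = g$species[j],
            notes = NA_character_)
          truth[[length(truth) + 1L]] <<- data.frame(
            pub_key = pk, name_key = keys[j], planted_species = g$species[j],
            expected_species = g$species[j], expected_in_part = FALSE)
        }
        groups[[pk]][[length(groups[[pk]]) + 1L]] <<-
          list(base = base, keys = keys, species = g$species, name = g$name)
      } else {
        # all citation entries of one logical citing usage share one key
        key_raw <- as.character(base)
        for (j in seq_along(g$cited_keys)) {
          rows[[length(rows) + 1L]] <<- data.frame(
            pub_key = pk, name_key = key_raw, name = g$name,
            common_name = NA_character_,
            locus = sprintf("p. %d", sample(1:400, 1L)),
            context = "citation",
            place = NA_character_, specimen_id = NA_character_,
            cited_pub = g$cited_pub[j], cited_key = g$cited_keys[j],
            accepted_mode = "compute", accepted_species = NA_character_,
            notes = NA_character_)
        }
        truth[[length(truth) + 1L]] <<- data.frame(
          pub_key = pk, name_key = key_raw, planted_species = g$expected,
          expected_species = g$expected, expected_in_part = g$expected_in_part)
        groups[[pk]][[length(groups[[pk]]) + 1L]] <<-
          list(base = base, keys = key_raw, species = g$expected, name = g$name)
      }
    }
  }

  # choose split sites: (source pub, citing pub) pairs with source < citing
  split_sources <- integer(0)
  if (params$n_splits > 0L) {
    split_sources <- sample(seq_len(max(1L, n_pub - 1L)), params$n_splits, replace = TRUE)
  }

  for (i in seq_len(n_pub)) {
    specs <- list()
    # planted splits anchored at this publication: a mixed group with
    # 2 contexts of the original species and 1 of the segregate
    for (s in which(split_sources == i)) {
      orig <- sample(species$species_id, 1L)
      seg <- paste0(orig, "i")           # newly recognised segregate
      if (!(seg %in% species$species_id)) {
        species <- rbind(species, data.frame(species_id = seg,
                                             binomial = paste("Uca", seg),
                                             status = "extant",
                                             etymology = NA_character_))
      }
      specs[[length(specs) + 1L]] <- list(kind = "primary",
                                          species = c(orig, orig, seg),
                                          name = paste("Uca", orig))
      attr(specs[[length(specs)]], "split_expected") <- orig
    }
    have_citable <- i > 1L && any(vapply(groups[seq_len(i - 1L)], length, integer(1)) > 0L)

    # an earlier name group whose contexts are purely one species; used
    # when a citation entry must join a group without disturbing its
    # expected resolution
    pick_pure_target <- function(expected) {
      cands <- list()
      for (pi in seq_len(i - 1L)) {
        for (g in groups[[pub_keys[pi]]]) {
          if (identical(unique(g$species), expected)) {
            cands[[length(cands) + 1L]] <- list(pub = pub_keys[pi], g = g)
          }
        }
      }
      if (length(cands) == 0L) return(NULL)
      c0 <- pick1(cands)
      key <- if (length(c0$g$keys) > 1L &&
                 stats::runif(1) >= params$p_general_citation) {
        pick1(c0$g$keys)
      } else {
        as.character(c0$g$base)
      }
      list(pub = c0$pub, key = key)
    }

    # each loop iteration is one record (one row); citation entries and
    # extra contexts join existing groups so the per-row citation share
    # is an honest Bernoulli draw at citation_fraction
    for (r in seq_len(params$records_per_pub)) {
      if (have_citable && stats::runif(1) < params$citation_fraction) {
        appendable <- which(vapply(specs, function(s) s$kind == "citation", logical(1)))
        if (length(appendable) && stats::runif(1) < 0.3) {
          j <- pick1(appendable)
          tgt <- pick_pure_target(specs[[j]]$expected)
          if (!is.null(tgt)) {
            specs[[j]]$cited_pub <- c(specs[[j]]$cited_pub, tgt$pub)
            specs[[j]]$cited_keys <- c(specs[[j]]$cited_keys, tgt$key)
            next
          }
        }
        cited_i <- pick1(which(vapply(groups[seq_len(i - 1L)], length, integer(1)) > 0L))
        cited_pk <- pub_keys[cited_i]
        g <- pick1(groups[[cited_pk]])
        multi <- length(g$keys) > 1L
        if (!multi || stats::runif(1) < params$p_general_citation) {
          cited_keys <- as.character(g$base)          # base-only
          pooled <- g$species
        } else {
          cited_keys <- pick1(g$keys)                 # one specific context
          pooled <- g$species[match(cited_keys, g$keys)]
        }
        distinct <- unique(pooled)
        expected <- if (length(distinct) == 1L) distinct else {
          counts <- vapply(distinct, function(s) sum(pooled == s), integer(1))
          distinct[which.max(counts)]    # mixed groups are built 2-vs-1
        }
        specs[[length(specs) + 1L]] <- list(
          kind = "citation", cited_pub = cited_pk, cited_keys = cited_keys,
          name = render_name(expected),
          expected = expected, expected_in_part = length(distinct) > 1L)
      } else {
        pure <- which(vapply(specs, function(s) {
          s$kind == "primary" && length(unique(s$species)) == 1L
        }, logical(1)))
        if (length(pure) && stats::runif(1) < 0.3) {
          j <- pick1(pure)     # one more context of an existing name
          specs[[j]]$species <- c(specs[[j]]$species, specs[[j]]$species[1L])
        } else {
          sp <- sample(species$species_id, 1L)
          specs[[length(specs) + 1L]] <- list(kind = "primary", species = sp,
                                              name = render_name(sp))
        }
      }
    }
    add_pub_rows(i, specs)
  }

  # guarantee every planted split is actually cited base-only by a later
  # publication (appended as an extra record in the last publication
  # unless a later one exists)
  for (s in seq_along(split_sources)) {
    src_i <- split_sources[s]
    src_pk <- pub_keys[src_i]
    mixed <- Filter(function(g) length(unique(g$species)) > 1L, groups[[src_pk]])
    for (g in mixed) {
      citing_i <- if (src_i < n_pub) pick1((src_i + 1L):n_pub) else n_pub
      counts <- table(g$species)
      expected <- names(counts)[which.max(counts)]
      extra <- list(list(kind = "citation", cited_pub = src_pk,
                         cited_keys = as.character(g$base),
                         name = g$name, expected = expected,
                         expected_in_part = TRUE))
      add_pub_rows(citing_i, extra)
    }
    groups[[src_pk]] <- Filter(function(g) length(unique(g$species)) == 1L,
                               groups[[src_pk]])
  }

  usages <- do.call(rbind, rows)
  # file order: chronological by (year, pub key), rows within a
  # publication in generation order
  ord <- c_order(match(usages$pub_key, pub_keys))
  usages <- usages[ord, , drop = FALSE]
  truth <- do.call(rbind, truth)

  variants <- variant_table(var_from, var_to,
                            rep("typographic", length(var_from)))
  dataset <- taxon_dataset(usages, publications, species, variants)

  if (!is.null(out_dir)) {
    write_dataset(dataset, out_dir)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  list(dataset = dataset, truth = truth, params = params)
}
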