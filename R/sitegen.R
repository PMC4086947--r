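# Static site generation. Every page is regenerated wholesale on each
# build from the cross-reference entries; identical input yields a
# byte-identical file tree. Pages are plain HTML5 assembled by small
# template functions; acceptance-relevant content is the text and the
# relative-link graph, not the markup.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# filename-safe slug: spaces to underscores, anything else unsafe
# percent-encoded
slug <- function(x) {
  x <- gsub("[[:space:]]+", "_", x)
  chars <- strsplit(x, "")[[1L]]
  paste(vapply(chars, function(ch) {
    if (grepl("^[A-Za-z0-9._-]$", ch)) ch
    else paste0("%", toupper(sprintf("%02x", utf8ToInt(ch))))
  }, character(1)), collapse = "")
}

page_path <- function(kind, key) {
  switch(kind,
    index_specific = "names/index_specific.html",
    index_binomial = "names/index_binomial.html",
    specific = paste0("names/sn_", slug(key), ".html"),
    binomial = paste0("names/", slug(key), ".html"),
    publication = paste0("references/", slug(key), ".html"),
    species = paste0("species/", slug(key), ".html")
  )
}

# relative href from one emitted page to another
rel_href <- function(from_path, to_path) {
  from_dir <- dirname(from_path)
  to_dir <- dirname(to_path)
  if (from_dir == to_dir) basename(to_path) else file.path("..", to_path)
}

html_page <- function(title, body_lines) {
  c("<!DOCTYPE html>",
    "<html lang=\"en\">",
    "<head>",
    "<meta charset=\"utf-8\">",
    paste0("<title>", html_escape(title), "</title>"),
    "</head>",
    "<body>",
    body_lines,
    "</body>",
    "</html>")
}

a_link <- function(from_path, kind, key, label = key) {
  href <- rel_href(from_path, page_path(kind, key))
  # file names may contain literal %xx from slug(); escape for the href
  href <- gsub("%", "%25", href, fixed = TRUE)
  sprintf("<a href=\"%s\">%s</a>", href, html_escape(label))
}

species_label <- function(entries, sid) {
  e <- entries$species[[sid]]
  if (!is.null(e) && !is.na(e$binomial)) e$binomial else sid
}

species_link_or_text <- function(entries, from_path, sid, in_part = FALSE) {
  suffix <- if (in_part) " in part" else ""
  if (is.na(sid)) return("unknown")
  if (!is.null(entries$species[[sid]])) {
    paste0(a_link(from_path, "species", sid, species_label(entries, sid)), suffix)
  } else {
    paste0(html_escape(sid), suffix)
  }
}

pub_link_or_text <- function(entries, from_path, pk) {
  if (!is.null(entries$publications[[pk]])) a_link(from_path, "publication", pk)
  else html_escape(pk)
}

usage_table_html <- function(entries, from_path, tab, first_col, first_cell) {
  lines <- c("<table>",
             sprintf("<tr><th>%s</th><th>Locus</th><th>Context</th><th>Accepted species</th></tr>",
                     html_escape(first_col)))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
      first_cell(i),
      html_escape(tab$locus[i] %||% "."),
      html_escape(tab$summary[i]),
      species_link_or_text(entries, from_path, tab$accepted_species[i], tab$in_part[i])
    ))
  }
  c(lines, "</table>")
}

render_index_specific <- function(entries) {
  path <- page_path("index_specific", "")
  items <- vapply(names(entries$specific), function(ep) {
    paste0("<li>", a_link(path, "specific", ep, ep), "</li>")
  }, character(1))
  html_page("Specific name index",
            c("<h1>Specific name index</h1>",
              "<p>Accepted spellings only; genus omitted.</p>",
              "<ul>", unname(items), "</ul>"))
}

render_index_binomial <- function(entries) {
  path <- page_path("index_binomial", "")
  items <- vapply(names(entries$binomial), function(k) {
    paste0("<li>", a_link(path, "binomial", entries$binomial[[k]]$name,
                          entries$binomial[[k]]$name), "</li>")
  }, character(1))
  html_page("Binomial and compound name index",
            c("<h1>Binomial/compound name index</h1>",
              "<p>Every variation of every name; only capitalization is ignored.</p>",
              "<ul>", unname(items), "</ul>"))
}

render_specific_page <- function(entries, ep) {
  e <- entries$specific[[ep]]
  path <- page_path("specific", ep)
  body <- c(sprintf("<h1>%s</h1>", html_escape(ep)))
  if (length(e$species_ids)) {
    body <- c(body, "<p>Currently recognized as: ",
              paste(vapply(e$species_ids, function(s)
                species_link_or_text(entries, path, s), character(1)),
                collapse = ", "),
              "</p>")
  }
  body <- c(body, sprintf("<p>Original spelling: <i>%s</i> in %s</p>",
                          html_escape(e$original_spelling %||% ep),
                          pub_link_or_text(entries, path, e$original_source)))
  if (!is.na(e$etymology)) {
    body <- c(body, sprintf("<p>Etymology: %s</p>", html_escape(e$etymology)))
  }
  for (n in e$notes) body <- c(body, sprintf("<p>Note: %s</p>", html_escape(n)))
  body <- c(body, "<h2>Binomials using this name</h2>", "<ul>")
  for (b in e$binomials) {
    body <- c(body, paste0("<li>", a_link(path, "binomial", b, b), "</li>"))
  }
  c_body <- c(body, "</ul>")
  html_page(paste("Specific name:", ep), c_body)
}

render_binomial_page <- function(entries, key) {
  e <- entries$binomial[[key]]
  path <- page_path("binomial", e$name)
  tab <- e$rows
  sn <- usage_epithet(e$name, entries$dataset$variants)
  body <- c(sprintf("<h1><i>%s</i></h1>", html_escape(e$name)))
  if (!is.na(sn) && !is.null(entries$specific[[sn]])) {
    body <- c(body, paste0("<p>Specific name: ", a_link(path, "specific", sn, sn), "</p>"))
  }
  body <- c(body,
            usage_table_html(entries, path, tab, "Publication",
                             function(i) pub_link_or_text(entries, path, tab$pub_key[i])))
  if (length(e$species_ids)) {
    body <- c(body, "<p>This name has been applied to: ",
              paste(vapply(e$species_ids, function(s)
                species_link_or_text(entries, path, s), character(1)), collapse = ", "),
              "</p>")
  }
  html_page(paste("Name:", e$name), body)
}

render_publication_page <- function(entries, pk) {
  e <- entries$publications[[pk]]
  path <- page_path("publication", pk)
  tab <- e$rows
  body <- c(sprintf("<h1>%s</h1>", html_escape(pk)),
            sprintf("<p>%s</p>", html_escape(e$citation_text %||% ".")))
  if (!isTRUE(e$recorded)) {
    body <- c(body, "<p>Name records for this publication have not yet been entered.</p>")
  }
  if (nrow(tab)) {
    body <- c(body,
              usage_table_html(entries, path, tab, "Name used",
                               function(i) {
                                 nm <- tab$name[i]
                                 k <- tolower(nm)
                                 if (!is.null(entries$binomial[[k]])) {
                                   a_link(path, "binomial", entries$binomial[[k]]$name,
                                          nm)
                                 } else html_escape(nm)
                               }))
  }
  body <- c(body, "<h2>Cited by</h2>")
  if (length(e$cited_by)) {
    body <- c(body, "<ul>",
              vapply(e$cited_by, function(cb)
                paste0("<li>", pub_link_or_text(entries, path, cb), "</li>"),
                character(1)),
              "</ul>")
  } else {
    body <- c(body, "<p>No name-record citations.</p>")
  }
  html_page(paste("Publication:", pk), body)
}

render_species_page <- function(entries, sid) {
  e <- entries$species[[sid]]
  path <- page_path("species", sid)
  body <- c(sprintf("<h1><i>%s</i></h1>", html_escape(e$binomial %||% sid)),
            sprintf("<p>Status: %s</p>", html_escape(e$status %||% ".")))
  if (!is.na(e$etymology %||% NA_character_)) {
    body <- c(body, sprintf("<p>Etymology: %s</p>", html_escape(e$etymology)))
  }
  body <- c(body, "<h2>Synonyms and name variants</h2>")
  if (length(e$synonyms)) {
    body <- c(body, "<ul>",
              vapply(e$synonyms, function(s) {
                k <- tolower(s)
                if (!is.null(entries$binomial[[k]])) {
                  paste0("<li>", a_link(path, "binomial", entries$binomial[[k]]$name, s), "</li>")
                } else paste0("<li>", html_escape(s), "</li>")
              }, character(1)),
              "</ul>")
  } else {
    body <- c(body, "<p>None recorded.</p>")
  }
  body <- c(body, "<h2>Publications referring to this species</h2>")
  if (length(e$publications)) {
    body <- c(body, "<ul>",
              vapply(e$publications, function(p) {
                paste0("<li>", pub_link_or_text(entries, path, p$pub_key),
                       " &mdash; as ", html_escape(paste(p$names_used, collapse = "; ")),
                       if (p$in_part) " (in part)" else "", "</li>")
              }, character(1)),
              "</ul>")
  } else {
    body <- c(body, "<p>No publications resolved to this species.</p>")
  }
  html_page(paste("Species:", e$binomial %||% sid), body)
}

#' Generate the static site
#'
#' Renders the full cross-referenced dataset as a static website: the two
#' name index pages plus one page per specific name, compound name,
#' publication, and species. The output directory's page set is wholly
#' regenerated on every run; two runs on identical input produce
#' byte-identical trees. Colliding generated file names (two entries
#' mapping to one path) are an error naming both sources.
#'
#' @param entries A `crossref_entries` object from [build_crossref()].
#' @param outdir Output directory (created if needed).
#' @return A `site_build` list: `outdir` and a `manifest` data frame with
#'   columns `path`, `kind`, `key`.
#' @seealso [check_links()]
#' @export
generate_site <- function(entries, outdir) {
  stopifnot(inherits(entries, "crossref_entries"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("names", "references", "species")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }

  pages <- list()
  add_page <- function(kind, key, lines) {
    path <- page_path(kind, key)
    if (!is.null(pages[[path]])) {
      fail("generated file name collision at '%s': '%s' (%s) vs '%s' (%s)",
           path, pages[[path]]$key, pages[[path]]$kind, key, kind)
    }
    pages[[path]] <<- list(kind = kind, key = key, lines = lines)
  }

  add_page("index_specific", "", render_index_specific(entries))
  add_page("index_binomial", "", render_index_binomial(entries))
  for (ep in names(entries$specific)) {
    add_page("specific", ep, render_specific_page(entries, ep))
  }
  for (k in names(entries$binomial)) {
    add_page("binomial", entries$binomial[[k]]$name, render_binomial_page(entries, k))
  }
  for (pk in names(entries$publications)) {
    add_page("publication", pk, render_publication_page(entries, pk))
  }
  for (sid in names(entries$species)) {
    add_page("species", sid, render_species_page(entries, sid))
  }

  for (path in names(pages)) {
    con <- file(file.path(outdir, path), open = "wb")
    writeLines(pages[[path]]$lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }

  manifest <- data.frame(
    path = names(pages),
    kind = vapply(pages, `[[`, character(1), "kind"),
    key = vapply(pages, `[[`, character(1), "key")
  )
  manifest <- manifest[c_order(manifest$path), , drop = FALSE]
  rownames(manifest) <- NULL
  structure(list(outdir = outdir, manifest = manifest), class = "site_build")
}

#' @export
print.site_build <- function(x, ...) {
  cat(sprintf("<site_build: %d pages under %s>\n", nrow(x$manifest), x$outdir))
  invisible(x)
}

#' Check a generated site for broken internal links
#'
#' Crawls the emitted pages and reports every relative link whose target
#' file does not exist. External links (`http:`, `https:`, `mailto:`) and
#' fragment-only links are ignored. A freshly generated build always
#' passes.
#'
#' @param build A `site_build` from [generate_site()], or an output
#'   directory path.
#' @return Data frame with columns `file`, `href`; zero rows when clean.
#' @export
check_links <- function(build) {
  if (inherits(build, "site_build")) {
    outdir <- build$outdir
    files <- build$manifest$path
  } else {
    outdir <- build
    files <- list.files(outdir, pattern = "\\.html$", recursive = TRUE)
  }
  broken_file <- character(0)
  broken_href <- character(0)
  for (f in files) {
    lines <- readLines(file.path(outdir, f), warn = FALSE)
    hrefs <- unlist(regmatches(lines, gregexpr("href=\"[^\"]*\"", lines)))
    hrefs <- sub("^href=\"", "", sub("\"$", "", hrefs))
    for (h in hrefs) {
      if (grepl("^(https?:|mailto:|#)", h)) next
      target <- utils::URLdecode(h)
      target_path <- file.path(dirname(file.path(outdir, f)), target)
      target_path <- normalizePath(target_path, mustWork = FALSE)
      if (!file.exists(target_path)) {
        broken_file <- c(broken_file, f)
        broken_href <- c(broken_href, h)
      }
    }
  }
  data.frame(file = broken_file, href = broken_href)
}
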