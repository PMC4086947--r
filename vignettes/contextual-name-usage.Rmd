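---
title: "Contextual name usage: model, resolution algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual name usage: model, resolution algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chresonym)
```

## The model

A chresonymy database records *usages*, not names: one row per occurrence
of a taxonomic name in a publication, annotated with the context of that
occurrence. Four context categories cover the literature:

* **specimen** — an explicit museum lot or deposition; the geographic
  place is recorded, plus the specimen id when available;
* **location** — a collecting locality or study site (experimental
  studies that discarded their animals are treated as locations);
* **citation** — the name is applied to an earlier author's usage; the
  record stores the cited publication key and a *name key* addressing
  the cited usage;
* **none** — no determinable context (bare mentions, studies with no
  locality, secondary spellings of a name the author used elsewhere
  deliberately).

Within a publication each distinct name gets a positive integer base key;
when a name is used in several contexts, each context appends a decimal
index (`3.1`, `3.2`, …). A citation may target the base (`3` — all
contexts of that name), one context (`3.1`), the whole publication with
no name context (the reserved key `0`), or an unrecorded work (`.`).
Keys are parsed as two integers split on the dot, never as floats —
`3.10` is context ten, distinct from `3.1` — and leading zeros are
rejected so parsing and serialisation round-trip exactly.

Every non-citation record carries the currently accepted species the
author was actually referring to (or an explicit *unknown*). Citation
records instead carry the marker `=`: their species is derived at
resolution time from the records they cite. When one record is known to
span several modern species (early coarse usages), the row is duplicated
with one explicit species id each.

Verbatim names are sacred: spelling, capitalisation, diacritics and
internal whitespace are stored exactly as printed and are never
normalised in the primary records. A separate variant table maps
spellings (gender-agreement forms, typos) to canonical epithets; the
table is closed at load time so `canonical_epithet()` is idempotent, and
untabled epithets pass through unchanged because the database
deliberately contains misspellings nobody has tabled yet.

## Resolution

`resolve_all()` copies explicit and unknown assignments through, then
processes citation records publication by publication in ascending
(year, key) order. All citation entries sharing a (publication, name key)
pair form one logical citing usage; their cited contexts are pooled and
the plurality rules applied:

1. collect the accepted names of all cited contexts;
2. one name covering the pool wins, with `in_part = FALSE`;
3–4. otherwise a unique plurality wins, `in_part = TRUE`;
5. on a tie, a tied species whose accepted binomial matches the *citing*
   verbatim name (modulo the variant table, ignoring genus) wins;
6. otherwise the first tied name in order of first appearance among the
   cited contexts wins.

`in_part` is true exactly when the pool contains two or more distinct
known names. The flag is stored as a boolean and rendered as the literal
suffix `" in part"` only at output time (`write_resolved()`, site
pages), keeping species identifiers clean for joins.

Chronological processing makes a single pass sufficient: everything a
record may cite is resolved before it is consulted. The historical
alternative — recursively drilling down through transitive citations to
basal specimen records — is implemented only as the test oracle's
conceptual contrast, not exposed: early monographs carried enormous
citation lists under one or two coarse names, and drilling through them
overrides the narrower concept the citing author actually meant.

### Decisions the sources left open

* **Unknowns in the pool.** Cited contexts whose accepted species is
  unknown are excluded from the plurality count unless the whole pool is
  unknown. Letting "unknown" outvote, or tie with, a real name would
  manufacture false in-part flags from missing data.
* **Same-year citations.** Chronology does not order publications from
  one year. We allow same-year citations (they exist in real
  literature), order year-tie groups topologically along their internal
  citation links with the publication key as deterministic tie-break,
  and treat a genuine cycle within a year group as an error listing its
  members. This is an artifact policy, not a claim about the original
  dataset.
* **Step 6 determinism.** "First name in the plurality set" is pinned to
  first appearance among the cited contexts in the cited publication's
  record order; the same rule breaks the residual tie if step 5 matches
  more than one tied name. Any reproducible convention would do; this
  one needs no extra state.
* **Anachronisms.** A citation to a strictly later publication is flagged
  by `validate_dataset()` and is a hard error in the resolver, because
  honouring it would violate the rule that resolution never consults
  publications later than the citing one.
* **Multi-species duplicates.** Duplicated rows are disambiguated by
  their distinct explicit species ids in the accepted-species column;
  we deliberately do not also tag the key column (the id would be stored
  twice). Validation enforces distinctness. In the plurality count each
  duplicated row is one cited context, i.e. duplicates are counted
  per-row; whether the original system weighted them once or per-row is
  unknowable from the description, and per-row counting is what makes a
  generally-cited duplicate produce the expected two-species tie.
* **One shared variant table.** Specific and subspecific epithets share
  a single variant table; nothing in the record layout suggests separate
  tables, and gender agreement affects both alike.
* **Genus-insensitive matching.** `names_match()` compares canonical
  specific (and, when both present, subspecific) epithets and ignores
  the genus: the wholesale migration of epithets between *Gelasimus* and
  *Uca* makes the genus uninformative for identity. Only capitalisation
  is ignored in the compound-name index, per the same convention.

## File formats

The canonical dialect is tab-delimited UTF-8 with a header and no
quoting; a period marks missing data in any cell (columns are never left
blank), and a CSV delimiter option exists for interchange. Because no
quoting is performed, cells may not contain the delimiter — the writer
refuses them rather than silently corrupting verbatim strings. Citation
context details occupy two cells (cited publication key; cited name
key), mirroring the two detail columns of the record layout. Files
written by `write_usages()` round-trip byte-identically. The original
spreadsheet's exact column census is not fully documented (two rarely
used columns are known to exist but unspecified); this layout is a
faithful reconstruction, with the common-name column appended last.

## The synthetic generator, and what a green test establishes

`generate_synthetic_dataset()` emulates the *structure* of the real
database: publications spread over a year range, each contributing a few
records; ~70% of records citations (the generator draws one Bernoulli
per record at `citation_fraction`, so the realised share is the
requested share minus only the first publication's forced non-citations);
citations pointing only at strictly earlier publications (acyclic by
construction); occasional multi-context names; misspelled epithets at
`variant_rate`, every one registered in the emitted variant table; and
planted taxonomic splits — a name group whose location records carry two
explicit species 2-vs-1, plus a later base-only citation of it, which
must resolve to the majority species with `in_part = TRUE`.

Ground truth is derivable at construction time because cited groups are
kept single-species except the planted mixed groups, whose 2-vs-1 design
has an unambiguous plurality; no tie-breaking logic is duplicated in the
generator. Split runs add a handful of rows outside the per-record
Bernoulli draw, so the citation-share recovery test uses split-free
parameters.

What the generator does *not* model: realistic description rates or
author behaviour, homonymy, unregistered misspellings (available as a
stress flag only in the sense that untabled epithets pass through
matching unchanged), multilingual citation practices, or location-name
ambiguity. A green property suite therefore establishes that the
resolver implements the stated rules exactly (fixed-point oracle
equivalence, planted-truth recovery, order independence over linear
extensions of the citation partial order, anti-anachronism) — not that
those rules recover the right species in messy real literature, which
the original curators checked by manual inspection.

## Numerical and procedural choices

* All randomness in the generator flows from one integer seed; the
  caller's RNG state is saved and restored, and identical parameters
  plus seed give byte-identical files.
* Index ordering and site output use locale-independent radix sorting on
  lowercased keys; repeated builds on identical input are byte-identical
  (hash-compared in tests), which makes site diffs meaningful.
* Page file names replace whitespace with underscores and percent-encode
  any other non-`[A-Za-z0-9._-]` byte; `%` inside an href is escaped as
  `%25`. Name collisions between generated pages abort the build naming
  both source entries.
* The degenerate inputs are defined, not accidental: an empty dataset
  yields empty indices, an all-zero summary, and a site of exactly the
  two index pages; an empty variant table is the identity; a citation
  pool that is empty (zero key, `.`, unrecorded or dangling cited work)
  resolves to unknown with `in_part = FALSE` and a log entry.

## Known limitations

* Publication keys are opaque case-sensitive strings; the author+year
  convention is not enforced.
* The resolver loads the whole dataset in memory; fine for the tens of
  thousands of rows this class of database reaches, not engineered
  beyond that.
* Homonym detection in the specific-name index relies on
  "type description" notes; datasets that do not annotate type
  descriptions get no homonymy notes.
* Media (photo/video) content is out of scope; species pages simply do
  not reference media directories, so link checking stays meaningful.
* Citations *within* one publication (a record citing another record of
  its own publication) are not supported and surface as chronology
  errors.
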