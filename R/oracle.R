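#' Fixed-point reference resolver
#'
#' Naive alternative to [resolve_all()] used as an independent check:
#' instead of ordering publications chronologically, it repeatedly
#' re-resolves every citation group against the current state until
#' nothing changes. On any acyclic dataset this converges to the same
#' answer as the single chronological pass; it exists purely so the two
#' routes can be compared in tests and is far slower on deep citation
#' chains. (The historical recursive drill-down through transitive
#' citations is deliberately not implemented anywhere user-facing: chasing
#' citations to their basal works overrides the narrower context the
#' citing author actually meant.)
#'
#' @param dataset A [taxon_dataset()].
#' @param variants Variant table for the tie-match step.
#' @param max_iter Iteration cap; non-convergence (a citation cycle)
#'   is an error. Defaults to the number of citation groups plus two.
#' @return A `resolved_usages` table, comparable row-for-row with the
#'   output of [resolve_all()].
#' @export
oracle_resolve <- function(dataset, variants = dataset$variants, max_iter = NULL) {
  stopifnot(inherits(dataset, "taxon_dataset"))
  u <- dataset$usages
  res <- new_resolved(dataset)
  log <- make_log()

  expl <- u$accepted_mode == "explicit"
  res$accepted_species[expl] <- u$accepted_species[expl]
  resolved_flag <- u$accepted_mode != "compute"

  comp <- which(u$accepted_mode == "compute")
  group_ids <- unique(paste(u$pub_key[comp], u$name_key[comp], sep = "\r"))
  groups <- lapply(group_ids, function(g) {
    comp[paste(u$pub_key[comp], u$name_key[comp], sep = "\r") == g]
  })
  if (is.null(max_iter)) max_iter <- length(groups) + 2L

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      fail("fixed-point resolver did not converge after %d iterations (citation cycle?)", max_iter)
    }
    changed <- FALSE
    for (g in groups) {
      out <- resolve_citation_group(dataset, g, res$accepted_species,
                                    resolved_flag, variants, lenient = TRUE)
      if (!identical(out$accepted, res$accepted_species[g[1L]]) ||
          !identical(out$in_part, res$in_part[g[1L]]) ||
          is.null(res$provenance[[g[1L]]])) {
        changed <- TRUE
      }
      res$accepted_species[g] <- out$accepted
      res$in_part[g] <- out$in_part
      for (r in g) res$provenance[[r]] <- out$provenance
      resolved_flag[g] <- TRUE
    }
    if (!changed) break
  }

  finish_resolved(res, log$df())
}
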