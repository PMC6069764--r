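# Record-level filters and per-miRNA tallies.

#' Filter records by publication support
#'
#' Retains records supported by at least `min_publications` distinct
#' publication identifiers. The roster is unchanged: a miRNA whose records
#' are all dropped remains under study with zero targets.
#'
#' @param corpus a `target_corpus`.
#' @param min_publications non-negative count; 0 is the identity.
#' @return the filtered `target_corpus`.
#' @export
support_filter <- function(corpus, min_publications = 1L) {
  stopifnot(inherits(corpus, "target_corpus"))
  if (min_publications < 0) usage_error("min_publications must be >= 0")
  n_pub <- vapply(split_multi(corpus$records$pmids), function(p)
    length(unique(p)), integer(1))
  keep <- n_pub >= min_publications
  target_corpus(corpus$records[keep, , drop = FALSE], corpus$roster)
}

#' Filter records by MeSH annotation under a match mode
#'
#' Computes the expansion set of the query term under `mode` and retains
#' exactly the records whose `mesh_term_ids` intersect it. Containment is
#' literal: a record annotated only with a *descendant* of the query term
#' does not survive an exact or broader match on the query term — no
#' subsumption inference is applied to the record's own annotations.
#'
#' @param corpus a `target_corpus`.
#' @param ontology a `mesh_ontology`.
#' @param term_id query term identifier (must exist in the ontology).
#' @param mode one of `"exact"`, `"broader"`, `"narrower"`.
#' @param max_depth expansion depth for broader/narrower; `Inf` = unbounded.
#' @return the filtered `target_corpus` (roster unchanged).
#' @export
#' @examples
#' corp <- paper_corpus()
#' ont <- paper_ontology()
#' n_records(mesh_filter(corp, ont, "leukemia", "exact"))
mesh_filter <- function(corpus, ontology, term_id,
                        mode = c("exact", "broader", "narrower"),
                        max_depth = Inf) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "target_corpus"))
  expansion <- mesh_expand(ontology, term_id, mode, max_depth)
  anns <- split_multi(corpus$records$mesh_term_ids)
  keep <- vapply(anns, function(a) any(a %in% expansion), logical(1))
  target_corpus(corpus$records[keep, , drop = FALSE], corpus$roster)
}

#' Tally distinct targets per roster miRNA
#'
#' Counts distinct (gene, evidence) pairs per miRNA, one row per roster
#' member (zero counts included). Rows are ordered by descending total
#' (predicted + validated), ties by descending validated count, then by
#' `mirna_id`.
#'
#' @param corpus a `target_corpus`.
#' @return data.frame with columns `mirna_id`, `predicted_count`,
#'   `validated_count`.
#' @export
tally <- function(corpus) {
  stopifnot(inherits(corpus, "target_corpus"))
  recs <- unique(corpus$records[, c("mirna_id", "gene_symbol", "evidence")])
  count_for <- function(id, ev) {
    sum(recs$mirna_id == id & recs$evidence == ev)
  }
  out <- data.frame(
    mirna_id = corpus$roster,
    predicted_count = vapply(corpus$roster, count_for, integer(1),
                             ev = "predicted"),
    validated_count = vapply(corpus$roster, count_for, integer(1),
                             ev = "validated"),
    stringsAsFactors = FALSE
  )
  ord <- order(-(out$predicted_count + out$validated_count),
               -out$validated_count, out$mirna_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
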