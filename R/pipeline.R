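# Multi-round filtering pipeline: plans, execution, reduction statistics,
# prioritization heuristic, and report rendering.

#' Describe one filtering round
#'
#' @param label unique round label (used in report file names).
#' @param term_id query term identifier.
#' @param mode one of `"exact"`, `"broader"`, `"narrower"`.
#' @param max_depth positive expansion depth or `Inf` for unbounded.
#' @return a `filter_round` list.
#' @export
filter_round <- function(label, term_id,
                         mode = c("exact", "broader", "narrower"),
                         max_depth = Inf) {
  mode <- match.arg(mode)
  if (!nzchar(label)) usage_error("round label must be non-empty")
  if (!nzchar(term_id)) usage_error("round term_id must be non-empty")
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1) {
    usage_error("max_depth must be a positive count or Inf")
  }
  structure(list(label = label, term_id = term_id, mode = mode,
                 max_depth = max_depth),
            class = "filter_round")
}

#' Assemble a pipeline plan
#'
#' A plan is the declarative description of a run: a publication-support
#' threshold applied once up front, then an ordered list of MeSH-expansion
#' rounds, with optional removal of miRNAs left with zero targets after each
#' round.
#'
#' @param rounds list of [filter_round()] objects (at least one); labels
#'   must be unique.
#' @param min_publications non-negative support threshold (default 1:
#'   records must be backed by at least one publication).
#' @param exclude_zero_target_mirnas drop miRNAs with zero surviving records
#'   from the working roster after each round (default `TRUE`).
#' @param label plan label used in rendered file names.
#' @return a `pipeline_plan` object.
#' @export
pipeline_plan <- function(rounds, min_publications = 1L,
                          exclude_zero_target_mirnas = TRUE,
                          label = "plan") {
  if (!is.list(rounds) || !length(rounds)) {
    usage_error("a plan needs at least one round")
  }
  if (inherits(rounds, "filter_round")) rounds <- list(rounds)
  ok <- vapply(rounds, inherits, logical(1), what = "filter_round")
  if (!all(ok)) usage_error("rounds must be filter_round objects")
  labels <- vapply(rounds, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    usage_error(sprintf("duplicate round label: '%s'",
                        labels[duplicated(labels)][1L]))
  }
  if (min_publications < 0) usage_error("min_publications must be >= 0")
  structure(list(label = label, rounds = rounds,
                 min_publications = as.integer(min_publications),
                 exclude_zero_target_mirnas =
                   isTRUE(exclude_zero_target_mirnas)),
            class = "pipeline_plan")
}

#' The two-round leukemia replication plan
#'
#' Round 1 widens the query upward: Broader-Match on the leukemia term at
#' depth 1, so records annotated with the term or its direct parent
#' (neoplasms by histologic type) survive. Round 2 tightens to Exact-Match
#' on the leukemia term alone. Publication support threshold 1; zero-target
#' miRNAs are excluded after each round.
#'
#' @return a `pipeline_plan`.
#' @export
#' @examples
#' run_pipeline(paper_corpus(), paper_ontology(), paper_plan())
paper_plan <- function() {
  pipeline_plan(
    rounds = list(
      filter_round("broader-leukemia", "leukemia", "broader", max_depth = 1),
      filter_round("exact-leukemia", "leukemia", "exact")
    ),
    min_publications = 1L,
    exclude_zero_target_mirnas = TRUE,
    label = "leukemia-two-round"
  )
}

#' Read a pipeline plan from YAML
#'
#' Keys: `min_publications`, `exclude_zero_target_mirnas`, optional `label`,
#' and `rounds`, a list of mappings with `label`, `term_id`, `mode`
#' (`exact|broader|narrower`) and `max_depth` (integer or `"unbounded"`).
#'
#' @param path YAML file path.
#' @return a `pipeline_plan`.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such file: '%s'", path))
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    usage_error(sprintf("malformed plan YAML '%s': %s", path,
                        conditionMessage(e))))
  if (is.null(doc$rounds)) usage_error("plan YAML must list rounds")
  rounds <- lapply(doc$rounds, function(r) {
    depth <- r$max_depth %||% "unbounded"
    if (identical(depth, "unbounded")) depth <- Inf
    filter_round(label = r$label %||% usage_error("round without label"),
                 term_id = r$term_id %||% usage_error("round without term_id"),
                 mode = r$mode %||% "exact",
                 max_depth = as.numeric(depth))
  })
  pipeline_plan(rounds,
                min_publications = doc$min_publications %||% 1L,
                exclude_zero_target_mirnas =
                  doc$exclude_zero_target_mirnas %||% TRUE,
                label = doc$label %||% "plan")
}

#' Write a pipeline plan to YAML
#' @param plan a `pipeline_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "pipeline_plan"))
  doc <- list(
    label = plan$label,
    min_publications = plan$min_publications,
    exclude_zero_target_mirnas = plan$exclude_zero_target_mirnas,
    rounds = lapply(plan$rounds, function(r) {
      list(label = r$label, term_id = r$term_id, mode = r$mode,
           max_depth = if (is.infinite(r$max_depth)) "unbounded"
                       else as.integer(r$max_depth))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Percentage reduction in miRNA:target pairs
#'
#' `100 * (1 - final/initial)`, rounded half-up to one decimal; defined as
#' 0 when there was nothing to reduce.
#'
#' @param initial_pairs record count before filtering.
#' @param final_pairs record count after filtering; at most `initial_pairs`.
#' @return percentage with one decimal.
#' @export
#' @examples
#' reduction_percent(232, 19)
reduction_percent <- function(initial_pairs, final_pairs) {
  if (final_pairs > initial_pairs) {
    usage_error("final_pairs cannot exceed initial_pairs")
  }
  if (initial_pairs == 0) return(0)
  round_half_up(100 * (1 - final_pairs / initial_pairs), 1)
}

#' Rank miRNAs by surviving target support (heuristic)
#'
#' Orders by descending total count, ties by descending validated count,
#' then by `mirna_id`. The `dual_evidence` flag marks miRNAs retaining at
#' least one predicted *and* one validated target. This is a package
#' convention for surfacing the strongest candidates; it is not a substitute
#' for expert literature review, which is how final candidates are
#' adjudicated in practice.
#'
#' @param tallies data.frame as returned by [tally()].
#' @return data.frame with columns `mirna_id`, `predicted_count`,
#'   `validated_count`, `dual_evidence`, in priority order.
#' @export
prioritize <- function(tallies) {
  stopifnot(is.data.frame(tallies),
            all(c("mirna_id", "predicted_count", "validated_count") %in%
                  names(tallies)))
  ord <- order(-(tallies$predicted_count + tallies$validated_count),
               -tallies$validated_count, tallies$mirna_id)
  out <- tallies[ord, c("mirna_id", "predicted_count", "validated_count"),
                 drop = FALSE]
  out$dual_evidence <- out$predicted_count >= 1L & out$validated_count >= 1L
  rownames(out) <- NULL
  out
}

#' Execute a filtering plan over a corpus
#'
#' Applies the publication-support filter once, then each round's MeSH
#' filter in order. When zero-target exclusion is enabled, miRNAs with no
#' surviving records after a round are removed from the working roster (and
#' their records, necessarily already absent, from the working corpus) and
#' recorded as excluded for that round.
#'
#' @param corpus a `target_corpus`.
#' @param ontology a `mesh_ontology`; every plan term must resolve in it
#'   (checked before any filtering).
#' @param plan a `pipeline_plan`.
#' @return an object of class `pipeline_report`: a list with
#'   `plan_label`, `initial_pairs`, `round_reports` (each with `round_label`,
#'   `tallies`, `excluded_mirnas`, `surviving_pairs`), `final_pairs`,
#'   `reduction_percent`, `surviving_roster` and `prioritized`.
#' @export
#' @examples
#' report <- run_pipeline(paper_corpus(), paper_ontology(), paper_plan())
#' report$final_pairs
#' summary(report)
run_pipeline <- function(corpus, ontology, plan) {
  stopifnot(inherits(corpus, "target_corpus"),
            inherits(ontology, "mesh_ontology"),
            inherits(plan, "pipeline_plan"))
  for (r in plan$rounds) {
    if (!r$term_id %in% ontology$terms$term_id) {
      usage_error(sprintf("plan round '%s' references unknown term '%s'",
                          r$label, r$term_id))
    }
  }

  work <- support_filter(corpus, plan$min_publications)
  initial_pairs <- n_records(work)

  round_reports <- vector("list", length(plan$rounds))
  for (k in seq_along(plan$rounds)) {
    r <- plan$rounds[[k]]
    work <- mesh_filter(work, ontology, r$term_id, r$mode, r$max_depth)
    # tallies cover the roster as it stood entering the round, so zero-target
    # miRNAs appear explicitly before being excluded
    tal <- tally(work)
    excluded <- character(0)
    if (plan$exclude_zero_target_mirnas) {
      zero <- tal$predicted_count + tal$validated_count == 0L
      excluded <- sort(tal$mirna_id[zero])
      if (length(excluded)) {
        keep <- !work$records$mirna_id %in% excluded
        work <- target_corpus(work$records[keep, , drop = FALSE],
                              setdiff(work$roster, excluded))
      }
    }
    round_reports[[k]] <- list(
      round_label = r$label,
      tallies = tal,
      excluded_mirnas = excluded,
      surviving_pairs = n_records(work)
    )
  }

  final_pairs <- n_records(work)
  final_tallies <- tally(work)
  pri <- prioritize(final_tallies)

  structure(
    list(
      plan_label = plan$label,
      initial_pairs = initial_pairs,
      round_reports = round_reports,
      final_pairs = final_pairs,
      reduction_percent = reduction_percent(initial_pairs, final_pairs),
      surviving_roster = pri$mirna_id,
      prioritized = pri
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> plan '%s': %d -> %d pairs (%.1f%% reduction)\n",
              x$plan_label, x$initial_pairs, x$final_pairs,
              x$reduction_percent))
  cat(sprintf("surviving miRNAs (%d): %s\n", length(x$surviving_roster),
              paste(x$surviving_roster, collapse = ", ")))
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) {
  cat(sprintf("Filtering plan '%s'\n", object$plan_label))
  cat(sprintf("  initial pairs (after support filter): %d\n",
              object$initial_pairs))
  for (rr in object$round_reports) {
    cat(sprintf("  round '%s': %d surviving pairs, %d miRNA(s) excluded\n",
                rr$round_label, rr$surviving_pairs,
                length(rr$excluded_mirnas)))
  }
  cat(sprintf("  final pairs: %d (reduction %.1f%%)\n", object$final_pairs,
              object$reduction_percent))
  dual <- object$prioritized$mirna_id[object$prioritized$dual_evidence]
  cat(sprintf("  dual-evidence candidates (heuristic): %s\n",
              if (length(dual)) paste(dual, collapse = ", ") else "none"))
  invisible(object)
}

#' Render a pipeline report to documents
#'
#' `tsv` style yields one table per round (columns `mirna_id`, `predicted`,
#' `validated`), named `<plan-label>.<round-label>.tsv`, plus
#' `<plan-label>.summary.tsv`, a key/value table carrying initial pairs,
#' per-round survivors and exclusions, final pairs, the reduction
#' percentage, the surviving roster and the prioritized list (the
#' `prioritized_heuristic` key; `[dual]` marks dual-evidence miRNAs).
#' `text` style yields a single human-readable document. Output is
#' byte-deterministic for a fixed report.
#'
#' @param report a `pipeline_report`.
#' @param style `"tsv"` or `"text"`.
#' @return named list of character scalars: document name -> content.
#' @export
render_report <- function(report, style = c("tsv", "text")) {
  style <- match.arg(style)
  stopifnot(inherits(report, "pipeline_report"))
  red <- sprintf("%.1f", report$reduction_percent)
  pri <- report$prioritized
  pri_str <- paste0(pri$mirna_id,
                    ifelse(pri$dual_evidence, "[dual]", ""),
                    collapse = MULTI_SEP)
  if (style == "tsv") {
    docs <- list()
    for (rr in report$round_reports) {
      lines <- c("mirna_id\tpredicted\tvalidated",
                 sprintf("%s\t%d\t%d", rr$tallies$mirna_id,
                         rr$tallies$predicted_count,
                         rr$tallies$validated_count))
      docs[[sprintf("%s.%s.tsv", report$plan_label, rr$round_label)]] <-
        paste0(paste(lines, collapse = "\n"), "\n")
    }
    kv <- c("key\tvalue",
            sprintf("initial_pairs\t%d", report$initial_pairs))
    for (rr in report$round_reports) {
      kv <- c(kv,
              sprintf("round.%s.surviving_pairs\t%d", rr$round_label,
                      rr$surviving_pairs),
              sprintf("round.%s.excluded\t%s", rr$round_label,
                      paste(rr$excluded_mirnas, collapse = MULTI_SEP)))
    }
    kv <- c(kv,
            sprintf("final_pairs\t%d", report$final_pairs),
            sprintf("reduction_percent\t%s", red),
            sprintf("surviving_roster\t%s",
                    paste(report$surviving_roster, collapse = MULTI_SEP)),
            sprintf("prioritized_heuristic\t%s", pri_str))
    docs[[sprintf("%s.summary.tsv", report$plan_label)]] <-
      paste0(paste(kv, collapse = "\n"), "\n")
    docs
  } else {
    lines <- c(sprintf("Filtering plan '%s'", report$plan_label),
               sprintf("initial pairs: %d", report$initial_pairs))
    for (rr in report$round_reports) {
      lines <- c(lines,
                 sprintf("round '%s': %d surviving pairs; excluded: %s",
                         rr$round_label, rr$surviving_pairs,
                         if (length(rr$excluded_mirnas))
                           paste(rr$excluded_mirnas, collapse = ", ")
                         else "none"),
                 sprintf("  %s: %d predicted, %d validated",
                         rr$tallies$mirna_id, rr$tallies$predicted_count,
                         rr$tallies$validated_count))
    }
    lines <- c(lines,
               sprintf("final pairs: %d", report$final_pairs),
               sprintf("reduction: %s%%", red),
               sprintf("prioritized (heuristic): %s",
                       gsub(MULTI_SEP, ", ", pri_str, fixed = TRUE)))
    stats::setNames(list(paste0(paste(lines, collapse = "\n"), "\n")),
                    sprintf("%s.report.txt", report$plan_label))
  }
}
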