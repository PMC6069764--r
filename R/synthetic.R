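# Deterministic study fixture (mini ontology + corpus reproducing the
# published per-miRNA target counts) and a seeded generator of randomized
# corpora from stratum-count specifications.

# Per-miRNA counts from the study: total targets supported by >= 1
# publication, predicted/validated survivors of the broader-match round,
# and predicted/validated survivors of the exact-match round.
study_counts <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
mirna_id         total r1_pred r1_val r2_pred r2_val
hsa-miR-124-3p      15       0      7       0      0
hsa-miR-124-5p       0       0      0       0      0
hsa-miR-128-3p       5       4      0       1      0
hsa-miR-142-3p      69      12     11       5      4
hsa-miR-15b-3p       0       0      0       0      0
hsa-miR-17-5p       84       7     11       3      3
hsa-miR-18a-3p       4       2      2       2      0
hsa-miR-182-5p      16       4      4       0      0
hsa-miR-193a-3p     17       4      1       0      1
hsa-miR-218-5p       2       1      0       0      0
hsa-miR-221-3p       1       0      0       0      0
hsa-miR-335-5p       8       1      0       0      0
hsa-miR-532-5p       5       0      1       0      0
hsa-miR-550a-3p      0       0      0       0      0
hsa-miR-625-5p       1       1      0       0      0
hsa-miR-633          0       0      0       0      0
hsa-miR-638          3       0      0       0      0
hsa-miR-708-5p       2       0      1       0      0
")
  df
}

# Named target genes retained by the exact-match round for the five
# surviving miRNAs, with descriptive gene names.
study_named_targets <- function() {
  read.table(header = TRUE, sep = "|", strip.white = TRUE,
             stringsAsFactors = FALSE, text = "
mirna_id|gene_symbol|evidence|gene_name
hsa-miR-142-3p|ASH1L|predicted|ash1 (absent, small, or homeotic)-like (Drosophila)
hsa-miR-142-3p|CP|predicted|ceruloplasmin (ferroxidase)
hsa-miR-142-3p|MLLT1|predicted|myeloid/lymphoid or mixed-lineage leukemia; translocated to, 1
hsa-miR-142-3p|MLLT4|predicted|myeloid/lymphoid or mixed-lineage leukemia; translocated to, 4
hsa-miR-142-3p|SAG|predicted|S-antigen; retina and pineal gland (arrestin)
hsa-miR-142-3p|CCNT2|validated|cyclin T2
hsa-miR-142-3p|EGR2|validated|early growth response 2
hsa-miR-142-3p|HOXA10|validated|homeobox A10
hsa-miR-142-3p|HOXA7|validated|homeobox A7
hsa-miR-17-5p|AGO2|predicted|argonaute 2, RISC catalytic component
hsa-miR-17-5p|BCR|predicted|breakpoint cluster region
hsa-miR-17-5p|NPM1|predicted|nucleophosmin (nucleolar phosphoprotein B23, nunatrin)
hsa-miR-17-5p|E2F1|validated|E2F transcription factor 1
hsa-miR-17-5p|RUNX1|validated|runt related transcription factor 1
hsa-miR-17-5p|TP53|validated|tumor protein p53
hsa-miR-18a-3p|ARHGAP26|predicted|Rho GTPase activating protein 26
hsa-miR-18a-3p|IMPACT|predicted|impact RWD domain protein
hsa-miR-128-3p|PHF6|predicted|PHD finger protein 6
hsa-miR-193a-3p|MCL1|validated|myeloid cell leukemia 1
")
}

QUERY_TERM <- "leukemia"
BROADER_TERM <- "neoplasms-by-histologic-type"
UNRELATED_TERM <- "diabetes-mellitus"
SOURCE_DBS <- c("predict-db-1", "predict-db-2", "predict-db-3",
                "curated-db-4")

#' The bundled mini MeSH-style ontology
#'
#' A small is_a hierarchy around the leukemia descriptor: its direct parent
#' (neoplasms by histologic type), its lymphoid subtree (B-cell and T-cell
#' leukemias, with the three T-cell offspring terms), and one disjoint
#' disease term (diabetes mellitus) used to annotate records unrelated to
#' the query. Term identifiers are deterministic slugs of the labels, not
#' real MeSH descriptor UIs.
#'
#' @return a `mesh_ontology` of 9 terms.
#' @export
#' @examples
#' mesh_descendants(paper_ontology(), "leukemia-t-cell")
paper_ontology <- function() {
  labels <- c(
    "Neoplasms by Histologic Type",
    "Leukemia",
    "Leukemia, Lymphoid",
    "Leukemia, B-Cell",
    "Leukemia, T-Cell",
    "Leukemia, Large Granular Lymphocytic",
    "Leukemia, Prolymphocytic, T-Cell",
    "Leukemia-Lymphoma, Adult T-Cell",
    "Diabetes Mellitus"
  )
  ids <- term_slug(labels)
  parents <- list(
    character(0),                       # neoplasms-by-histologic-type
    "neoplasms-by-histologic-type",     # leukemia
    "leukemia",                         # leukemia-lymphoid
    "leukemia-lymphoid",                # leukemia-b-cell
    "leukemia-lymphoid",                # leukemia-t-cell
    "leukemia-t-cell",
    "leukemia-t-cell",
    "leukemia-t-cell",
    character(0)                        # diabetes-mellitus
  )
  synonyms <- rep(list(character(0)), length(ids))
  synonyms[[3]] <- "Lymphoid Leukemia"
  synonyms[[4]] <- "B-Cell Leukemia"
  synonyms[[5]] <- "T-Cell Leukemia"
  mesh_ontology(ids, labels, synonyms, parents)
}

#' @noRd
stratum_records <- function(mirna, n, evidence, term, gene_symbols = NULL,
                            gene_names = NULL, start_index = 1L,
                            pmid_start = 1L, db_start = 1L) {
  if (n == 0L) return(NULL)
  if (is.null(gene_symbols)) {
    gene_symbols <- sprintf("%s-T%d", mirna, seq.int(start_index,
                                                     length.out = n))
  }
  data.frame(
    mirna_id = mirna,
    gene_symbol = gene_symbols,
    gene_name = gene_names %||% "",
    evidence = evidence,
    source_db = SOURCE_DBS[((seq.int(db_start, length.out = n) - 1L) %%
                              length(SOURCE_DBS)) + 1L],
    pmids = sprintf("SYN%05d", seq.int(pmid_start, length.out = n)),
    mesh_term_ids = term,
    stringsAsFactors = FALSE
  )
}

#' The bundled study corpus
#'
#' A deterministic corpus of 232 miRNA:target records over the 18-miRNA
#' roster, built so that filtering reproduces the study's published counts:
#' records surviving the exact-match round carry the named target genes of
#' the five top miRNAs and are annotated with the leukemia term; records
#' surviving only the broader-match round carry synthetic gene symbols and
#' are annotated with the direct parent term; the remainder are annotated
#' with a disjoint disease term. Every record is supported by one synthetic
#' publication identifier.
#'
#' @return a `target_corpus` with 232 records and an 18-miRNA roster.
#' @export
#' @examples
#' n_records(paper_corpus())
paper_corpus <- function() {
  counts <- study_counts()
  named <- study_named_targets()

  bad <- with(counts, r2_pred > r1_pred | r2_val > r1_val |
                (r1_pred + r1_val) > total)
  if (any(bad)) {
    data_error(sprintf("inconsistent stratum counts for %s",
                       counts$mirna_id[bad][1L]))
  }

  pmid <- 1L
  db <- 1L
  chunks <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    m <- row$mirna_id
    nm <- named[named$mirna_id == m, , drop = FALSE]
    for (ev in EVIDENCE_LEVELS) {
      nmev <- nm[nm$evidence == ev, , drop = FALSE]
      n_exact <- if (ev == "predicted") row$r2_pred else row$r2_val
      if (nrow(nmev) != n_exact) {
        data_error(sprintf(
          "named %s targets for %s (%d) do not match exact-round count (%d)",
          ev, m, nrow(nmev), n_exact))
      }
      if (n_exact > 0L) {
        chunks[[length(chunks) + 1L]] <- stratum_records(
          m, n_exact, ev, QUERY_TERM, gene_symbols = nmev$gene_symbol,
          gene_names = nmev$gene_name, pmid_start = pmid, db_start = db)
        pmid <- pmid + n_exact
        db <- db + n_exact
      }
    }
    syn_i <- 1L
    for (ev in EVIDENCE_LEVELS) {
      n_broad <- if (ev == "predicted") row$r1_pred - row$r2_pred
                 else row$r1_val - row$r2_val
      if (n_broad > 0L) {
        chunks[[length(chunks) + 1L]] <- stratum_records(
          m, n_broad, ev, BROADER_TERM, start_index = syn_i,
          pmid_start = pmid, db_start = db)
        syn_i <- syn_i + n_broad
        pmid <- pmid + n_broad
        db <- db + n_broad
      }
    }
    n_unrel <- row$total - (row$r1_pred + row$r1_val)
    if (n_unrel > 0L) {
      chunks[[length(chunks) + 1L]] <- stratum_records(
        m, n_unrel, "predicted", UNRELATED_TERM, start_index = syn_i,
        pmid_start = pmid, db_start = db)
      pmid <- pmid + n_unrel
      db <- db + n_unrel
    }
  }
  target_corpus(do.call(rbind, chunks), roster = counts$mirna_id)
}

#' Build a stratum-count specification for the corpus generator
#'
#' A `corpus_spec` states, per miRNA, how many records should survive the
#' exact-match round (`exact_*`), how many should survive only the
#' broader-match round (`broader_only_*`), and how many should be unrelated
#' to the query; plus the three annotation terms and the seed driving
#' generation.
#'
#' @param strata data.frame with columns `mirna_id`, `exact_predicted`,
#'   `exact_validated`, `broader_only_predicted`, `broader_only_validated`,
#'   `unrelated_total` (non-negative integers).
#' @param query_term_id term the exact stratum is annotated with.
#' @param broader_annotation_term_id ancestor of the query term used to
#'   annotate the broader-only stratum.
#' @param unrelated_term_id term for the unrelated stratum; must be neither
#'   the query term nor one of its ancestors.
#' @param seed integer seed for reproducible generation.
#' @return a `corpus_spec` object.
#' @export
corpus_spec <- function(strata, query_term_id = QUERY_TERM,
                        broader_annotation_term_id = BROADER_TERM,
                        unrelated_term_id = UNRELATED_TERM, seed = 1L) {
  need <- c("mirna_id", "exact_predicted", "exact_validated",
            "broader_only_predicted", "broader_only_validated",
            "unrelated_total")
  if (!is.data.frame(strata) || !all(need %in% names(strata))) {
    usage_error(paste("strata must be a data.frame with columns",
                      paste(need, collapse = ", ")))
  }
  for (col in setdiff(need, "mirna_id")) {
    if (any(strata[[col]] < 0)) {
      data_error(sprintf("negative count in strata column '%s'", col))
    }
    strata[[col]] <- as.integer(strata[[col]])
  }
  if (anyDuplicated(strata$mirna_id)) {
    data_error("duplicate mirna_id in strata")
  }
  structure(list(strata = strata[, need, drop = FALSE],
                 query_term_id = query_term_id,
                 broader_annotation_term_id = broader_annotation_term_id,
                 unrelated_term_id = unrelated_term_id,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @noRd
validate_spec_terms <- function(spec, ontology) {
  assert_term(ontology, spec$query_term_id)
  assert_term(ontology, spec$broader_annotation_term_id)
  assert_term(ontology, spec$unrelated_term_id)
  anc <- mesh_ancestors(ontology, spec$query_term_id)
  if (!spec$broader_annotation_term_id %in% anc) {
    data_error(sprintf(
      "broader_annotation_term_id '%s' is not an ancestor of query term '%s'",
      spec$broader_annotation_term_id, spec$query_term_id))
  }
  if (spec$unrelated_term_id %in% c(spec$query_term_id, anc)) {
    data_error(sprintf(
      "unrelated_term_id '%s' must be neither the query term nor its ancestor",
      spec$unrelated_term_id))
  }
  invisible(TRUE)
}

#' Generate a randomized corpus matching a stratum specification
#'
#' Produces exactly the requested stratum counts with synthetic gene
#' symbols and publication identifiers. Output is identical for identical
#' `(spec, seed)`; the unrelated stratum's evidence classes are drawn
#' reproducibly from the seed.
#'
#' @param spec a [corpus_spec()].
#' @param ontology companion `mesh_ontology` the spec's terms must satisfy
#'   their invariants against.
#' @return a `target_corpus` whose roster is the spec's miRNA list.
#' @export
#' @examples
#' spec <- random_spec(seed = 7, n_mirnas = 4, max_per_stratum = 3)
#' corp <- random_corpus(spec, paper_ontology())
random_corpus <- function(spec, ontology) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(ontology, "mesh_ontology"))
  validate_spec_terms(spec, ontology)
  with_local_seed(spec$seed, {
    pmid <- 1L
    db <- 1L
    chunks <- list()
    rand_tag <- function(n) {
      vapply(seq_len(n), function(i)
        paste(sample(LETTERS, 3, replace = TRUE), collapse = ""), character(1))
    }
    for (i in seq_len(nrow(spec$strata))) {
      row <- spec$strata[i, ]
      m <- row$mirna_id
      k <- 1L
      emit <- function(n, evidence, term) {
        if (n == 0L) return()
        genes <- sprintf("%s-T%d-%s", m, seq.int(k, length.out = n),
                         rand_tag(n))
        chunks[[length(chunks) + 1L]] <<- stratum_records(
          m, n, evidence, term, gene_symbols = genes,
          pmid_start = pmid, db_start = db)
        k <<- k + n
        pmid <<- pmid + n
        db <<- db + n
      }
      emit(row$exact_predicted, "predicted", spec$query_term_id)
      emit(row$exact_validated, "validated", spec$query_term_id)
      emit(row$broader_only_predicted, "predicted",
           spec$broader_annotation_term_id)
      emit(row$broader_only_validated, "validated",
           spec$broader_annotation_term_id)
      if (row$unrelated_total > 0L) {
        ev <- EVIDENCE_LEVELS[stats::rbinom(row$unrelated_total, 1, 0.5) + 1L]
        for (evv in EVIDENCE_LEVELS) {
          emit(sum(ev == evv), evv, spec$unrelated_term_id)
        }
      }
    }
    target_corpus(if (length(chunks)) do.call(rbind, chunks) else NULL,
                  roster = spec$strata$mirna_id)
  })
}

#' Draw a random stratum specification
#'
#' Reproducible: a fixed seed yields an identical spec. Stratum counts are
#' uniform on `[0, max_per_stratum]`; annotation terms are the bundled
#' ontology's query, parent and unrelated terms.
#'
#' @param seed integer seed.
#' @param n_mirnas number of roster miRNAs (>= 1).
#' @param max_per_stratum upper bound for each stratum count.
#' @return a `corpus_spec` (its own `seed` field is set to `seed`).
#' @export
random_spec <- function(seed, n_mirnas = 6L, max_per_stratum = 5L) {
  if (n_mirnas < 1) usage_error("n_mirnas must be >= 1")
  if (max_per_stratum < 0) usage_error("max_per_stratum must be >= 0")
  with_local_seed(seed, {
    draw <- function() sample.int(max_per_stratum + 1L, n_mirnas,
                                  replace = TRUE) - 1L
    corpus_spec(
      data.frame(
        mirna_id = sprintf("syn-miR-%03d", seq_len(n_mirnas)),
        exact_predicted = draw(),
        exact_validated = draw(),
        broader_only_predicted = draw(),
        broader_only_validated = draw(),
        unrelated_total = draw(),
        stringsAsFactors = FALSE
      ),
      seed = seed
    )
  })
}
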