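# miRNA:target evidence records: data model, validation and TSV/JSON I/O.

CORPUS_COLS <- c("mirna_id", "gene_symbol", "gene_name", "evidence",
                 "source_db", "pmids", "mesh_term_ids")
EVIDENCE_LEVELS <- c("predicted", "validated")

#' Construct a validated corpus of miRNA:target records
#'
#' Each record asserts that a gene is a target of a miRNA with one evidence
#' class: `predicted` (from a computational prediction database) or
#' `validated` (experimentally supported). Records carry the reporting
#' database, supporting publication identifiers and MeSH-style disease term
#' annotations. The roster lists every miRNA under study, including those
#' with zero records, so that downstream tallies report them explicitly.
#'
#' Multi-valued fields (`pmids`, `mesh_term_ids`) are stored as
#' `"|"`-separated strings; the empty string means none.
#'
#' @param records data.frame with character columns `mirna_id`,
#'   `gene_symbol`, `gene_name`, `evidence`, `source_db`, `pmids`,
#'   `mesh_term_ids` (missing optional columns are filled with `""`).
#' @param roster character vector of miRNA identifiers under study; must
#'   cover every `mirna_id` in `records`. Defaults to the distinct
#'   `mirna_id` values.
#' @return an object of class `target_corpus`.
#' @export
target_corpus <- function(records = NULL, roster = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(CORPUS_COLS)), CORPUS_COLS),
      stringsAsFactors = FALSE)
  }
  for (col in setdiff(CORPUS_COLS, names(records))) {
    if (col %in% c("mirna_id", "gene_symbol", "evidence")) {
      data_error(sprintf("corpus records are missing column '%s'", col))
    }
    records[[col]] <- ""
  }
  records <- records[, CORPUS_COLS, drop = FALSE]
  for (col in CORPUS_COLS) records[[col]] <- as.character(records[[col]])
  records[is.na(records)] <- ""
  rownames(records) <- NULL

  roster <- unique(as.character(roster %||% unique(records$mirna_id)))
  validate_records(records, roster)
  structure(list(records = records, roster = roster), class = "target_corpus")
}

#' @noRd
validate_records <- function(records, roster, line_offset = 0L) {
  where <- function(i) {
    if (line_offset > 0L) sprintf("line %d", i + line_offset)
    else sprintf("record %d", i)
  }
  bad <- which(!nzchar(records$mirna_id) | !nzchar(records$gene_symbol))
  if (length(bad)) {
    data_error(sprintf("%s: mirna_id and gene_symbol must be non-empty",
                       where(bad[1L])))
  }
  bad <- which(!records$evidence %in% EVIDENCE_LEVELS)
  if (length(bad)) {
    data_error(sprintf("%s: unknown evidence class '%s' (expected %s)",
                       where(bad[1L]), records$evidence[bad[1L]],
                       paste(EVIDENCE_LEVELS, collapse = "/")))
  }
  pm <- split_multi(records$pmids)
  bad <- which(vapply(pm, anyDuplicated, integer(1)) > 0L)
  if (length(bad)) {
    data_error(sprintf("%s: duplicate pmid within a record", where(bad[1L])))
  }
  triple <- paste(records$mirna_id, records$gene_symbol, records$evidence,
                  sep = "\r")
  if (anyDuplicated(triple)) {
    i <- which(duplicated(triple))[1L]
    data_error(sprintf(
      "%s: duplicate (mirna_id, gene_symbol, evidence) triple: (%s, %s, %s)",
      where(i), records$mirna_id[i], records$gene_symbol[i],
      records$evidence[i]))
  }
  stray <- setdiff(records$mirna_id, roster)
  if (length(stray)) {
    data_error(sprintf("mirna_id '%s' appears in records but not in roster",
                       stray[1L]))
  }
  invisible(TRUE)
}

#' Number of records in a corpus
#' @param corpus a `target_corpus`.
#' @return integer count of miRNA:target pairs.
#' @export
n_records <- function(corpus) {
  stopifnot(inherits(corpus, "target_corpus"))
  nrow(corpus$records)
}

#' @export
print.target_corpus <- function(x, ...) {
  ev <- table(factor(x$records$evidence, levels = EVIDENCE_LEVELS))
  cat(sprintf(
    "<target_corpus> %d records (%d predicted, %d validated), roster of %d miRNAs\n",
    n_records(x), ev[["predicted"]], ev[["validated"]], length(x$roster)))
  invisible(x)
}

#' Read a corpus document
#'
#' TSV dialect: tab-separated with the seven columns `mirna_id`,
#' `gene_symbol`, `gene_name`, `evidence`, `source_db`, `pmids`,
#' `mesh_term_ids` in that order; multi-valued cells use `"|"`. The roster
#' travels in a companion single-column TSV (header `mirna_id`); without one
#' the roster defaults to the miRNAs present. JSON dialect: an object with
#' `roster` and `records` fields.
#'
#' @param path corpus file path.
#' @param dialect `"auto"` (by extension: `.json` vs anything else),
#'   `"tsv"`, or `"json"`.
#' @param roster_path optional companion roster TSV (TSV dialect only).
#' @return a validated `target_corpus`.
#' @export
read_corpus <- function(path, dialect = c("auto", "tsv", "json"),
                        roster_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) usage_error(sprintf("no such file: '%s'", path))
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (dialect == "tsv") {
    records <- tryCatch(
      utils::read.delim(path, colClasses = "character", na.strings = NULL,
                        check.names = FALSE),
      error = function(e) data_error(sprintf("malformed TSV '%s': %s", path,
                                             conditionMessage(e))))
    if (!identical(names(records), CORPUS_COLS)) {
      data_error(sprintf("line 1: expected header '%s'",
                         paste(CORPUS_COLS, collapse = "\\t")))
    }
    roster <- NULL
    if (!is.null(roster_path)) {
      rdf <- utils::read.delim(roster_path, colClasses = "character",
                               na.strings = NULL)
      if (!"mirna_id" %in% names(rdf)) {
        data_error("roster file must have a 'mirna_id' column")
      }
      roster <- rdf$mirna_id
    }
    for (col in CORPUS_COLS) records[[col]] <- as.character(records[[col]])
    records[is.na(records)] <- ""
    validate_records(records, roster %||% unique(records$mirna_id),
                     line_offset = 1L)
    target_corpus(records, roster)
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
    if (!is.list(doc) || is.null(doc$records) && is.null(doc$roster)) {
      data_error("JSON corpus must be an object with 'roster' and 'records'")
    }
    records <- doc$records
    if (is.null(records) || length(records) == 0L) {
      records <- NULL
    } else {
      missing <- setdiff(c("mirna_id", "gene_symbol", "evidence"),
                         names(records))
      if (length(missing)) {
        data_error(sprintf("JSON records are missing field '%s'", missing[1L]))
      }
      for (col in c("pmids", "mesh_term_ids")) {
        if (is.list(records[[col]])) {
          records[[col]] <- join_multi(records[[col]])
        }
      }
    }
    target_corpus(records, as.character(doc$roster %||% NULL))
  }
}

#' Write a corpus document
#'
#' Round-trips exactly: `read_corpus()` on the output reproduces the corpus,
#' record order included.
#'
#' @param corpus a `target_corpus`.
#' @param path output file path.
#' @param dialect `"tsv"` or `"json"`.
#' @param roster_path companion roster TSV path (TSV dialect; `NULL` to skip).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("tsv", "json"),
                         roster_path = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(corpus, "target_corpus"))
  if (dialect == "tsv") {
    utils::write.table(corpus$records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(roster_path)) {
      utils::write.table(
        data.frame(mirna_id = corpus$roster, stringsAsFactors = FALSE),
        roster_path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    recs <- corpus$records
    doc <- list(
      roster = corpus$roster,
      records = lapply(seq_len(nrow(recs)), function(i) {
        list(mirna_id = recs$mirna_id[i],
             gene_symbol = recs$gene_symbol[i],
             gene_name = recs$gene_name[i],
             evidence = recs$evidence[i],
             source_db = recs$source_db[i],
             pmids = I(split_multi(recs$pmids[i])[[1L]]),
             mesh_term_ids = I(split_multi(recs$mesh_term_ids[i])[[1L]]))
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Check that corpus annotations resolve in an ontology
#'
#' Purely diagnostic: filtering never requires resolvable annotations, but
#' unresolvable ones can silently match nothing.
#'
#' @param corpus a `target_corpus`.
#' @param ontology a `mesh_ontology`.
#' @return data.frame with one row per unresolvable annotation occurrence
#'   (columns `record`, `mirna_id`, `gene_symbol`, `missing_term`); zero rows
#'   when every annotation resolves.
#' @export
validate_against_ontology <- function(corpus, ontology) {
  stopifnot(inherits(corpus, "target_corpus"),
            inherits(ontology, "mesh_ontology"))
  known <- ontology$terms$term_id
  anns <- split_multi(corpus$records$mesh_term_ids)
  rows <- list()
  for (i in seq_along(anns)) {
    for (t in setdiff(anns[[i]], known)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = i,
        mirna_id = corpus$records$mirna_id[i],
        gene_symbol = corpus$records$gene_symbol[i],
        missing_term = t,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(record = integer(0), mirna_id = character(0),
                      gene_symbol = character(0), missing_term = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
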