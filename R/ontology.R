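# MeSH-style is_a hierarchy: construction, validation, I/O, and the three
# query-expansion modes (Exact-, Broader-, Narrower-Match).

#' Construct a validated MeSH-style ontology
#'
#' A `mesh_ontology` is a directed acyclic graph of disease terms linked by
#' is_a edges. Multiple parents are permitted (MeSH descriptors form a
#' poly-hierarchy), cycles are not. Preferred labels must be unique under
#' case-insensitive comparison; identifiers must be unique exactly.
#'
#' @param term_id character vector of unique, non-empty term identifiers.
#' @param preferred_label character vector of non-empty labels, same length.
#' @param synonyms list of character vectors (one per term), or `NULL`.
#' @param parent_ids list of character vectors of parent identifiers (one per
#'   term; empty for roots), or `NULL`.
#' @return an object of class `mesh_ontology`.
#' @export
#' @examples
#' ont <- mesh_ontology(
#'   term_id = c("neoplasms", "leukemia"),
#'   preferred_label = c("Neoplasms", "Leukemia"),
#'   parent_ids = list(character(0), "neoplasms")
#' )
#' n_terms(ont)
mesh_ontology <- function(term_id, preferred_label, synonyms = NULL,
                          parent_ids = NULL) {
  term_id <- as.character(term_id)
  preferred_label <- as.character(preferred_label)
  n <- length(term_id)
  if (length(preferred_label) != n) {
    usage_error("term_id and preferred_label must have the same length")
  }
  synonyms <- synonyms %||% rep(list(character(0)), n)
  parent_ids <- parent_ids %||% rep(list(character(0)), n)
  if (length(synonyms) != n || length(parent_ids) != n) {
    usage_error("synonyms and parent_ids must have one entry per term")
  }
  synonyms <- lapply(synonyms, as.character)
  parent_ids <- lapply(parent_ids, function(p) unique(as.character(p)))

  if (any(!nzchar(term_id)) || anyNA(term_id)) {
    data_error("term identifiers must be non-empty")
  }
  if (anyDuplicated(term_id)) {
    data_error(sprintf("duplicate term identifier: '%s'",
                       term_id[duplicated(term_id)][1L]))
  }
  if (any(!nzchar(preferred_label)) || anyNA(preferred_label)) {
    data_error("preferred labels must be non-empty")
  }
  folded <- norm_label(preferred_label)
  if (anyDuplicated(folded)) {
    data_error(sprintf("duplicate case-folded label: '%s'",
                       preferred_label[duplicated(folded)][1L]))
  }
  names(synonyms) <- term_id
  names(parent_ids) <- term_id

  for (id in term_id) {
    p <- parent_ids[[id]]
    if (id %in% p) data_error(sprintf("term '%s' lists itself as parent", id))
    missing <- setdiff(p, term_id)
    if (length(missing)) {
      data_error(sprintf("dangling parent reference: '%s' (parent of '%s')",
                         missing[1L], id))
    }
  }

  # Kahn's algorithm over parent edges: leftover nodes witness a cycle.
  indeg <- vapply(parent_ids, length, integer(1))
  children <- invert_parents(term_id, parent_ids)
  queue <- term_id[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < n) {
    data_error(sprintf("is_a cycle detected involving term '%s'",
                       term_id[indeg > 0L][1L]))
  }

  structure(
    list(
      terms = data.frame(term_id = term_id,
                         preferred_label = preferred_label,
                         stringsAsFactors = FALSE),
      synonyms = synonyms,
      parents = parent_ids,
      children = children
    ),
    class = "mesh_ontology"
  )
}

#' @noRd
invert_parents <- function(term_id, parent_ids) {
  children <- stats::setNames(rep(list(character(0)), length(term_id)), term_id)
  for (id in term_id) {
    for (p in parent_ids[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children
}

#' Number of terms in an ontology
#' @param ontology a `mesh_ontology`.
#' @return integer count.
#' @export
n_terms <- function(ontology) {
  stopifnot(inherits(ontology, "mesh_ontology"))
  nrow(ontology$terms)
}

#' @export
print.mesh_ontology <- function(x, ...) {
  roots <- x$terms$term_id[vapply(x$parents, length, integer(1)) == 0L]
  cat(sprintf("<mesh_ontology> %d terms, %d root(s)\n", n_terms(x),
              length(roots)))
  if (length(roots)) {
    cat("roots:", paste(sort(roots), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @noRd
assert_term <- function(ontology, term_id) {
  if (length(term_id) != 1L || is.na(term_id) || !nzchar(term_id)) {
    usage_error("term_id must be a single non-empty identifier")
  }
  if (!term_id %in% ontology$terms$term_id) {
    usage_error(sprintf("unknown term identifier: '%s'", term_id))
  }
  invisible(term_id)
}

#' @noRd
reachable <- function(adj, start, max_depth) {
  out <- character(0)
  frontier <- start
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(out, start))
    out <- c(out, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(out)
}

#' Ancestors of a term
#'
#' All terms reachable by following is_a (parent) links, excluding the term
#' itself, in deterministic sorted order.
#'
#' @param ontology a `mesh_ontology`.
#' @param term_id identifier of a term present in the ontology.
#' @param max_depth positive number of is_a steps to follow; `Inf` (the
#'   default) follows the hierarchy to its roots.
#' @return sorted character vector of term identifiers.
#' @export
#' @examples
#' ont <- paper_ontology()
#' mesh_ancestors(ont, "leukemia-b-cell", max_depth = 1)
mesh_ancestors <- function(ontology, term_id, max_depth = Inf) {
  stopifnot(inherits(ontology, "mesh_ontology"))
  assert_term(ontology, term_id)
  if (max_depth < 1) usage_error("max_depth must be positive")
  reachable(ontology$parents, term_id, max_depth)
}

#' Descendants of a term
#'
#' All terms reachable by following child links (inverted is_a), excluding
#' the term itself, in deterministic sorted order.
#'
#' @inheritParams mesh_ancestors
#' @return sorted character vector of term identifiers.
#' @export
#' @examples
#' mesh_descendants(paper_ontology(), "leukemia-t-cell")
mesh_descendants <- function(ontology, term_id, max_depth = Inf) {
  stopifnot(inherits(ontology, "mesh_ontology"))
  assert_term(ontology, term_id)
  if (max_depth < 1) usage_error("max_depth must be positive")
  reachable(ontology$children, term_id, max_depth)
}

#' Expand a query term under a match mode
#'
#' The three modes mirror the semantic search options of ontology-backed
#' record retrieval: `exact` keeps only the term itself; `broader` adds its
#' parent terms (the query is too specific, widen it upward); `narrower`
#' adds its offspring terms (the query is too general, widen it downward).
#'
#' @inheritParams mesh_ancestors
#' @param mode one of `"exact"`, `"broader"`, `"narrower"`.
#' @return sorted character vector of term identifiers; always contains
#'   `term_id`. `max_depth` is ignored under `exact`.
#' @export
#' @examples
#' ont <- paper_ontology()
#' mesh_expand(ont, "leukemia-b-cell", "broader", max_depth = 1)
#' mesh_expand(ont, "leukemia-t-cell", "narrower")
mesh_expand <- function(ontology, term_id, mode = c("exact", "broader", "narrower"),
                        max_depth = Inf) {
  mode <- match.arg(mode)
  stopifnot(inherits(ontology, "mesh_ontology"))
  assert_term(ontology, term_id)
  others <- switch(mode,
    exact = character(0),
    broader = mesh_ancestors(ontology, term_id, max_depth),
    narrower = mesh_descendants(ontology, term_id, max_depth)
  )
  sort(unique(c(term_id, others)))
}

#' Resolve free text to ontology terms
#'
#' Case-insensitive, whitespace-normalized search over preferred labels and
#' synonyms, so a user who knows only part of a term (or an alternative
#' phrasing) can still locate it.
#'
#' @param ontology a `mesh_ontology`.
#' @param query non-empty search text.
#' @param where `"beginning"` matches labels/synonyms starting with the query;
#'   `"anywhere"` matches the query at any position.
#' @return data.frame with columns `term_id`, `preferred_label`, sorted by
#'   label.
#' @export
#' @examples
#' find_terms(paper_ontology(), "Leukemia, T", where = "beginning")
find_terms <- function(ontology, query, where = c("beginning", "anywhere")) {
  where <- match.arg(where)
  stopifnot(inherits(ontology, "mesh_ontology"))
  if (length(query) != 1L || is.na(query) || !nzchar(trimws(query))) {
    usage_error("query must be non-empty text")
  }
  q <- norm_label(query)
  hit <- vapply(seq_len(nrow(ontology$terms)), function(i) {
    texts <- norm_label(c(ontology$terms$preferred_label[i],
                          ontology$synonyms[[ontology$terms$term_id[i]]]))
    if (where == "beginning") any(startsWith(texts, q))
    else any(grepl(q, texts, fixed = TRUE))
  }, logical(1))
  out <- ontology$terms[hit, , drop = FALSE]
  out <- out[order(out$preferred_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- I/O ------------------------------------------------------------------

#' Read an ontology document
#'
#' Two dialects are supported. The OBO subset honors only `[Term]` stanzas
#' with `id:`, `name:`, `synonym:` (quoted string; scope token ignored) and
#' `is_a:` (optional trailing `! comment` ignored); any other tag inside a
#' `[Term]` stanza is skipped with a notice. The edge-list dialect is a TSV
#' with header `child_id`, `child_label`, `parent_id` — one row per parent
#' link, empty `parent_id` for roots, the first row for a child carrying its
#' label.
#'
#' @param path file path to the document.
#' @param dialect `"auto"` (by extension: `.obo` vs anything else),
#'   `"obo"`, or `"edgelist"`.
#' @return a validated `mesh_ontology`.
#' @export
read_ontology <- function(path, dialect = c("auto", "obo", "edgelist")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) usage_error(sprintf("no such file: '%s'", path))
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "obo") "obo" else "edgelist"
  }
  switch(dialect,
    obo = read_ontology_obo(path),
    edgelist = read_ontology_edgelist(path)
  )
}

#' @noRd
read_ontology_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  labels <- character(0)
  syns <- list()
  parents <- list()
  skipped <- character(0)

  in_term <- FALSE
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id) || !nzchar(cur$id)) {
      data_error("OBO [Term] stanza without an id")
    }
    if (is.na(cur$name)) {
      data_error(sprintf("OBO term '%s' has no name", cur$id))
    }
    ids <<- c(ids, cur$id)
    labels <<- c(labels, cur$name)
    syns[[length(syns) + 1L]] <<- cur$syn
    parents[[length(parents) + 1L]] <<- cur$isa
  }

  for (raw in lines) {
    line <- trimws(sub("!.*$", "", raw))
    if (grepl("^\\[", raw)) {
      flush()
      in_term <- trimws(raw) == "[Term]"
      cur <- if (in_term) {
        list(id = NA_character_, name = NA_character_,
             syn = character(0), isa = character(0))
      } else {
        NULL
      }
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (grepl("^name:", line)) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (grepl("^synonym:", raw)) {
      m <- regmatches(raw, regexpr('"[^"]*"', raw))
      if (length(m)) cur$syn <- c(cur$syn, gsub('"', "", m))
    } else if (grepl("^is_a:", line)) {
      cur$isa <- c(cur$isa, trimws(sub("^is_a:", "", line)))
    } else {
      skipped <- c(skipped, sub(":.*$", "", line))
    }
  }
  flush()

  if (length(skipped)) {
    message("read_ontology: skipped OBO tag(s): ",
            paste(sort(unique(skipped)), collapse = ", "))
  }
  mentioned <- setdiff(unique(unlist(parents)), ids)
  if (length(mentioned)) {
    data_error(sprintf("dangling parent reference: '%s'", mentioned[1L]))
  }
  mesh_ontology(ids, labels, syns, parents)
}

#' @noRd
read_ontology_edgelist <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  need <- c("child_id", "child_label", "parent_id")
  if (!all(need %in% names(df))) {
    data_error(paste("edge-list ontology must have columns",
                     paste(need, collapse = ", ")))
  }
  ids <- unique(df$child_id)
  labels <- vapply(ids, function(id) {
    lab <- df$child_label[df$child_id == id]
    lab[nzchar(lab)][1L] %||% ""
  }, character(1))
  parents <- lapply(ids, function(id) {
    p <- df$parent_id[df$child_id == id]
    p[nzchar(p)]
  })
  mentioned <- setdiff(unique(unlist(parents)), ids)
  if (length(mentioned)) {
    data_error(sprintf("dangling parent reference: '%s'", mentioned[1L]))
  }
  mesh_ontology(ids, unname(labels), NULL, parents)
}

#' Write an ontology document
#'
#' Serializes to either supported dialect; `read_ontology()` recovers an
#' identical ontology.
#'
#' @param ontology a `mesh_ontology`.
#' @param path output file path.
#' @param dialect `"edgelist"` or `"obo"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path, dialect = c("edgelist", "obo")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ontology, "mesh_ontology"))
  ids <- ontology$terms$term_id
  if (dialect == "edgelist") {
    rows <- lapply(ids, function(id) {
      p <- ontology$parents[[id]]
      lab <- ontology$terms$preferred_label[ontology$terms$term_id == id]
      if (!length(p)) {
        data.frame(child_id = id, child_label = lab, parent_id = "",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(child_id = id,
                   child_label = c(lab, rep("", length(p) - 1L)),
                   parent_id = p, stringsAsFactors = FALSE)
      }
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    out <- c("format-version: 1.2", "")
    for (i in seq_along(ids)) {
      id <- ids[[i]]
      out <- c(out, "[Term]", paste0("id: ", id),
               paste0("name: ", ontology$terms$preferred_label[i]),
               sprintf('synonym: "%s" EXACT []', ontology$synonyms[[id]]),
               paste0("is_a: ", ontology$parents[[id]], recycle0 = TRUE), "")
    }
    writeLines(out, path)
  }
  invisible(path)
}
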