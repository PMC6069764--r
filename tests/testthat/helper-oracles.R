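# Independent oracles and generators for property-style tests.

# Brute-force reachability by exhaustive enumeration of all paths along the
# adjacency map (no visited set: on a DAG every path is finite, and a node
# is reachable iff some path reaches it). Independent of the BFS used by
# the package.
oracle_reachable <- function(adj, start, max_depth = Inf) {
  found <- character(0)
  walk <- function(node, depth) {
    if (depth >= max_depth) return(invisible())
    for (nb in adj[[node]]) {
      found <<- union(found, nb)
      walk(nb, depth + 1)
    }
  }
  walk(start, 0)
  sort(setdiff(found, start))
}

oracle_ancestors <- function(ontology, term_id, max_depth = Inf) {
  oracle_reachable(ontology$parents, term_id, max_depth)
}

oracle_descendants <- function(ontology, term_id, max_depth = Inf) {
  oracle_reachable(ontology$children, term_id, max_depth)
}

# Random DAG ontology: node i may only have parents among nodes 1..(i-1),
# which guarantees acyclicity by construction.
random_dag_ontology <- function(seed, n_max = 12L, p_edge = 0.35) {
  set.seed(seed)
  n <- sample.int(n_max, 1L)
  ids <- sprintf("t%02d", seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1L) return(character(0))
    cand <- ids[seq_len(i - 1L)]
    cand[stats::runif(length(cand)) < p_edge]
  })
  mesh_ontology(ids, paste("Term", ids), parent_ids = parents)
}

# Randomized corpus with varied pmid multiplicity (0-3 pmids per record) so
# the publication-support filter actually discriminates.
random_test_corpus <- function(seed, ontology = paper_ontology()) {
  spec <- random_spec(seed, n_mirnas = 4L, max_per_stratum = 3L)
  corp <- random_corpus(spec, ontology)
  set.seed(seed + 1L)
  n <- n_records(corp)
  if (n > 0L) {
    k <- sample(0:3, n, replace = TRUE)
    corp$records$pmids <- vapply(seq_len(n), function(i) {
      if (k[i] == 0L) "" else
        paste(sprintf("SYNX%05d", seq.int(i * 10L, length.out = k[i])),
              collapse = "|")
    }, character(1))
  }
  list(spec = spec, corpus = corp)
}

paper_fixture_path <- function(name) {
  system.file("extdata", name, package = "meshmir", mustWork = TRUE)
}

# Expected per-miRNA survivor counts after each round (frozen from the
# study's published tables); excluded = zero-total rows of each table.
expected_round1 <- data.frame(
  mirna_id = c("hsa-miR-142-3p", "hsa-miR-17-5p", "hsa-miR-18a-3p",
               "hsa-miR-128-3p", "hsa-miR-193a-3p", "hsa-miR-124-3p",
               "hsa-miR-182-5p", "hsa-miR-335-5p", "hsa-miR-708-5p",
               "hsa-miR-625-5p", "hsa-miR-218-5p", "hsa-miR-532-5p"),
  predicted = c(12L, 7L, 2L, 4L, 4L, 0L, 4L, 1L, 0L, 1L, 1L, 0L),
  validated = c(11L, 11L, 2L, 0L, 1L, 7L, 4L, 0L, 1L, 0L, 0L, 1L),
  stringsAsFactors = FALSE
)

expected_round1_excluded <- c("hsa-miR-124-5p", "hsa-miR-15b-3p",
                              "hsa-miR-221-3p", "hsa-miR-550a-3p",
                              "hsa-miR-633", "hsa-miR-638")

expected_round2 <- data.frame(
  mirna_id = c("hsa-miR-142-3p", "hsa-miR-17-5p", "hsa-miR-18a-3p",
               "hsa-miR-128-3p", "hsa-miR-193a-3p"),
  predicted = c(5L, 3L, 2L, 1L, 0L),
  validated = c(4L, 3L, 0L, 0L, 1L),
  stringsAsFactors = FALSE
)

expected_round2_excluded <- c("hsa-miR-124-3p", "hsa-miR-182-5p",
                              "hsa-miR-218-5p", "hsa-miR-335-5p",
                              "hsa-miR-532-5p", "hsa-miR-625-5p",
                              "hsa-miR-708-5p")

# Compare tallies (any row order) against an expected table; miRNAs absent
# from `expected` are expected to have zero counts.
expect_tallies_match <- function(tallies, expected) {
  for (i in seq_len(nrow(tallies))) {
    id <- tallies$mirna_id[i]
    j <- match(id, expected$mirna_id)
    exp_p <- if (is.na(j)) 0L else expected$predicted[j]
    exp_v <- if (is.na(j)) 0L else expected$validated[j]
    expect_identical(tallies$predicted_count[i], exp_p, label = id)
    expect_identical(tallies$validated_count[i], exp_v, label = id)
  }
  expect_true(all(expected$mirna_id %in% tallies$mirna_id))
}
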