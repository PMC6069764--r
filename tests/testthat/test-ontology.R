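test_that("structural validation rejects cycles, dangling parents and duplicates", {
  expect_error(
    mesh_ontology(c("A", "B"), c("a", "b"),
                  parent_ids = list("B", "A")),
    "cycle", class = "meshmir_data_error")
  expect_error(
    mesh_ontology("A", "a", parent_ids = list("ghost")),
    "dangling parent reference.*ghost", class = "meshmir_data_error")
  expect_error(
    mesh_ontology(c("A", "A"), c("a", "b")),
    "duplicate term identifier", class = "meshmir_data_error")
  expect_error(
    mesh_ontology(c("A", "B"), c("Leukemia", "LEUKEMIA")),
    "case-folded label", class = "meshmir_data_error")
  expect_error(
    mesh_ontology("A", "a", parent_ids = list("A")),
    "itself", class = "meshmir_data_error")
})

test_that("cycles are caught when reading an edge-list document", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\tchild_label\tparent_id",
               "A\tTerm A\tB",
               "B\tTerm B\tA"), f)
  expect_error(read_ontology(f), "cycle", class = "meshmir_data_error")
})

test_that("empty documents yield an empty ontology", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("child_id\tchild_label\tparent_id", f)
  expect_identical(n_terms(read_ontology(f)), 0L)

  g <- withr::local_tempfile(fileext = ".obo")
  writeLines("format-version: 1.2", g)
  expect_identical(n_terms(read_ontology(g)), 0L)
})

test_that("the bundled mini-ontology parses from both dialects with the leukemia subtree", {
  for (file in c("mesh_leukemia.obo", "mesh_leukemia_edges.tsv")) {
    ont <- read_ontology(paper_fixture_path(file))
    expect_identical(n_terms(ont), 9L)
    expect_identical(
      mesh_descendants(ont, "leukemia-t-cell"),
      c("leukemia-large-granular-lymphocytic",
        "leukemia-lymphoma-adult-t-cell",
        "leukemia-prolymphocytic-t-cell"))
  }
})

test_that("unknown OBO tags are skipped with a notice, known tags are honored", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: neo", "name: Neoplasms", "def: \"ignored\" []", "",
    "[Term]", "id: leu", "name: Leukemia",
    "synonym: \"blood cancer\" EXACT []",
    "is_a: neo ! Neoplasms", "xref: MESH:D007938", ""), f)
  expect_message(ont <- read_ontology(f), "skipped OBO tag")
  expect_identical(mesh_ancestors(ont, "leu"), "neo")
  expect_identical(find_terms(ont, "blood", where = "anywhere")$term_id, "leu")
})

test_that("ancestors and descendants follow is_a links with depth limits", {
  ont <- paper_ontology()
  expect_identical(mesh_ancestors(ont, "leukemia-b-cell", max_depth = 1),
                   "leukemia-lymphoid")
  expect_identical(
    mesh_ancestors(ont, "leukemia-b-cell"),
    c("leukemia", "leukemia-lymphoid", "neoplasms-by-histologic-type"))
  expect_identical(mesh_ancestors(ont, "neoplasms-by-histologic-type"),
                   character(0))
  expect_identical(mesh_descendants(ont, "leukemia-b-cell"), character(0))
  expect_error(mesh_ancestors(ont, "nope"), "unknown term",
               class = "meshmir_usage_error")
})

test_that("expansion modes implement exact/broader/narrower semantics", {
  ont <- paper_ontology()
  expect_identical(mesh_expand(ont, "leukemia-b-cell", "broader", 1),
                   c("leukemia-b-cell", "leukemia-lymphoid"))
  expect_identical(mesh_expand(ont, "leukemia-lymphoid", "exact"),
                   "leukemia-lymphoid")
  narrower <- mesh_expand(ont, "leukemia-t-cell", "narrower")
  expect_length(narrower, 4L)
  expect_true("leukemia-t-cell" %in% narrower)
})

test_that("free-text term search honors both label-query modes", {
  ont <- paper_ontology()
  expect_identical(find_terms(ont, "Leukemia, T", "beginning")$preferred_label,
                   "Leukemia, T-Cell")
  # oracle: exhaustive scan of every label and synonym
  scan_hits <- sort(ont$terms$preferred_label[vapply(
    seq_len(nrow(ont$terms)),
    function(i) {
      texts <- tolower(c(ont$terms$preferred_label[i],
                         ont$synonyms[[ont$terms$term_id[i]]]))
      any(grepl("lymph", texts, fixed = TRUE))
    }, logical(1))])
  expect_identical(find_terms(ont, "lymph", "anywhere")$preferred_label,
                   scan_hits)
  expect_identical(nrow(find_terms(ont, "zzz", "anywhere")), 0L)
  expect_error(find_terms(ont, "  "), "non-empty",
               class = "meshmir_usage_error")
})

test_that("beginning-mode matches are a subset of anywhere-mode matches", {
  ont <- paper_ontology()
  for (q in c("Leukemia", "leu", "T-Cell", "cell", "diab")) {
    beg <- find_terms(ont, q, "beginning")$term_id
    any <- find_terms(ont, q, "anywhere")$term_id
    expect_true(all(beg %in% any), label = q)
  }
})

test_that("closure operations agree with the brute-force path oracle on random DAGs", {
  for (seed in 1:40) {
    ont <- random_dag_ontology(seed)
    ids <- ont$terms$term_id
    for (id in ids) {
      for (d in c(1, 2, Inf)) {
        expect_identical(mesh_ancestors(ont, id, d),
                         oracle_ancestors(ont, id, d),
                         label = sprintf("anc seed=%d id=%s d=%s", seed, id, d))
        expect_identical(mesh_descendants(ont, id, d),
                         oracle_descendants(ont, id, d),
                         label = sprintf("desc seed=%d id=%s d=%s", seed, id, d))
      }
    }
  }
})

test_that("descendant/ancestor duality and depth monotonicity hold on random DAGs", {
  for (seed in 41:60) {
    ont <- random_dag_ontology(seed)
    ids <- ont$terms$term_id
    for (x in ids) {
      anc_x <- mesh_ancestors(ont, x)
      for (y in ids) {
        expect_identical(x %in% mesh_descendants(ont, y),
                         y %in% anc_x)
      }
      # unbounded equals depth = number of terms; monotone in depth
      expect_identical(mesh_ancestors(ont, x, length(ids)), anc_x)
      prev <- character(0)
      for (d in seq_len(min(4, length(ids)))) {
        cur <- mesh_ancestors(ont, x, d)
        expect_true(all(prev %in% cur))
        prev <- cur
      }
      # exact expansion is contained in broader and narrower expansions
      expect_true(all(mesh_expand(ont, x, "exact") %in%
                        mesh_expand(ont, x, "broader", 2)))
      expect_true(all(mesh_expand(ont, x, "exact") %in%
                        mesh_expand(ont, x, "narrower", 2)))
    }
  }
})

test_that("ontology serialization round-trips in both dialects", {
  ont <- paper_ontology()
  for (dialect in c("edgelist", "obo")) {
    f <- withr::local_tempfile(fileext = if (dialect == "obo") ".obo" else ".tsv")
    write_ontology(ont, f, dialect)
    back <- read_ontology(f)
    expect_identical(back$terms, ont$terms)
    expect_identical(back$parents, ont$parents)
    if (dialect == "obo") expect_identical(back$synonyms, ont$synonyms)
  }
})
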