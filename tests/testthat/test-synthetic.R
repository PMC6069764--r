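test_that("the mini ontology encodes the leukemia neighborhood", {
  ont <- paper_ontology()
  expect_identical(ont$parents[["leukemia-b-cell"]], "leukemia-lymphoid")
  expect_identical(ont$parents[["leukemia"]], "neoplasms-by-histologic-type")
  expect_length(ont$children[["leukemia-t-cell"]], 3L)
  # the unrelated term is disjoint from the leukemia lineage
  expect_false("diabetes-mellitus" %in%
                 c("leukemia", mesh_ancestors(ont, "leukemia")))
})

test_that("the study corpus realizes the published stratum arithmetic", {
  corp <- paper_corpus()
  expect_identical(n_records(corp), 232L)
  expect_identical(length(corp$roster), 18L)

  recs <- corp$records
  # named validated targets of hsa-miR-17-5p retained by the exact round
  exact_17 <- recs[recs$mirna_id == "hsa-miR-17-5p" &
                     recs$evidence == "validated" &
                     recs$mesh_term_ids == "leukemia", ]
  expect_setequal(exact_17$gene_symbol, c("E2F1", "RUNX1", "TP53"))

  # roster members may carry zero records
  expect_identical(sum(recs$mirna_id == "hsa-miR-15b-3p"), 0L)
  expect_true("hsa-miR-15b-3p" %in% corp$roster)

  # per miRNA: exact stratum <= broader survivors <= total
  for (m in corp$roster) {
    sub <- recs[recs$mirna_id == m, ]
    n_exact <- sum(sub$mesh_term_ids == "leukemia")
    n_broad <- sum(sub$mesh_term_ids %in%
                     c("leukemia", "neoplasms-by-histologic-type"))
    expect_lte(n_exact, n_broad)
    expect_lte(n_broad, nrow(sub))
  }

  # every record is supported by exactly one synthetic publication
  expect_true(all(grepl("^SYN[0-9]+$", recs$pmids)))

  # deterministic construction
  expect_identical(paper_corpus(), corp)
})

test_that("random specs are reproducible and valid", {
  s1 <- random_spec(11, n_mirnas = 5, max_per_stratum = 4)
  s2 <- random_spec(11, n_mirnas = 5, max_per_stratum = 4)
  expect_identical(s1, s2)

  s0 <- random_spec(3, n_mirnas = 3, max_per_stratum = 0)
  counts <- as.matrix(s0$strata[, -1L])
  expect_true(all(counts == 0L))

  ont <- paper_ontology()
  for (seed in 1:25) {
    sp <- random_spec(seed, n_mirnas = 4, max_per_stratum = 5)
    expect_true(all(as.matrix(sp$strata[, -1L]) >= 0L))
    expect_silent(meshmir:::validate_spec_terms(sp, ont))
  }
  expect_error(random_spec(1, n_mirnas = 0), class = "meshmir_usage_error")
})

test_that("the generator honors its stratum counts exactly", {
  ont <- paper_ontology()
  spec <- corpus_spec(data.frame(
    mirna_id = c("syn-miR-001", "syn-miR-002"),
    exact_predicted = c(3L, 0L), exact_validated = c(1L, 0L),
    broader_only_predicted = c(2L, 0L), broader_only_validated = c(0L, 0L),
    unrelated_total = c(4L, 0L), stringsAsFactors = FALSE), seed = 5L)
  corp <- random_corpus(spec, ont)
  expect_identical(n_records(corp), 10L)
  expect_identical(corp$roster, spec$strata$mirna_id)

  survivors <- mesh_filter(corp, ont, "leukemia", "exact")
  tal <- tally(survivors)
  expect_identical(tal$predicted_count[tal$mirna_id == "syn-miR-001"], 3L)
  expect_identical(tal$validated_count[tal$mirna_id == "syn-miR-001"], 1L)
  expect_identical(sum(tal$predicted_count + tal$validated_count), 4L)
})

test_that("an all-zero spec yields an empty corpus with an intact roster", {
  spec <- random_spec(9, n_mirnas = 3, max_per_stratum = 0)
  corp <- random_corpus(spec, paper_ontology())
  expect_identical(n_records(corp), 0L)
  expect_identical(corp$roster, spec$strata$mirna_id)
})

test_that("identical (spec, seed) gives byte-identical corpora; different seeds preserve tallies", {
  ont <- paper_ontology()
  spec <- random_spec(21, n_mirnas = 4, max_per_stratum = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(random_corpus(spec, ont), f1)
  write_corpus(random_corpus(spec, ont), f2)
  expect_identical(readLines(f1), readLines(f2))

  spec_b <- spec
  spec_b$seed <- 22L
  a <- random_corpus(spec, ont)
  b <- random_corpus(spec_b, ont)
  for (term in c("leukemia", "neoplasms-by-histologic-type")) {
    expect_identical(tally(mesh_filter(b, ont, term, "exact")),
                     tally(mesh_filter(a, ont, term, "exact")))
  }
  expect_false(identical(a$records$gene_symbol, b$records$gene_symbol))
})

test_that("generation fails loudly on invalid spec terms", {
  ont <- paper_ontology()
  spec <- random_spec(2, n_mirnas = 2)
  spec$broader_annotation_term_id <- "diabetes-mellitus"
  expect_error(random_corpus(spec, ont), "ancestor",
               class = "meshmir_data_error")
  spec2 <- random_spec(2, n_mirnas = 2)
  spec2$unrelated_term_id <- "neoplasms-by-histologic-type"
  expect_error(random_corpus(spec2, ont), "unrelated",
               class = "meshmir_data_error")
  expect_error(
    corpus_spec(data.frame(mirna_id = "m", exact_predicted = -1L,
                           exact_validated = 0L, broader_only_predicted = 0L,
                           broader_only_validated = 0L, unrelated_total = 0L)),
    "negative", class = "meshmir_data_error")
})

test_that("the replication plan recovers spec strata from generated corpora", {
  ont <- paper_ontology()
  plan <- paper_plan()
  for (seed in 1:20) {
    spec <- random_spec(seed, n_mirnas = 5, max_per_stratum = 4)
    corp <- random_corpus(spec, ont)
    report <- run_pipeline(corp, ont, plan)
    st <- spec$strata
    expect_identical(report$initial_pairs,
                     sum(st$exact_predicted + st$exact_validated +
                           st$broader_only_predicted +
                           st$broader_only_validated + st$unrelated_total))
    expect_identical(report$round_reports[[1L]]$surviving_pairs,
                     sum(st$exact_predicted + st$exact_validated +
                           st$broader_only_predicted +
                           st$broader_only_validated))
    expect_identical(report$round_reports[[2L]]$surviving_pairs,
                     sum(st$exact_predicted + st$exact_validated))
    tal1 <- report$round_reports[[1L]]$tallies
    for (i in seq_len(nrow(st))) {
      m <- st$mirna_id[i]
      j <- match(m, tal1$mirna_id)
      if (!is.na(j)) {
        expect_identical(tal1$predicted_count[j],
                         st$exact_predicted[i] + st$broader_only_predicted[i],
                         label = sprintf("seed=%d %s", seed, m))
        expect_identical(tal1$validated_count[j],
                         st$exact_validated[i] + st$broader_only_validated[i])
      }
    }
  }
})
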