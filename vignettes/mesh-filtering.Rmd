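---
title: "Ontology-driven filtering of miRNA target evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven filtering of miRNA target evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshmir)
```

## The filtering model

`meshmir` narrows a corpus of miRNA:target evidence records down to the
records relevant to a disease context, using the subsumption structure of a
MeSH-style vocabulary rather than free-text matching.

The substrate is an **is_a hierarchy**: a set of terms, each with a unique
identifier, a preferred label (unique case-insensitively), optional synonyms
and zero or more parents. The structure is a DAG, not a tree — real MeSH
descriptors sit in a poly-hierarchy, and the load-time validator only rejects
cycles, dangling parent references and duplicate identifiers or labels.
Because acyclicity is established at load, every traversal terminates.

A query term `t` and a **match mode** define an expansion set:

* *Exact-Match* — `{t}`; the depth argument is ignored.
* *Broader-Match* — `t` plus its ancestors within `max_depth` is_a steps.
  This widens a query that proved too specific.
* *Narrower-Match* — `t` plus its descendants within `max_depth` steps,
  for queries that are too general.

A record survives a round exactly when its own annotation list intersects
the expansion set. Two semantic choices deserve emphasis:

* **Containment is literal.** A record annotated only with a *descendant*
  of the query term (say, the B-cell leukemia term when the query is the
  leukemia term) does not survive an exact or broader match on the query.
  No inference is applied to the record side. This mirrors how the two-round
  leukemia workflow behaves in practice: records related to other neoplasm
  subtypes are excluded in the exact round even though their annotations are
  ontologically related to the query, and it keeps round results a pure
  function of the stored annotations.
* **Depth is a parameter.** The broader expansion accepts `max_depth`
  (default unbounded, i.e. all ancestors). The bundled replication plan sets
  depth 1 — only the direct parent — because that is the configuration under
  which the reference workflow was run. Both semantics are expressible; the
  bundled corpus annotates broader-only records with the direct parent term
  only, so its results are identical under either depth.

## Records, corpora and tallies

A record is one `(miRNA, gene, evidence)` assertion, with evidence either
`predicted` (a computational prediction database) or `validated`
(experimental support), plus the reporting database, supporting publication
identifiers and MeSH annotations. The same gene may legitimately appear
under both evidence classes for one miRNA — prediction and validation are
reported separately — so uniqueness is enforced on the full triple, and a
target reported by several prediction databases is stored once. A corpus
carries a **roster** of miRNAs under study that may be wider than the miRNAs
with records: a literature-derived candidate can enter the analysis with
zero targets and must still appear (as zeros) in every tally.

Tallies count distinct `(gene, evidence)` pairs per roster miRNA, ordered by
descending total, ties broken by descending validated count and then by
name. The same ordering drives prioritization (below). Tally totals conserve
record counts, and all outputs are invariant under permutation of the input
records.

## The pipeline

A plan is declarative (YAML): a publication-support threshold
(`min_publications`, default 1 — a record must be backed by at least one
distinct publication), a switch for zero-target exclusion (default on), and
an ordered list of rounds, each a `(term, mode, depth)` triple. Execution
applies the support filter once, then each round in order with no
short-circuiting. After a round, excluded miRNAs leave the working roster;
their records are necessarily already absent, so exclusion never changes
later record counts — it changes what the reports enumerate. Round tallies
cover the roster *as it stood entering the round*, so newly zeroed miRNAs
appear explicitly (as the reference workflow's tables print them) before
being dropped.

The reduction statistic is `100 × (1 − final/initial)` in **pairs**
(records), not genes, rounded half-up to one decimal; it is defined as 0
for an empty initial corpus. Half-up rounding is deliberate: base R's
`round()` rounds half to even, which would print boundary cases differently
from the convention used in this literature.

Prioritization is a labeled **heuristic**, not a discovery procedure: order
by the tally rule and flag miRNAs retaining at least one predicted *and*
one validated target (`dual_evidence`). On the bundled fixture it surfaces
hsa-miR-142-3p and hsa-miR-17-5p — the pair the source workflow ultimately
selected by expert literature review — but expert judgment is what that
selection was, and the flag only encodes a defensible proxy for it.

```{r pipeline}
report <- run_pipeline(paper_corpus(), paper_ontology(), paper_plan())
summary(report)
report$prioritized
```

## The bundled fixture and the generator

`paper_ontology()` is a nine-term hierarchy: the leukemia term under its
direct parent (neoplasms by histologic type), the lymphoid subtree with the
B-cell and T-cell terms, the three T-cell offspring terms, and one disjoint
disease term (diabetes mellitus) used for annotations unrelated to the
query. Identifiers are deterministic slugs of the labels
(`term_slug("Leukemia, B-Cell")` is `leukemia-b-cell`), not real MeSH
descriptor UIs — inventing realistic-looking UIs would assert registry
facts the package cannot guarantee.

`paper_corpus()` realizes the published per-miRNA counts as three strata per
miRNA: records that survive the exact round (the named target genes of the
five surviving miRNAs, annotated with the query term), records that survive
only the broader round (synthetic gene symbols, annotated with the direct
parent), and unrelated records (annotated with the disjoint term). Synthetic
gene symbols follow `<miRNA>-Tn` and publication ids `SYNnnnnn`, clearly
non-real by construction; source databases rotate through four fixed labels.
The unrelated stratum's evidence class is fixed to `predicted`: the input
tables never split that stratum by evidence, every filter in scope is
indifferent to it, and a fixed choice keeps construction deterministic.
Construction validates the stratum arithmetic (exact ≤ broader ≤ total per
miRNA) and fails loudly rather than emit an inconsistent corpus.

`random_corpus()` generalizes the same three-stratum layout to arbitrary
counts (`corpus_spec`), with seeded determinism: identical spec and seed
give byte-identical serialized corpora, while different seeds preserve all
stratum tallies and vary only incidental content (gene-symbol tags, the
evidence split of the unrelated stratum). That makes generated corpora an
*oracle with known answers*: running the two-round plan must recover the
spec's stratum sums exactly, which the test suite checks across seeds.

What the generator does **not** emulate: multi-term annotations per record
(real records often carry several descriptors; the filters support this,
the generator emits one), disagreement between databases, annotation noise
or missingness, and real miRBase/registry content. Passing tests therefore
demonstrate the correctness of the filtering semantics, not robustness to
noisy real-world annotation practice.

## Numerical and interface choices

* All returned term collections and report rows are deterministically
  ordered (sorted identifiers; the tally ordering rule), so reports are
  byte-reproducible and diffable; rendering a report twice yields identical
  bytes.
* Label search is case-insensitive and whitespace-normalized; identifiers
  match exactly. `"beginning"` mode matches label or synonym prefixes,
  `"anywhere"` substrings; beginning-mode hits are always a subset of
  anywhere-mode hits.
* Multi-valued TSV cells use `|` with no quoting; the empty cell is the
  empty collection. Corpora round-trip exactly through both the TSV and
  JSON dialects.
* The command-line layer exits 0 on success with results, 1 on an empty
  result set, 2 on usage or configuration errors, 3 on data validation
  errors, and never writes partial outputs on failure.

## Scale of the verification suite

The property suites run at desk scale, chosen to exercise the combinatorics
while keeping the full test run fast: 200 seeded random DAGs of up to 12
nodes for the closure-versus-brute-force oracle checks (a size at which
exhaustive path enumeration is still instant), 100 seeded corpora for filter
monotonicity, idempotence and commutation, and 100 seeded specs for
generator recovery. The brute-force oracle enumerates parent paths with no
visited set — an intentionally naive, independent computation of
reachability.

## Limitations

* Only is_a transitivity is modeled: no other ontology relations, no upper
  level reasoning, no OWL semantics.
* The OBO reader honors the tag subset the package emits (`id`, `name`,
  `synonym`, `is_a`) and skips everything else with a notice; it is not a
  general OBO parser.
* No live federation with target prediction databases or publication
  registries: corpora are files, and miRNA names are free text in the
  miRBase style, not validated against a registry.
* The dual-evidence prioritization is a convention for surfacing candidates
  and is labeled as such in every report.
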