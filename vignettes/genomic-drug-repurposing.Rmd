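---
title: "Genomic-network drug repurposing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-network drug repurposing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwas2drug)
```

## The procedure and its assumptions

gwas2drug implements a genomics-first drug-repurposing workflow for a
disease trait (the motivating application is acute lymphoblastic
leukemia). The pipeline treats curated association hits as the primary
signal and layers progressively broader biological context on top:

1. **Variant selection** keeps catalog rows with association
   p-value ≤ `p_max` and odds ratio strictly above `or_min`. The OR gate
   is directional — the workflow targets *risk*-increasing alleles — so a
   record with no reported OR is uninformative for the rule and is
   dropped (and counted). Duplicate rsIDs are collapsed to unique
   variants; the number of catalog rows per variant is retained as its
   "hit" multiplicity, defined as input rows per rsID (a catalog may list
   one row per study or per trait; the package is agnostic and simply
   counts rows).
2. **LD expansion** admits proxy variants at r² ≥ `r2_min`, one hop only:
   proxies of proxies are not chased, because transitive r² chaining is
   not a valid LD relation and the upstream proxy services report only
   first-degree proxies. The threshold is inclusive by default (the
   conventional proxy cut is r² ≥ 0.8); `r2_inclusive = FALSE` gives the
   strict "> 0.8" reading.
3. **Six-criterion scoring** assigns one point per line of functional
   evidence: missense variant, significant cis-eQTL in the gated tissue
   (default whole blood, the accessible tissue for a hematological
   trait), annotation presence in each of the three GO namespaces, and
   membership in at least one enriched KEGG set. GO criteria are
   *presence*-based (≥ 1 term in the namespace), not enrichment-based:
   observed molecular-function coverage above 80% of a gene list is
   consistent only with presence, since namespace-level enrichment of a
   GWAS gene list rarely flags a majority of it. KEGG is the one
   enrichment-based criterion, because raw pathway membership is nearly
   universal and would not discriminate.
4. **Classification** calls genes scoring ≥ 2 of 6 *biological risk
   genes*. The threshold asks for two independent lines of evidence; one
   annotation hit alone is too weak given how generic GO coverage is.
5. **Network expansion** grows the risk set by its first interaction
   shell under a fixed budget. "Budget" here is interactor count, not
   edge count: the conventional web default of 50 added interactors is
   what makes 42 seeds grow to 92 targets.
6. **Druggability and ranking** intersect the expanded set with a
   filtered drug-target table, then rank the overlapped drugs by their
   connectivity score against a comparator, keeping scores strictly
   above +80 (strong positive correlation — the candidate's
   transcriptional signature mimics the comparator's).

The connectivity score itself is an *input*: computing it requires a
perturbational transcriptome compendium, and the pipeline consumes a
drug → score table in [−100, 100] rather than re-deriving it.

## The enrichment statistic

KEGG enrichment uses the EASE score: for a list of `n` genes overlapping
a pathway in `k` genes, with `K` of `N` background genes annotated,

$$p = P(X \ge k - 1), \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

Deflating the overlap by one is the conservative convention of the DAVID
service this stage stands in for: it makes a single-gene overlap
unreportable (p = 1) and penalizes small categories. Plain one-tailed
Fisher (`ease = FALSE`) is available. The implementation delegates the
tail probability to `stats::phyper`; the test suite checks it against
exhaustive summation of the hypergeometric pmf for every configuration
with N ≤ 25 at 10⁻¹² absolute tolerance.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `p_max` | 1e-5 | p-value | catalog-wide suggestive-significance cut used by the study design |
| `or_min` | 1 (exclusive) | odds ratio | risk direction only |
| `r2_min` | 0.8 (inclusive) | r² | conventional strong-proxy threshold |
| `score_threshold` | 2 | criteria (0–6) | two independent evidence lines |
| `enrich_p` | 0.05 | EASE p | single-threshold filter; no multiplicity correction (see limitations) |
| `eqtl_tissue` | "whole blood" | tissue label | accessible tissue for hematological traits |
| `max_interactors` | 50 | genes | first-shell web default; 42 + 50 = 92 targets |
| `min_confidence` | 0.4 | edge confidence | "medium confidence" interaction cut |
| `score_min` | 80 (exclusive) | connectivity score | strong positive correlation |
| `comparator` | dasatinib | drug | standard-of-care TKI anchor for Ph+ ALL |

All thresholds surface as named config keys in the `run_pipeline()`
config; none are hard-coded in stage logic.

## What the synthetic generator emulates

`simulate_inputs()` fabricates every input dialect with planted truth:

- **Catalog**: 74 surviving variants across 57 genes, with duplicate rows
  Poisson-inflated (mean 0.73/variant) to ≈ 128 catalog hits, decoy
  variants failing each filter arm (high p, low OR, missing OR), and LD
  proxy rows straddling the r² cut, a few of which deliver genes not
  reachable from the catalog alone.
- **Annotations**: the six criterion memberships are drawn independently
  per gene with the observed study marginals (7, 12, 30, 36, 47, 5 out of
  57). Independence is a modeling choice — only marginals are known, and
  it makes planted-truth recovery provable. KEGG sets are built so the
  EASE filter at p ≤ 0.05 recovers exactly the planted KEGG-true genes:
  the planted pathway contains exactly those genes, decoy pathways touch
  the list in at most one (KEGG-false) gene, and a verification pass
  re-runs the package's own enrichment before accepting the draw. Because
  an overlap of one or two genes can never reach p ≤ 0.05 under the EASE
  deflation at these background sizes, the KEGG column is redrawn when
  the Bernoulli draw lands on exactly 1 or 2 members (probability ≈ 0.12
  at the default marginal) — a small, documented distortion of that one
  marginal.
- **Network**: preferential attachment (`igraph::sample_pa`, power 1,
  m = 2) over seeds + 50 planted interactors + 400 background nodes.
  Seed–interactor edges get confidences in [0.85, 0.99], all others in
  [0.4, 0.8], so the planted shell is exactly the top of the interactor
  ranking by construction.
- **Drugs and scores**: a planted druggable subset of the expanded genes
  (fraction 0.3), decoy records failing each druggability gate, and
  connectivity scores placing `round(10 × max(0, comparator_correlation))`
  candidate drugs strictly above +80 (5 at the default 0.5), the rest
  below 75.

What it does **not** emulate: realistic LD block structure, GO DAG
topology, correlated criteria (real annotation criteria are positively
correlated through gene function), hub-biased druggability, or the
cell-line/dose/time structure behind real connectivity scores. Passing
tests therefore demonstrate that the *pipeline logic* is exact and
deterministic given tables — not that the biological databases themselves
would yield these numbers.

## Numerical and design choices

- **Serialization**: reals are written with the shortest decimal string
  that reparses to the identical double, so table round-trips are
  record-for-record exact and byte-stable across runs.
- **Rounding**: coverage percentages use half-up rounding to one decimal
  (base R's banker's rounding would print 21.0 where the convention
  prints 21.1). An exhaustive scan shows the printed GO percentages
  52.6 / 63.2 / 82.5 identify unique counts (30 / 36 / 47) out of 57 —
  which is how the packaged evidence fixture's marginals are pinned down.
- **Tie-breaks** are total and deterministic everywhere: interactors by
  (max confidence, summed confidence, symbol), scores by (score, symbol),
  enrichment by (p, set id), ranked drugs by (score, name). Stage outputs
  are invariant under input-row permutation.
- **Degenerate inputs**: an empty association table (or an empty
  risk-gene set) short-circuits the pipeline with zero downstream counts
  and a warning rather than an error; an empty edge list returns the
  seeds unchanged with a warning; the comparator found among candidates
  is removed and logged.
- **Gene-group labels** in the hit summary keep multi-gene catalog cells
  intact ("SLC7A8, CEBPE") rather than exploding them — the summary
  mirrors the shape of the study's per-gene table, while `collect_genes()`
  explodes cells for the analysis gene pool. Variants with no known gene
  are grouped under "(unknown)" and excluded from the pool (but counted).
- **Fixture design**: the packaged 57-gene evidence matrix is synthetic.
  Its row sums (score distribution 4×0, 11×1, 12×2, 19×3, 10×4, 1×5) and
  column sums (the six marginals) are jointly forced by the published
  summary numbers — the total of the marginals (137) equals the total of
  the scores only for this distribution — and a greedy assignment
  realizes them. The top scorer carries every criterion except KEGG; the
  published account does not say which five criteria it met, so that is
  a fixture convention, not a claim.
- **Problem sizes** in the test suite are deliberately small (20-gene,
  120-node bundles for the 20-seed recovery sweep; N ≤ 25 for the
  exhaustive enrichment scan; ≤ 25-row instances for the oracle trials)
  — chosen so the full suite exercises every stage against brute-force
  references in well under a minute.

## Known limitations

- No multiplicity correction across enriched sets (single-threshold
  filter, matching the upstream design); with many candidate pathways,
  apply your own FDR control upstream of the KEGG criterion.
- Gene symbols are opaque case-insensitive identifiers; no alias
  resolution is attempted, so inputs from different database snapshots
  must be pre-harmonized.
- Single-tissue eQTL gating; multi-tissue evidence models are out of
  scope.
- The druggable-gene/drug counts of a real run depend entirely on the
  drug-database snapshot supplied; the package checks structural
  properties (subset relations, commutation of filter and overlap), not
  snapshot-specific counts.
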