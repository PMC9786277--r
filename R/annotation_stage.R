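# Six-criterion functional annotation stage: evidence assembly, EASE-style
# KEGG enrichment, 0-6 scoring, risk-gene classification, coverage report.

#' Assemble the functional-annotation evidence container
#'
#' Bundles the four annotation inputs plus the enrichment background into a
#' single validated object consumed by [assemble_evidence()] and
#' [enrich_sets()].
#'
#' @param missense_genes genes carrying a missense variant.
#' @param eqtl data.frame `gene`, `tissue`, `significant` (cis-eQTL calls).
#' @param go data.frame `gene`, `term`, `namespace` (`BP`/`CC`/`MF`).
#' @param kegg_sets named list: pathway id -> character vector of genes.
#' @param background enrichment universe; must contain every annotated gene.
#' @return an `annotation_table` list.
#' @export
annotation_table <- function(missense_genes = character(),
                             eqtl = NULL, go = NULL,
                             kegg_sets = list(),
                             background = character()) {
  eqtl <- eqtl %||% data.frame(gene = character(), tissue = character(),
                               significant = logical())
  go <- go %||% data.frame(gene = character(), term = character(),
                           namespace = character())
  stopifnot(all(c("gene", "tissue", "significant") %in% names(eqtl)),
            all(c("gene", "term", "namespace") %in% names(go)))
  if (!all(go$namespace %in% c("BP", "CC", "MF")))
    stop("GO namespace must be one of BP, CC, MF")
  missense_genes <- norm_symbols(missense_genes)
  eqtl$gene <- toupper(trimws(eqtl$gene))
  go$gene <- toupper(trimws(go$gene))
  kegg_sets <- lapply(kegg_sets, norm_symbols)
  background <- norm_symbols(background)
  annotated <- unique(c(missense_genes, eqtl$gene, go$gene,
                        unlist(kegg_sets, use.names = FALSE)))
  missing_bg <- setdiff(annotated, background)
  if (length(missing_bg))
    stop("background must contain every annotated gene; missing e.g. ",
         paste(utils::head(missing_bg, 5), collapse = ", "))
  structure(list(missense_genes = missense_genes, eqtl = eqtl, go = go,
                 kegg_sets = kegg_sets, background = background),
            class = "annotation_table")
}

#' EASE enrichment probability
#'
#' Upper-tail hypergeometric probability with the list-overlap count
#' reduced by one (the DAVID EASE convention): for a gene list of size `n`
#' overlapping an annotation category in `k` genes, with `K` of `N`
#' background genes annotated, returns `P(X >= k - 1)` for
#' `X ~ Hypergeometric(N, K, n)`. The deflated overlap makes the statistic
#' conservative for single-gene overlaps: `k <= 1` returns exactly 1.
#' `ease = FALSE` gives the plain one-tailed Fisher probability
#' `P(X >= k)`.
#'
#' @param k list genes annotated to the category.
#' @param n list size.
#' @param K background genes annotated to the category.
#' @param N background size.
#' @param ease apply the EASE k-1 deflation (default) or plain Fisher.
#' @return the enrichment p-value in (0, 1].
#' @export
ease_score <- function(k, n, K, N, ease = TRUE) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (is.na(k) || is.na(n) || is.na(K) || is.na(N) ||
      k < 0 || k > min(n, K) || n > N || K > N || N < 1)
    stop("invalid enrichment arguments: need 0 <= k <= min(n, K), n <= N, K <= N")
  a <- if (ease) k - 1 else k
  if (a <= 0) return(1.0)
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment scan over gene sets
#'
#' Scores every candidate set that overlaps the gene list in at least one
#' gene with [ease_score()] and returns those at `ease_p <= p_cut`, sorted
#' ascending by p with ties broken by set id.
#'
#' @param list_genes the gene list (must be contained in `background`).
#' @param sets named list: set id -> gene vector.
#' @param background enrichment universe.
#' @param p_cut significance threshold (default 0.05; `1` disables
#'   filtering).
#' @param ease passed to [ease_score()].
#' @return data.frame `set_id`, `k`, `n`, `K`, `N`, `ease_p`.
#' @export
enrich_sets <- function(list_genes, sets, background, p_cut = 0.05,
                        ease = TRUE) {
  background <- norm_symbols(background)
  if (!length(background)) stop("empty enrichment background")
  list_genes <- norm_symbols(list_genes)
  if (length(setdiff(list_genes, background)))
    stop("list_genes must be a subset of the background universe")
  N <- length(background)
  n <- length(list_genes)
  res <- lapply(names(sets), function(id) {
    members <- intersect(norm_symbols(sets[[id]]), background)
    k <- length(intersect(list_genes, members))
    if (k < 1) return(NULL)
    data.frame(set_id = id, k = k, n = n, K = length(members), N = N,
               ease_p = ease_score(k, n, length(members), N, ease = ease),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(
    data.frame(set_id = character(), k = integer(), n = integer(),
               K = integer(), N = integer(), ease_p = numeric(),
               stringsAsFactors = FALSE))))
  out <- out[out$ease_p <= p_cut, , drop = FALSE]
  out <- out[order(out$ease_p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the six-criterion evidence matrix
#'
#' One row per gene with the six boolean criteria: missense variant,
#' significant cis-eQTL in the target tissue, annotation presence in each
#' GO namespace (BP, CC, MF), and membership in at least one enriched KEGG
#' set. GO criteria are presence-based (>= 1 term in the namespace), not
#' significance-based.
#'
#' @param genes gene list (non-empty).
#' @param ann an [annotation_table()].
#' @param enriched result of [enrich_sets()] on the KEGG sets (may have
#'   zero rows).
#' @param eqtl_tissue tissue gate for the cis-eQTL criterion
#'   (case-insensitive; default `"whole blood"`).
#' @return evidence data.frame `gene`, `missense`, `cis_eqtl`, `go_bp`,
#'   `go_cc`, `go_mf`, `kegg`, one row per input gene, sorted by symbol.
#' @export
assemble_evidence <- function(genes, ann, enriched = NULL,
                              eqtl_tissue = "whole blood") {
  genes <- sort(norm_symbols(genes))
  if (!length(genes)) stop("gene list must be non-empty")
  stopifnot(inherits(ann, "annotation_table"))
  eq <- ann$eqtl
  eq_genes <- unique(eq$gene[eq$significant &
                             tolower(trimws(eq$tissue)) ==
                             tolower(trimws(eqtl_tissue))])
  ns_genes <- function(ns) unique(ann$go$gene[ann$go$namespace == ns])
  enriched_ids <- if (is.null(enriched)) character() else enriched$set_id
  kegg_genes <- unique(unlist(ann$kegg_sets[enriched_ids], use.names = FALSE))
  data.frame(
    gene = genes,
    missense = genes %in% ann$missense_genes,
    cis_eqtl = genes %in% eq_genes,
    go_bp = genes %in% ns_genes("BP"),
    go_cc = genes %in% ns_genes("CC"),
    go_mf = genes %in% ns_genes("MF"),
    kegg = genes %in% kegg_genes,
    stringsAsFactors = FALSE
  )
}

.criteria <- c("missense", "cis_eqtl", "go_bp", "go_cc", "go_mf", "kegg")

#' Score genes on the six criteria
#'
#' One point per fulfilled criterion (0-6); genes at or above the
#' threshold are flagged as biological risk genes. Output is sorted by
#' descending score, ties broken lexicographically by symbol.
#'
#' @param evidence evidence data.frame from [assemble_evidence()].
#' @param threshold risk-gene score floor, inclusive (default 2).
#' @return data.frame `gene`, `score`, `is_risk_gene`.
#' @export
score_genes <- function(evidence, threshold = 2) {
  score <- as.integer(rowSums(evidence[, .criteria, drop = FALSE]))
  out <- data.frame(gene = evidence$gene, score = score,
                    is_risk_gene = score >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Biological risk genes
#'
#' @param scores data.frame from [score_genes()].
#' @return sorted character vector of genes flagged `is_risk_gene`.
#' @export
classify_risk_genes <- function(scores) {
  sort(scores$gene[scores$is_risk_gene])
}

#' Per-criterion coverage report
#'
#' Counts and percentages of genes fulfilling each criterion, plus the
#' fraction classified as risk genes at the given threshold. Percentages
#' are half-up rounded to one decimal.
#'
#' @param evidence evidence data.frame (non-empty).
#' @param threshold risk-gene score floor used for the `risk_gene` row.
#' @return data.frame `criterion`, `count`, `percentage`.
#' @export
criterion_coverage <- function(evidence, threshold = 2) {
  if (!nrow(evidence)) stop("evidence must be non-empty")
  total <- nrow(evidence)
  counts <- vapply(.criteria, function(cr) sum(evidence[[cr]]), integer(1))
  risk <- sum(rowSums(evidence[, .criteria, drop = FALSE]) >= threshold)
  out <- data.frame(
    criterion = c(.criteria, "risk_gene"),
    count = as.integer(c(counts, risk)),
    percentage = round_half_up(100 * c(counts, risk) / total, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
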