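# Interaction-network expansion: grow the risk-gene seed set by its
# top-ranked first-shell interactors under a fixed budget.

#' Network expansion configuration
#'
#' @param max_interactors first-shell interactor budget (default 50, the
#'   conventional "max interactors" web default).
#' @param min_confidence minimum edge confidence for an interactor to
#'   qualify (default 0.4, "medium confidence").
#' @return an `expansion_config` list.
#' @export
expansion_config <- function(max_interactors = 50, min_confidence = 0.4) {
  stopifnot(max_interactors >= 0, min_confidence >= 0, min_confidence <= 1)
  structure(list(max_interactors = as.integer(max_interactors),
                 min_confidence = min_confidence),
            class = "expansion_config")
}

#' Expand a seed gene set over a weighted interaction network
#'
#' Candidate interactors are non-seed genes adjacent to at least one seed
#' through an edge with confidence at or above `min_confidence`.
#' Candidates are ranked by (1) maximum qualifying edge confidence to any
#' seed, (2) sum of qualifying seed-edge confidences, (3) gene symbol
#' ascending, and the top `max_interactors` are appended to the seeds.
#' The ranking is deterministic and invariant under edge-list permutation.
#'
#' @param seeds character vector of seed genes (non-empty).
#' @param edges edges data.frame (`gene_a`, `gene_b`, `confidence`).
#' @param cfg an [expansion_config()].
#' @return data.frame `gene`, `role` (`"seed"`/`"interactor"`),
#'   `max_confidence`, `sum_confidence`; seeds first (sorted), then
#'   interactors in rank order. The expanded gene set is the `gene` column.
#' @export
expand_network <- function(seeds, edges, cfg = expansion_config()) {
  seeds <- sort(norm_symbols(seeds))
  if (!length(seeds)) stop("seed set must be non-empty")
  seed_rows <- data.frame(gene = seeds, role = "seed",
                          max_confidence = NA_real_,
                          sum_confidence = NA_real_,
                          stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(edges)) {
    warning("empty edge list: returning seeds unchanged")
    return(seed_rows)
  }
  # orient every qualifying edge as seed -> candidate
  ok <- edges$confidence >= cfg$min_confidence
  a_seed <- edges$gene_a %in% seeds
  b_seed <- edges$gene_b %in% seeds
  cand <- c(edges$gene_b[ok & a_seed & !b_seed],
            edges$gene_a[ok & b_seed & !a_seed])
  conf <- c(edges$confidence[ok & a_seed & !b_seed],
            edges$confidence[ok & b_seed & !a_seed])
  if (!length(cand) || cfg$max_interactors == 0L) return(seed_rows)
  mx <- tapply(conf, cand, max)
  sm <- tapply(conf, cand, sum)
  rank_df <- data.frame(gene = names(mx), max_confidence = as.numeric(mx),
                        sum_confidence = as.numeric(sm),
                        stringsAsFactors = FALSE)
  rank_df <- rank_df[order(-rank_df$max_confidence, -rank_df$sum_confidence,
                           rank_df$gene), , drop = FALSE]
  rank_df <- utils::head(rank_df, cfg$max_interactors)
  rank_df$role <- "interactor"
  out <- rbind(seed_rows, rank_df[, names(seed_rows)])
  rownames(out) <- NULL
  out
}
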