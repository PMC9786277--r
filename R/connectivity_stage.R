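# Connectivity-score ranking of candidate drugs against a comparator.

#' Connectivity ranking configuration
#'
#' @param comparator comparator drug excluded from the candidate list
#'   (default `"dasatinib"`, the standard-of-care tyrosine kinase
#'   inhibitor anchor).
#' @param score_min exclusive connectivity-score floor (default 80: only
#'   strong positive correlation, score > +80, is kept).
#' @param top_k optional truncation of the ranked list.
#' @return a `ranking_config` list.
#' @export
ranking_config <- function(comparator = "dasatinib", score_min = 80,
                           top_k = NULL) {
  stopifnot(score_min >= -100, score_min <= 100)
  structure(list(comparator = comparator, score_min = score_min,
                 top_k = top_k),
            class = "ranking_config")
}

#' Rank candidate drugs by connectivity score
#'
#' Removes the comparator if present, keeps drugs with score strictly
#' above `score_min` (a score of exactly 80 is excluded under the
#' default), sorts descending by score with ties broken by drug name, and
#' optionally truncates to `top_k`. Scores pass through unmodified.
#'
#' @param records connectivity data.frame (`drug`, `score`).
#' @param cfg a [ranking_config()].
#' @return ranked data.frame `drug`, `score`.
#' @export
rank_candidates <- function(records, cfg = ranking_config()) {
  is_cmp <- tolower(trimws(records$drug)) == tolower(trimws(cfg$comparator))
  if (any(is_cmp))
    message("comparator '", cfg$comparator, "' removed from candidates")
  out <- records[!is_cmp & records$score > cfg$score_min, , drop = FALSE]
  out <- out[order(-out$score, tolower(out$drug)), , drop = FALSE]
  if (!is.null(cfg$top_k)) out <- utils::head(out, cfg$top_k)
  rownames(out) <- NULL
  out
}

#' Attach target genes to ranked drugs
#'
#' Inverts the gene-drug bipartite map from [overlap_druggable()] so each
#' ranked drug lists its target genes. Drugs without a mapped gene keep an
#' empty gene field; they are never dropped.
#'
#' @param ranked ranked data.frame from [rank_candidates()].
#' @param bipartite named list gene -> drugs (the `map` element of
#'   [overlap_druggable()]).
#' @return data.frame `drug`, `target_genes` (comma-joined, possibly
#'   empty), `score`, in ranked order.
#' @export
attach_targets <- function(ranked, bipartite) {
  genes_for <- function(drug) {
    d <- tolower(trimws(drug))
    hit <- vapply(bipartite, function(ds) d %in% ds, logical(1))
    paste(sort(names(bipartite)[hit]), collapse = ", ")
  }
  data.frame(
    drug = ranked$drug,
    target_genes = vapply(ranked$drug, genes_for, character(1),
                          USE.NAMES = FALSE),
    score = ranked$score,
    stringsAsFactors = FALSE
  )
}
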