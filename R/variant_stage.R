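# Variant selection stage: threshold filtering of catalog associations,
# duplicate-variant removal, LD proxy expansion, and the per-gene hit
# summary.

#' Variant filtering configuration
#'
#' Thresholds for the association-selection stage. Defaults follow the
#' study design: associations are kept at p-value <= 1e-5 with odds ratio
#' strictly greater than 1, and LD proxies are admitted at r-squared >= 0.8
#' (the conventional proxy cut; set `r2_inclusive = FALSE` for a strict
#' "> 0.8" rule).
#'
#' @param p_max inclusive p-value ceiling, in (0, 1].
#' @param or_min exclusive odds-ratio floor (>= 0).
#' @param r2_min LD r-squared threshold, in \[0, 1\].
#' @param r2_inclusive admit proxies at exactly `r2_min`?
#' @return a `variant_filter_config` list.
#' @export
variant_filter_config <- function(p_max = 1e-5, or_min = 1,
                                  r2_min = 0.8, r2_inclusive = TRUE) {
  stopifnot(p_max > 0, p_max <= 1, or_min >= 0,
            r2_min >= 0, r2_min <= 1, is.logical(r2_inclusive))
  structure(list(p_max = p_max, or_min = or_min,
                 r2_min = r2_min, r2_inclusive = r2_inclusive),
            class = "variant_filter_config")
}

#' Select risk-associated variants
#'
#' Keeps association rows with `p_value <= p_max` and an odds ratio that is
#' present and strictly greater than `or_min`. Rows without an odds ratio
#' cannot satisfy the risk-direction rule and are dropped. Input order is
#' preserved; counts of dropped rows by reason are attached as the
#' `"dropped"` attribute.
#'
#' @param records associations data.frame (see [read_table()]).
#' @param cfg a [variant_filter_config()].
#' @return the surviving rows, with attribute `dropped` =
#'   `c(p_value, odds_ratio_missing, odds_ratio_low)`.
#' @export
filter_associations <- function(records, cfg = variant_filter_config()) {
  p_ok <- records$p_value <= cfg$p_max
  or_present <- !is.na(records$odds_ratio)
  or_ok <- or_present & records$odds_ratio > cfg$or_min
  keep <- p_ok & or_ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(
    p_value = sum(!p_ok),
    odds_ratio_missing = sum(p_ok & !or_present),
    odds_ratio_low = sum(p_ok & or_present & !or_ok)
  )
  out
}

#' Collapse duplicate variants
#'
#' One record per rsID: the first occurrence is kept, its gene cell becomes
#' the union of gene mappings over all occurrences, and the number of
#' catalog rows per rsID is retained in an `n_hits` column (the
#' "hits in catalog" multiplicity used by [summarize_gene_hits()]).
#'
#' @param records associations data.frame.
#' @return deduplicated data.frame with an extra `n_hits` integer column.
#' @export
dedupe_variants <- function(records) {
  if (!nrow(records)) {
    records$n_hits <- integer()
    return(records)
  }
  first <- !duplicated(records$rsid)
  out <- records[first, , drop = FALSE]
  genes_by_rsid <- tapply(records$genes, records$rsid, function(g)
    paste(unique(unlist(lapply(g, split_genes))), collapse = ", "))
  hits <- table(records$rsid)
  out$genes <- as.character(genes_by_rsid[out$rsid])
  out$n_hits <- as.integer(hits[out$rsid])
  rownames(out) <- NULL
  out
}

#' Expand a variant set by LD proxies
#'
#' Single-hop proxy expansion: proxies of variants already in the set are
#' admitted when their r-squared passes the configured threshold; proxies
#' of proxies are not chased. Gene mappings carried by admitted proxies are
#' returned so they can join the gene pool.
#'
#' @param variants character vector of rsIDs already selected.
#' @param proxies ld_proxies data.frame (see [read_table()]).
#' @param cfg a [variant_filter_config()].
#' @return list with `rsids` (input plus admitted proxies, input order
#'   first) and `genes` (symbols contributed by admitted proxies).
#' @export
expand_ld <- function(variants, proxies, cfg = variant_filter_config()) {
  variants <- unique(variants)
  if (!nrow(proxies))
    return(list(rsids = variants, genes = character()))
  pass <- if (cfg$r2_inclusive) proxies$r2 >= cfg$r2_min else proxies$r2 > cfg$r2_min
  adm <- proxies[pass & proxies$index_rsid %in% variants, , drop = FALSE]
  new_rs <- setdiff(unique(adm$proxy_rsid), variants)
  genes <- unique(unlist(lapply(adm$proxy_genes, split_genes)))
  list(rsids = c(variants, new_rs), genes = genes %||% character())
}

#' Collect the gene pool from selected variants
#'
#' Union of all gene mappings across records plus any proxy-contributed
#' symbols, deduplicated and sorted. Records whose gene cell is blank (the
#' catalog's "not known" mappings) contribute nothing; their count is
#' attached as attribute `n_unknown`.
#'
#' @param records associations data.frame (typically post-dedupe).
#' @param extra_genes additional symbols (e.g. from [expand_ld()]).
#' @return sorted character vector of gene symbols with attr `n_unknown`.
#' @export
collect_genes <- function(records, extra_genes = character()) {
  lists <- lapply(records$genes, split_genes)
  unknown <- sum(vapply(lists, length, integer(1)) == 0L)
  pool <- sort(unique(c(unlist(lists), norm_symbols(extra_genes))))
  attr(pool, "n_unknown") <- unknown
  pool
}

#' Per-gene-group SNP and hit summary
#'
#' Reproduces the catalog summary table: one row per mapped-gene group
#' (multi-gene cells are kept as printed, not exploded), with the number of
#' distinct SNPs and the summed catalog-hit multiplicity. Requires
#' [dedupe_variants()] to have been applied (the `n_hits` column).
#' Variants with no known gene are grouped under the label `"(unknown)"`.
#'
#' @param records deduplicated associations with `n_hits`.
#' @return object of class `gene_hit_summary`: list with `rows`
#'   (data.frame `gene_group`, `n_snps`, `n_hits`, ordered by descending
#'   hits then group label), `total_snps`, `total_hits`.
#' @export
summarize_gene_hits <- function(records) {
  if (!"n_hits" %in% names(records))
    stop("records lack n_hits; apply dedupe_variants() first")
  label <- ifelse(nzchar(records$genes), records$genes, "(unknown)")
  if (nrow(records)) {
    n_snps <- tapply(records$rsid, label, function(x) length(unique(x)))
    n_hits <- tapply(records$n_hits, label, sum)
    rows <- data.frame(gene_group = names(n_snps),
                       n_snps = as.integer(n_snps),
                       n_hits = as.integer(n_hits),
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$n_hits, rows$gene_group), , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(gene_group = character(), n_snps = integer(),
                       n_hits = integer(), stringsAsFactors = FALSE)
  }
  structure(list(rows = rows,
                 total_snps = length(unique(records$rsid)),
                 total_hits = sum(records$n_hits)),
            class = "gene_hit_summary")
}

#' @export
print.gene_hit_summary <- function(x, ...) {
  cat(sprintf("Gene hit summary: %d gene groups, %d SNPs, %d catalog hits\n",
              nrow(x$rows), x$total_snps, x$total_hits))
  print(utils::head(x$rows, 10))
  if (nrow(x$rows) > 10) cat("...\n")
  invisible(x)
}
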