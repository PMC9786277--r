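# Druggability stage: drug-target filtering and the gene-drug bipartite
# overlap.

#' Filter a drug-target table by druggability criteria
#'
#' Keeps records with a known pharmacological action, human organism, and
#' at least one development-status group in the allowed set.
#'
#' @param records drug_targets data.frame (see [read_table()]).
#' @param allowed_groups status groups accepted (default approved,
#'   investigational, experimental).
#' @return the surviving rows, order preserved.
#' @export
filter_drug_targets <- function(records,
                                allowed_groups = c("approved",
                                                   "investigational",
                                                   "experimental")) {
  allowed_groups <- tolower(allowed_groups)
  grp_ok <- vapply(strsplit(records$groups, "\\|"), function(g)
    any(tolower(g) %in% allowed_groups), logical(1))
  keep <- records$action_known &
    tolower(trimws(records$organism)) == "humans" & grp_ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-drug bipartite overlap
#'
#' Intersects a gene list with a (pre-filtered) drug-target table. Drug
#' names are trimmed and case-folded for identity, so "Sirolimus" and
#' "sirolimus" count once.
#'
#' @param genes character vector of candidate target genes.
#' @param records filtered drug_targets data.frame.
#' @return list with `map` (named list: druggable gene -> sorted drugs),
#'   `non_druggable` (genes with no drug), `n_druggable_genes`, `n_drugs`
#'   (distinct drugs across the map).
#' @export
overlap_druggable <- function(genes, records) {
  genes <- norm_symbols(genes)
  rec <- records[records$gene %in% genes, , drop = FALSE]
  drug_norm <- tolower(trimws(rec$drug))
  map <- lapply(split(drug_norm, rec$gene), function(d) sort(unique(d)))
  map <- map[order(names(map))]
  list(
    map = map,
    non_druggable = sort(setdiff(genes, names(map))),
    n_druggable_genes = length(map),
    n_drugs = length(unique(drug_norm))
  )
}
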