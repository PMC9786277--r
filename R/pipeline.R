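# End-to-end pipeline runner: reads a declarative config, executes the
# stages in workflow order, writes per-stage TSVs, a JSON run summary and
# a plain-text log.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs))
  th_default <- list(p_max = 1e-5, or_min = 1, r2_min = 0.8,
                     r2_inclusive = TRUE, enrich_p = 0.05,
                     score_threshold = 2, eqtl_tissue = "whole blood",
                     max_interactors = 50, min_confidence = 0.4,
                     comparator = "dasatinib", score_min = 80)
  config$thresholds <- utils::modifyList(th_default,
                                         config$thresholds %||% list())
  required <- c("associations", "ld_proxies", "missense", "eqtl", "go",
                "kegg_gmt", "background", "edges", "drug_targets",
                "connectivity")
  missing_keys <- setdiff(required, names(config$inputs))
  if (length(missing_keys))
    stop("config$inputs lacks: ", paste(missing_keys, collapse = ", "))
  for (k in required)
    if (!file.exists(config$inputs[[k]]))
      stop(sprintf("input '%s' not found: %s", k, config$inputs[[k]]))
  config
}

#' Run the full drug-repurposing pipeline
#'
#' Executes the workflow end to end: variant filtering -> duplicate
#' removal -> LD expansion -> gene collection -> six-criterion evidence
#' and scoring -> risk-gene classification -> network expansion ->
#' druggability overlap -> connectivity ranking. Each stage writes its
#' table under `outdir`; `run_summary.json` records the counts at every
#' stage and `run.log` a human-readable trace. Only connectivity records
#' for drugs present in the gene-drug map are ranked (candidate drugs are
#' those overlapping the target genes). An empty association table yields
#' zero counts downstream with a warning, not an error.
#'
#' @param config path to a YAML config (as written by [simulate_inputs()])
#'   or an equivalent list with `inputs` (named file paths) and
#'   `thresholds`.
#' @param outdir output directory (created if absent).
#' @return invisibly, the run summary as a named list.
#' @export
run_pipeline <- function(config, outdir) {
  config <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  on_fail <- function(e) {
    writeLines(c(log_lines, paste("FAILED:", conditionMessage(e))), log_path)
    writeLines(conditionMessage(e), file.path(outdir, "FAILED"))
    stop(e)
  }
  summary <- tryCatch(run_stages(config, outdir, logf), error = on_fail)
  writeLines(log_lines, log_path)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

run_stages <- function(config, outdir, logf) {
  th <- config$thresholds
  inp <- config$inputs
  vcfg <- variant_filter_config(p_max = th$p_max, or_min = th$or_min,
                                r2_min = th$r2_min,
                                r2_inclusive = th$r2_inclusive)
  zeros <- list(n_expanded_genes = 0L, n_druggable_genes = 0L,
                n_drugs = 0L, n_candidates_scored = 0L, n_ranked = 0L)

  # stage 1: variants
  assoc <- read_table(inp$associations, "associations")
  kept <- filter_associations(assoc, vcfg)
  dropped <- attr(kept, "dropped")
  logf("variant filter: %d rows in, %d kept (dropped: p %d, OR missing %d, OR low %d)",
       nrow(assoc), nrow(kept), dropped["p_value"],
       dropped["odds_ratio_missing"], dropped["odds_ratio_low"])
  dd <- dedupe_variants(kept)
  hit_summary <- summarize_gene_hits(dd)
  gh <- hit_summary$rows
  gh <- rbind(gh, data.frame(gene_group = "TOTAL",
                             n_snps = hit_summary$total_snps,
                             n_hits = hit_summary$total_hits))
  utils::write.table(gh, file.path(outdir, "gene_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  proxies <- read_table(inp$ld_proxies, "ld_proxies")
  exp_ld <- expand_ld(dd$rsid, proxies, vcfg)
  genes <- collect_genes(dd, exp_ld$genes)
  logf("variants: %d unique (%d catalog hits), %d after LD expansion; %d genes",
       nrow(dd), hit_summary$total_hits, length(exp_ld$rsids), length(genes))

  summary <- list(
    associations = list(rows_in = nrow(assoc), rows_kept = nrow(kept),
                        dropped = as.list(dropped)),
    variants = list(n_variants = nrow(dd),
                    n_hits = hit_summary$total_hits,
                    n_after_ld = length(exp_ld$rsids)),
    genes = list(n_genes = length(genes),
                 n_unknown_records = attr(genes, "n_unknown"))
  )

  if (!length(genes)) {
    warning("no genes survive the variant stage; downstream counts are zero")
    return(c(summary, list(scoring = list(n_risk_genes = 0L)), zeros))
  }

  # stage 2: annotation scoring
  ann <- annotation_table(
    missense_genes = read_table(inp$missense, "missense")$gene,
    eqtl = read_table(inp$eqtl, "eqtl"),
    go = read_table(inp$go, "go"),
    kegg_sets = read_table(inp$kegg_gmt, "gmt"),
    background = union(read_table(inp$background, "genes")$gene, genes)
  )
  enriched <- enrich_sets(genes, ann$kegg_sets, ann$background,
                          p_cut = th$enrich_p)
  evidence <- assemble_evidence(genes, ann, enriched,
                                eqtl_tissue = th$eqtl_tissue)
  scores <- score_genes(evidence, threshold = th$score_threshold)
  risk <- classify_risk_genes(scores)
  ev_out <- merge(evidence, scores, by = "gene", sort = TRUE)
  write_table(ev_out[, .dialects$evidence$cols], file.path(outdir, "evidence.tsv"),
              "evidence")
  utils::write.table(scores, file.path(outdir, "gene_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(criterion_coverage(evidence, th$score_threshold),
                     file.path(outdir, "criterion_coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hist_tab <- table(factor(scores$score, levels = 0:6))
  logf("scoring: %d enriched sets; %d/%d risk genes (score >= %d)",
       nrow(enriched), length(risk), length(genes), th$score_threshold)
  summary$scoring <- list(n_enriched_sets = nrow(enriched),
                          n_risk_genes = length(risk),
                          score_histogram = as.list(stats::setNames(
                            as.integer(hist_tab), names(hist_tab))))

  if (!length(risk)) {
    warning("no risk genes at the score threshold; downstream counts are zero")
    return(c(summary, zeros))
  }

  # stage 3: network expansion
  edges <- read_table(inp$edges, "edges")
  ecfg <- expansion_config(max_interactors = th$max_interactors,
                           min_confidence = th$min_confidence)
  expanded <- expand_network(risk, edges, ecfg)
  utils::write.table(expanded, file.path(outdir, "expanded_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("network: %d seeds expanded to %d genes", length(risk), nrow(expanded))
  summary$network <- list(n_seeds = length(risk),
                          n_expanded_genes = nrow(expanded))

  # stage 4: druggability overlap
  targets <- read_table(inp$drug_targets, "drug_targets")
  filtered <- filter_drug_targets(targets)
  overlap <- overlap_druggable(expanded$gene, filtered)
  bip <- data.frame(
    gene = rep(names(overlap$map), lengths(overlap$map)),
    drug = unlist(overlap$map, use.names = FALSE))
  utils::write.table(bip, file.path(outdir, "gene_drug_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("druggability: %d target records, %d pass filters; %d druggable genes, %d drugs",
       nrow(targets), nrow(filtered), overlap$n_druggable_genes,
       overlap$n_drugs)
  summary$drugs <- list(n_target_records = nrow(targets),
                        n_filtered_records = nrow(filtered),
                        n_druggable_genes = overlap$n_druggable_genes,
                        n_drugs = overlap$n_drugs)

  # stage 5: connectivity ranking (candidates = drugs in the bipartite map)
  conn <- read_table(inp$connectivity, "connectivity")
  cand_drugs <- unique(unlist(overlap$map, use.names = FALSE))
  cand <- conn[tolower(trimws(conn$drug)) %in% cand_drugs |
               tolower(trimws(conn$drug)) == tolower(th$comparator), ,
               drop = FALSE]
  rcfg <- ranking_config(comparator = th$comparator, score_min = th$score_min)
  ranked <- rank_candidates(cand, rcfg)
  ranked_tbl <- attach_targets(ranked, overlap$map)
  utils::write.table(ranked_tbl, file.path(outdir, "ranked_drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- do.call(rbind, lapply(seq_len(nrow(ranked)), function(i) {
    gs <- split_genes(ranked_tbl$target_genes[i])
    if (!length(gs)) return(NULL)
    data.frame(drug = ranked$drug[i], gene = gs, score = ranked$score[i])
  }))
  if (is.null(adj))
    adj <- data.frame(drug = character(), gene = character(),
                      score = numeric())
  utils::write.table(adj, file.path(outdir, "drug_gene_adjacency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("ranking: %d candidates scored, %d above %s", nrow(cand) ,
       nrow(ranked), fmt_num(th$score_min))
  summary$ranking <- list(n_candidates_scored = nrow(cand),
                          n_ranked = nrow(ranked),
                          top = if (nrow(ranked)) as.list(ranked[1, ]) else NULL)
  summary
}
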