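# Synthetic-data generator: emits every input dialect with planted,
# exactly recoverable structure so the whole pipeline can be exercised and
# verified offline. Defaults reproduce the study conditions: 74 surviving
# variants over 57 genes with ~128 catalog rows, criterion-fulfilment
# marginals 7/12/30/36/47/5 out of 57, a 50-interactor planted first
# shell, and 5 candidate drugs above the +80 connectivity threshold.

#' Simulation configuration
#'
#' Parameters of the synthetic input bundle. Criterion probabilities
#' default to the observed study marginals (missense 7/57, cis-eQTL 12/57,
#' GO BP 30/57, CC 36/57, MF 47/57, KEGG 5/57). The expected number of
#' drugs exceeding the +80 connectivity threshold is
#' `round(10 * max(0, comparator_correlation))`, i.e. 5 at the default
#' correlation of 0.5.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output tables.
#' @param n_genes planted catalog genes (default 57).
#' @param n_variants planted surviving variants (default 74).
#' @param n_decoy_variants variants that must fail the p/OR filter.
#' @param hit_inflation mean extra catalog rows per surviving variant
#'   (Poisson; default 0.73 so the expected row count is ~128).
#' @param keep_frac probability each planted variant passes the filter
#'   (default 1: all `n_variants` survive).
#' @param criterion_probs named vector of six Bernoulli probabilities for
#'   the evidence criteria.
#' @param n_proxy_admit,n_proxy_reject LD proxy rows above / below the
#'   r-squared cut.
#' @param n_proxy_genes genes delivered only through admitted proxies.
#' @param n_background_genes filler genes in the enrichment universe.
#' @param n_kegg_decoy_sets non-enriched KEGG decoy sets.
#' @param n_network_genes background nodes in the interaction network.
#' @param n_planted_interactors planted first-shell interactors with
#'   strictly top-ranked confidences (default 50).
#' @param attachment_exponent preferential-attachment power of the
#'   scale-free network.
#' @param n_drugs size of the drug name pool.
#' @param frac_druggable fraction of expanded genes given a drug target.
#' @param comparator_correlation correlation proxy in \[-1, 1\] controlling
#'   how many candidate drugs exceed the +80 threshold.
#' @param comparator comparator drug name placed in the score table.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 57,
                       n_variants = 74,
                       n_decoy_variants = 25,
                       hit_inflation = 0.73,
                       keep_frac = 1,
                       criterion_probs = c(missense = 7, cis_eqtl = 12,
                                           go_bp = 30, go_cc = 36,
                                           go_mf = 47, kegg = 5) / 57,
                       n_proxy_admit = 6,
                       n_proxy_reject = 6,
                       n_proxy_genes = 3,
                       n_background_genes = 1000,
                       n_kegg_decoy_sets = 8,
                       n_network_genes = 400,
                       n_planted_interactors = 50,
                       attachment_exponent = 1,
                       n_drugs = 40,
                       frac_druggable = 0.3,
                       comparator_correlation = 0.5,
                       comparator = "dasatinib") {
  stopifnot(is.numeric(seed), length(seed) == 1, abs(seed) < 2^31 - 16,
            n_genes > 0, n_variants > 0, n_decoy_variants >= 0,
            hit_inflation >= 0, keep_frac >= 0, keep_frac <= 1,
            length(criterion_probs) == 6,
            all(criterion_probs >= 0 & criterion_probs <= 1),
            n_proxy_genes <= n_proxy_admit, n_proxy_genes < n_genes,
            n_background_genes > 0, n_network_genes > 0,
            n_planted_interactors >= 0, n_drugs > 0,
            frac_druggable >= 0, frac_druggable <= 1,
            comparator_correlation >= -1, comparator_correlation <= 1)
  names(criterion_probs) <- c("missense", "cis_eqtl", "go_bp", "go_cc",
                              "go_mf", "kegg")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic association catalog and LD proxy table
#'
#' Plants `n_variants` surviving variants (p <= 1e-5, OR > 1) covering all
#' `n_genes` gene symbols except those reserved for proxy delivery, adds
#' duplicate catalog rows (hit inflation), decoy variants that must fail
#' the filter, and LD proxy rows straddling the 0.8 r-squared cut.
#'
#' @param cfg a [sim_config()].
#' @return list `associations`, `ld_proxies` (dialect data.frames) and
#'   `truth` (surviving rsIDs, post-expansion rsIDs, final gene set,
#'   catalog hit count).
#' @export
generate_catalog <- function(cfg) {
  set.seed(cfg$seed + 1L)
  pool <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  proxy_genes <- if (cfg$n_proxy_genes > 0) utils::tail(pool, cfg$n_proxy_genes)
                 else character()
  var_genes <- setdiff(pool, proxy_genes)

  kept <- stats::runif(cfg$n_variants) <= cfg$keep_frac
  rsids <- sprintf("rs%d", 1000000L + seq_len(cfg$n_variants))

  # deal the catalog genes round-robin over KEPT variants so each catalog
  # gene is mapped by at least one surviving variant (multi-gene cells
  # appear when genes outnumber variants)
  kept_idx <- which(kept)
  if (!length(kept_idx)) kept_idx <- integer()
  gene_cells <- rep("", cfg$n_variants)
  if (length(kept_idx)) {
    shuffled <- sample(var_genes)
    owner <- kept_idx[(seq_along(shuffled) - 1L) %% length(kept_idx) + 1L]
    cells <- tapply(shuffled, owner, paste, collapse = ", ")
    gene_cells[as.integer(names(cells))] <- as.character(cells)
    # kept variants left without a gene re-use a random catalog gene
    empty <- kept_idx[!nzchar(gene_cells[kept_idx])]
    if (length(empty))
      gene_cells[empty] <- sample(var_genes, length(empty), replace = TRUE)
  }

  base <- data.frame(
    rsid = rsids,
    genes = gene_cells,
    p_value = 10^(-stats::runif(cfg$n_variants, 5.05, 12)),
    odds_ratio = stats::runif(cfg$n_variants, 1.05, 3),
    source_id = sprintf("GCST%06d", 900000L + seq_len(cfg$n_variants)),
    stringsAsFactors = FALSE
  )
  # failing planted variants get a failing p or OR, consistent per variant
  fail_idx <- which(!kept)
  if (length(fail_idx)) {
    mode <- (seq_along(fail_idx) - 1L) %% 3L
    base$p_value[fail_idx[mode == 0L]] <-
      10^(-stats::runif(sum(mode == 0L), 1, 4.5))
    base$odds_ratio[fail_idx[mode == 1L]] <-
      stats::runif(sum(mode == 1L), 0.3, 0.99)
    base$odds_ratio[fail_idx[mode == 2L]] <- NA_real_
  }

  # duplicate catalog rows (extra "hits") for kept variants
  extra <- if (length(kept_idx)) stats::rpois(length(kept_idx), cfg$hit_inflation)
           else integer()
  dup_rows <- rep(kept_idx, extra)
  dups <- base[dup_rows, , drop = FALSE]
  if (nrow(dups)) {
    dups$p_value <- 10^(-stats::runif(nrow(dups), 5.05, 12))
    dups$odds_ratio <- stats::runif(nrow(dups), 1.05, 3)
    dups$source_id <- sprintf("GCST%06d", 950000L + seq_len(nrow(dups)))
  }

  # decoy variants that must be filtered out
  decoys <- if (cfg$n_decoy_variants > 0) {
    mode <- (seq_len(cfg$n_decoy_variants) - 1L) %% 3L
    d <- data.frame(
      rsid = sprintf("rs%d", 3000000L + seq_len(cfg$n_decoy_variants)),
      genes = sprintf("DECOY%02d", seq_len(cfg$n_decoy_variants)),
      p_value = 10^(-stats::runif(cfg$n_decoy_variants, 5.05, 12)),
      odds_ratio = stats::runif(cfg$n_decoy_variants, 1.05, 3),
      source_id = sprintf("GCST%06d", 990000L + seq_len(cfg$n_decoy_variants)),
      stringsAsFactors = FALSE
    )
    d$p_value[mode == 0L] <- 10^(-stats::runif(sum(mode == 0L), 1, 4.5))
    d$odds_ratio[mode == 1L] <- stats::runif(sum(mode == 1L), 0.3, 0.99)
    d$odds_ratio[mode == 2L] <- NA_real_
    d
  } else base[0, , drop = FALSE]

  assoc <- rbind(base, dups, decoys)
  assoc <- assoc[sample(nrow(assoc)), , drop = FALSE]
  rownames(assoc) <- NULL

  # LD proxies: admitted rows (r2 above the cut) indexed on kept variants,
  # the first n_proxy_genes of them each delivering one reserved gene
  kept_rs <- rsids[kept]
  prox <- NULL
  if (cfg$n_proxy_admit > 0 && length(kept_rs)) {
    adm <- data.frame(
      index_rsid = sample(kept_rs, cfg$n_proxy_admit, replace = TRUE),
      proxy_rsid = sprintf("rs%d", 2000000L + seq_len(cfg$n_proxy_admit)),
      r2 = stats::runif(cfg$n_proxy_admit, 0.82, 0.99),
      proxy_genes = c(proxy_genes,
                      rep("", cfg$n_proxy_admit - length(proxy_genes))),
      stringsAsFactors = FALSE
    )
    prox <- adm
  }
  if (cfg$n_proxy_reject > 0 && length(kept_rs)) {
    rej <- data.frame(
      index_rsid = sample(kept_rs, cfg$n_proxy_reject, replace = TRUE),
      proxy_rsid = sprintf("rs%d", 2500000L + seq_len(cfg$n_proxy_reject)),
      r2 = stats::runif(cfg$n_proxy_reject, 0.2, 0.79),
      proxy_genes = sprintf("DECOYLD%02d", seq_len(cfg$n_proxy_reject)),
      stringsAsFactors = FALSE
    )
    prox <- rbind(prox, rej)
  }
  if (is.null(prox))
    prox <- data.frame(index_rsid = character(), proxy_rsid = character(),
                       r2 = numeric(), proxy_genes = character(),
                       stringsAsFactors = FALSE)
  prox <- prox[sample(nrow(prox)), , drop = FALSE]
  rownames(prox) <- NULL

  admitted_proxy_rs <- prox$proxy_rsid[prox$r2 >= 0.8 &
                                       prox$index_rsid %in% kept_rs]
  truth_genes <- sort(unique(c(
    unlist(lapply(gene_cells[kept_idx], split_genes)),
    if (length(kept_rs)) proxy_genes else character()
  )))
  list(
    associations = assoc,
    ld_proxies = prox,
    truth = list(
      kept_rsids = sort(kept_rs),
      expanded_rsids = sort(unique(c(kept_rs, admitted_proxy_rs))),
      genes = truth_genes,
      n_hits = length(kept_idx) + sum(extra)
    )
  )
}

#' Generate synthetic functional annotations with planted evidence
#'
#' Draws the six criterion memberships per gene independently from
#' `criterion_probs`, then materializes them as missense / cis-eQTL / GO
#' tables and KEGG gene sets built so that the EASE enrichment filter at
#' the default cut recovers exactly the planted KEGG-true genes. Decoy
#' rows (off-tissue eQTLs, non-significant calls, background-only KEGG
#' sets) are planted to exercise every gate. KEGG memberships are redrawn
#' if the Bernoulli draw yields exactly one or two KEGG-true genes, since
#' an overlap that small is never significant under the EASE statistic.
#'
#' @param cfg a [sim_config()].
#' @param genes gene list to annotate (default: the planted catalog pool).
#' @return list `ann` ([annotation_table()]), `kegg_sets`, and
#'   `truth_evidence` (the planted evidence matrix, rows sorted by gene).
#' @export
generate_annotations <- function(cfg, genes = NULL) {
  set.seed(cfg$seed + 2L)
  genes <- sort(norm_symbols(genes %||% sprintf("GENE%03d", seq_len(cfg$n_genes))))
  ng <- length(genes)
  p <- cfg$criterion_probs
  draw <- function(pr) stats::runif(ng) < pr
  ev <- data.frame(gene = genes,
                   missense = draw(p["missense"]),
                   cis_eqtl = draw(p["cis_eqtl"]),
                   go_bp = draw(p["go_bp"]),
                   go_cc = draw(p["go_cc"]),
                   go_mf = draw(p["go_mf"]),
                   kegg = draw(p["kegg"]),
                   stringsAsFactors = FALSE)
  for (i in seq_len(1000)) {
    if (!(sum(ev$kegg) %in% c(1L, 2L))) break
    ev$kegg <- draw(p["kegg"])
  }
  if (sum(ev$kegg) %in% c(1L, 2L))
    stop("could not draw a recoverable KEGG membership count")

  eqtl_rows <- function(g, tissue, sig)
    data.frame(gene = g, tissue = rep(tissue, length(g)),
               significant = rep(sig, length(g)), stringsAsFactors = FALSE)
  # decoys: off-tissue significant rows and on-tissue non-significant rows
  off <- genes[stats::runif(ng) < 0.2]
  ns <- genes[stats::runif(ng) < 0.1]
  eqtl <- rbind(eqtl_rows(ev$gene[ev$cis_eqtl], "whole blood", TRUE),
                eqtl_rows(off, "liver", TRUE),
                eqtl_rows(ns, "whole blood", FALSE))

  go_rows <- function(ns_flag, ns_name, offset) {
    g <- ev$gene[ev[[ns_flag]]]
    n_terms <- sample(1:3, length(g), replace = TRUE)
    data.frame(gene = rep(g, n_terms),
               term = sprintf("GO:%07d", offset + seq_len(sum(n_terms))),
               namespace = rep(ns_name, sum(n_terms)),
               stringsAsFactors = FALSE)
  }
  go <- rbind(go_rows("go_bp", "BP", 0L),
              go_rows("go_cc", "CC", 100000L),
              go_rows("go_mf", "MF", 200000L))

  fillers <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  background <- c(genes, fillers)
  kegg_true <- ev$gene[ev$kegg]
  for (attempt in seq_len(50)) {
    sets <- list()
    if (length(kegg_true))
      sets[["path001"]] <- sort(kegg_true)
    for (j in seq_len(cfg$n_kegg_decoy_sets)) {
      members <- sample(fillers, sample(10:25, 1))
      # half the decoys graze the list with a single (KEGG-false) gene;
      # a one-gene overlap is never significant under EASE
      if (j %% 2 == 0 && length(setdiff(genes, kegg_true)))
        members <- c(members, sample(setdiff(genes, kegg_true), 1))
      sets[[sprintf("path%03d", j + 1L)]] <- sort(members)
    }
    enr <- enrich_sets(genes, sets, background)
    recovered <- intersect(genes,
                           unique(unlist(sets[enr$set_id], use.names = FALSE)))
    if (setequal(recovered, kegg_true)) break
    if (attempt == 50) stop("failed to build enrichment-recoverable KEGG sets")
  }

  list(
    ann = annotation_table(missense_genes = ev$gene[ev$missense],
                           eqtl = eqtl, go = go, kegg_sets = sets,
                           background = background),
    kegg_sets = sets,
    truth_evidence = ev
  )
}

#' Generate the synthetic network, drug-target and connectivity tables
#'
#' Builds a scale-free interaction network (preferential attachment) over
#' the risk-gene seeds, a planted interactor shell, and background nodes.
#' Edges between seeds and planted interactors carry strictly higher
#' confidences (0.85-0.99) than any other seed-adjacent edge (0.4-0.8), so
#' the planted shell is exactly the top of the interactor ranking. Drug
#' targets are assigned to a planted druggable subset of the expanded gene
#' set (plus decoy records failing each druggability gate), and
#' connectivity scores place a planted subset of candidate drugs strictly
#' above +80.
#'
#' @param cfg a [sim_config()].
#' @param risk_genes seed genes for the expansion (non-empty).
#' @return list `edges`, `drug_targets`, `connectivity` (dialect
#'   data.frames) and `truth` (planted interactors, expanded set,
#'   druggable map, strong drugs in descending-score order).
#' @export
generate_network_drugs_scores <- function(cfg, risk_genes) {
  set.seed(cfg$seed + 3L)
  seeds <- sort(norm_symbols(risk_genes))
  if (!length(seeds)) stop("risk_genes must be non-empty")
  interactors <- if (cfg$n_planted_interactors > 0)
    sprintf("INTG%03d", seq_len(cfg$n_planted_interactors)) else character()
  bg <- sprintf("NETG%04d", seq_len(cfg$n_network_genes))
  nodes <- sample(c(seeds, interactors, bg))

  g <- igraph::sample_pa(length(nodes), power = cfg$attachment_exponent,
                         m = 2, directed = FALSE)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(gene_a = nodes[as.integer(el[, 1])],
                      gene_b = nodes[as.integer(el[, 2])],
                      confidence = NA_real_, stringsAsFactors = FALSE)
  # guarantee every planted interactor touches at least one seed
  have_seed_edge <- interactors %in%
    c(edges$gene_a[edges$gene_b %in% seeds & edges$gene_a %in% interactors],
      edges$gene_b[edges$gene_a %in% seeds & edges$gene_b %in% interactors])
  need <- interactors[!have_seed_edge]
  if (length(need))
    edges <- rbind(edges, data.frame(
      gene_a = need, gene_b = sample(seeds, length(need), replace = TRUE),
      confidence = NA_real_, stringsAsFactors = FALSE))
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  planted_edge <- (edges$gene_a %in% seeds & edges$gene_b %in% interactors) |
                  (edges$gene_b %in% seeds & edges$gene_a %in% interactors)
  edges$confidence[planted_edge] <- stats::runif(sum(planted_edge), 0.85, 0.99)
  edges$confidence[!planted_edge] <- stats::runif(sum(!planted_edge), 0.4, 0.8)
  edges <- edges[sample(nrow(edges)), , drop = FALSE]
  rownames(edges) <- NULL

  expanded <- c(seeds, sort(interactors))
  n_druggable <- max(1L, round(cfg$frac_druggable * length(expanded)))
  druggable <- sort(sample(expanded, min(n_druggable, length(expanded))))
  drug_pool <- sprintf("drug_%02d", seq_len(cfg$n_drugs))
  recs <- do.call(rbind, lapply(druggable, function(gn) {
    ds <- sample(drug_pool, sample(1:3, 1))
    data.frame(drug = ds, gene = gn, action_known = TRUE,
               organism = "Humans",
               groups = sample(c("approved", "investigational",
                                 "experimental", "approved|investigational"),
                               length(ds), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  decoys <- data.frame(
    drug = sprintf("decoy_drug_%02d", 1:6),
    gene = c(sample(druggable, 3, replace = TRUE), sprintf("OFFT%02d", 1:3)),
    action_known = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    organism = c("Humans", "Escherichia coli", "Humans",
                 "Humans", "Mus musculus", "Humans"),
    groups = c("approved", "approved", "other", "approved", "approved",
               "experimental"),
    stringsAsFactors = FALSE
  )
  drug_targets <- rbind(recs, decoys)
  drug_targets <- drug_targets[sample(nrow(drug_targets)), , drop = FALSE]
  rownames(drug_targets) <- NULL

  truth_map <- lapply(split(tolower(recs$drug), recs$gene),
                      function(d) sort(unique(d)))
  cand_drugs <- sort(unique(tolower(recs$drug)))
  n_strong <- min(length(cand_drugs),
                  round(10 * max(0, cfg$comparator_correlation)))
  strong <- if (n_strong > 0) sample(cand_drugs, n_strong) else character()
  weak <- setdiff(cand_drugs, strong)
  connectivity <- rbind(
    data.frame(drug = strong,
               score = round(stats::runif(length(strong), 80.5, 99), 2),
               stringsAsFactors = FALSE),
    data.frame(drug = weak,
               score = round(stats::runif(length(weak), -90, 75), 2),
               stringsAsFactors = FALSE),
    data.frame(drug = cfg$comparator, score = 100, stringsAsFactors = FALSE)
  )
  connectivity <- connectivity[sample(nrow(connectivity)), , drop = FALSE]
  rownames(connectivity) <- NULL

  strong_tbl <- connectivity[connectivity$drug %in% strong, , drop = FALSE]
  strong_tbl <- strong_tbl[order(-strong_tbl$score, strong_tbl$drug), ,
                           drop = FALSE]
  list(
    edges = edges,
    drug_targets = drug_targets,
    connectivity = connectivity,
    truth = list(
      interactors = sort(interactors),
      expanded_genes = sort(expanded),
      druggable_genes = druggable,
      drug_map = truth_map,
      strong_drugs = strong_tbl$drug
    )
  )
}

#' Materialize a full synthetic input bundle
#'
#' Runs all three generators, writes every input table in its dialect to
#' `outdir` together with a ready-to-run pipeline config (`config.yaml`)
#' and a machine-readable planted-truth sidecar (`truth.json`, consumed
#' only by tests).
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with `config` (path), `truth`, and `paths`.
#' @export
simulate_inputs <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cat_out <- generate_catalog(cfg)
  ann_out <- generate_annotations(cfg, cat_out$truth$genes)
  planted_scores <- score_genes(ann_out$truth_evidence)
  risk <- classify_risk_genes(planted_scores)
  net_out <- generate_network_drugs_scores(cfg, risk)

  p <- function(f) file.path(outdir, f)
  paths <- list(
    associations = p("associations.tsv"), ld_proxies = p("ld_proxies.tsv"),
    missense = p("missense.tsv"), eqtl = p("eqtl.tsv"), go = p("go.tsv"),
    kegg_gmt = p("kegg.gmt"), background = p("background.tsv"),
    edges = p("edges.tsv"), drug_targets = p("drug_targets.tsv"),
    connectivity = p("connectivity.tsv")
  )
  write_table(cat_out$associations, paths$associations, "associations")
  write_table(cat_out$ld_proxies, paths$ld_proxies, "ld_proxies")
  write_table(data.frame(gene = ann_out$ann$missense_genes),
              paths$missense, "missense")
  write_table(ann_out$ann$eqtl, paths$eqtl, "eqtl")
  write_table(ann_out$ann$go, paths$go, "go")
  write_table(ann_out$kegg_sets, paths$kegg_gmt, "gmt")
  write_table(data.frame(gene = ann_out$ann$background),
              paths$background, "genes")
  write_table(net_out$edges, paths$edges, "edges")
  write_table(net_out$drug_targets, paths$drug_targets, "drug_targets")
  write_table(net_out$connectivity, paths$connectivity, "connectivity")

  truth <- c(cat_out$truth,
             list(evidence = ann_out$truth_evidence,
                  risk_genes = risk),
             net_out$truth)
  jsonlite::write_json(
    truth[setdiff(names(truth), "evidence")],
    p("truth.json"), auto_unbox = FALSE, digits = NA)
  write_table(ann_out$truth_evidence, p("truth_evidence.tsv"), "evidence")

  config <- list(
    inputs = lapply(paths, normalizePath),
    thresholds = list(p_max = 1e-5, or_min = 1, r2_min = 0.8,
                      r2_inclusive = TRUE, enrich_p = 0.05,
                      score_threshold = 2, eqtl_tissue = "whole blood",
                      max_interactors = cfg$n_planted_interactors,
                      min_confidence = 0.4,
                      comparator = cfg$comparator, score_min = 80)
  )
  yaml::write_yaml(config, p("config.yaml"))
  invisible(list(config = p("config.yaml"), truth = truth, paths = paths))
}
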