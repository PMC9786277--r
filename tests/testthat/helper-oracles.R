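# Independent brute-force oracles and random-table generators. These are
# deliberately naive (per-row loops, exhaustive enumeration) and share no
# code with the package implementation.

ease_enum <- function(k, n, K, N, ease = TRUE) {
  a <- if (ease) k - 1 else k
  if (a <= 0) return(1.0)
  xs <- a:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (!length(xs)) return(0.0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

oracle_filter_associations <- function(df, cfg) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- df$p_value[i] <= cfg$p_max &&
      !is.na(df$odds_ratio[i]) && df$odds_ratio[i] > cfg$or_min
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_expand_ld <- function(variants, proxies, cfg) {
  adm <- character()
  for (i in seq_len(nrow(proxies))) {
    ok <- if (cfg$r2_inclusive) proxies$r2[i] >= cfg$r2_min
          else proxies$r2[i] > cfg$r2_min
    if (ok && proxies$index_rsid[i] %in% variants)
      adm <- c(adm, proxies$proxy_rsid[i])
  }
  sort(unique(c(variants, adm)))
}

oracle_expand_network <- function(seeds, edges, cfg) {
  seeds <- sort(unique(toupper(seeds)))
  cand <- list()
  for (i in seq_len(nrow(edges))) {
    if (edges$confidence[i] < cfg$min_confidence) next
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    pair <- NULL
    if (a %in% seeds && !(b %in% seeds)) pair <- c(b, edges$confidence[i])
    if (b %in% seeds && !(a %in% seeds)) pair <- c(a, edges$confidence[i])
    if (is.null(pair)) next
    g <- pair[1]
    cand[[g]] <- c(cand[[g]], as.numeric(pair[2]))
  }
  if (!length(cand)) return(seeds)
  tab <- data.frame(gene = names(cand),
                    mx = vapply(cand, max, numeric(1)),
                    sm = vapply(cand, sum, numeric(1)))
  tab <- tab[order(-tab$mx, -tab$sm, tab$gene), ]
  c(seeds, head(tab$gene, cfg$max_interactors))
}

oracle_filter_drug_targets <- function(df, allowed) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    grps <- tolower(strsplit(df$groups[i], "\\|")[[1]])
    keep[i] <- isTRUE(df$action_known[i]) &&
      tolower(trimws(df$organism[i])) == "humans" &&
      length(intersect(grps, allowed)) > 0
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_rank_candidates <- function(df, cfg) {
  df <- df[tolower(trimws(df$drug)) != tolower(cfg$comparator), , drop = FALSE]
  df <- df[df$score > cfg$score_min, , drop = FALSE]
  df <- df[order(-df$score, tolower(df$drug)), , drop = FALSE]
  if (!is.null(cfg$top_k)) df <- head(df, cfg$top_k)
  rownames(df) <- NULL
  df
}

# --- random-table generators ----------------------------------------------

rand_associations <- function(n, gene_pool = LETTERS) {
  data.frame(
    rsid = sprintf("rs%d", sample(100:999, n, replace = TRUE)),
    genes = replicate(n, paste(sample(gene_pool, sample(0:3, 1)),
                               collapse = ", ")),
    p_value = 10^-runif(n, 0, 9),
    odds_ratio = ifelse(runif(n) < 0.15, NA, runif(n, 0.2, 3)),
    source_id = sprintf("GCST%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

rand_proxies <- function(n, index_pool) {
  data.frame(
    index_rsid = sample(index_pool, n, replace = TRUE),
    proxy_rsid = sprintf("rs%d", sample(5000:5999, n)),
    r2 = round(runif(n), 3),
    proxy_genes = replicate(n, paste(sample(LETTERS, sample(0:2, 1)),
                                     collapse = ", ")),
    stringsAsFactors = FALSE
  )
}

rand_edges <- function(n_nodes, n_edges) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(replicate(n_edges, sample(nodes, 2)))
  df <- data.frame(gene_a = pmin(pairs[, 1], pairs[, 2]),
                   gene_b = pmax(pairs[, 1], pairs[, 2]),
                   confidence = round(runif(n_edges), 3),
                   stringsAsFactors = FALSE)
  df[!duplicated(df[, 1:2]), , drop = FALSE]
}

rand_drug_targets <- function(n) {
  data.frame(
    drug = sprintf("drug%02d", sample(1:15, n, replace = TRUE)),
    gene = sprintf("G%02d", sample(1:20, n, replace = TRUE)),
    action_known = runif(n) < 0.7,
    organism = sample(c("Humans", "humans", "Escherichia coli", "Mus musculus"),
                      n, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
    groups = replicate(n, paste(sample(c("approved", "investigational",
                                         "experimental", "other"),
                                       sample(1:2, 1)), collapse = "|")),
    stringsAsFactors = FALSE
  )
}

rand_connectivity <- function(n) {
  data.frame(
    drug = c("dasatinib", sprintf("cmpd%02d", seq_len(n - 1))),
    score = round(runif(n, -100, 100), 2),
    stringsAsFactors = FALSE
  )
}

fixture_path <- function(f) {
  system.file("extdata", f, package = "gwas2drug", mustWork = TRUE)
}

small_sim_config <- function(seed) {
  sim_config(seed = seed, n_genes = 20, n_variants = 24,
             n_decoy_variants = 9, n_proxy_admit = 4, n_proxy_reject = 4,
             n_proxy_genes = 2, n_background_genes = 250,
             n_kegg_decoy_sets = 4, n_network_genes = 120,
             n_planted_interactors = 12, n_drugs = 15,
             frac_druggable = 0.35)
}
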