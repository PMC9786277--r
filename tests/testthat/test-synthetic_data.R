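test_that("same seed gives byte-identical simulated bundles", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  cfg <- small_sim_config(31)
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in setdiff(files, "config.yaml")) {   # config embeds absolute paths
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("catalog generator: keep-flags, duplicates and proxies behave as planted", {
  # all keep-flags true, no duplicates, no decoys, no proxies -> the variant
  # stage returns every planted variant
  cfg <- sim_config(seed = 3, n_genes = 10, n_variants = 12,
                    n_decoy_variants = 0, hit_inflation = 0,
                    n_proxy_admit = 0, n_proxy_reject = 0, n_proxy_genes = 0)
  cat0 <- generate_catalog(cfg)
  surv <- dedupe_variants(filter_associations(cat0$associations))
  expect_identical(sort(surv$rsid), cat0$truth$kept_rsids)
  expect_identical(nrow(surv), 12L)
  expect_true(all(surv$n_hits == 1L))

  # default-shaped cfg: survivors, LD expansion and gene pool equal truth
  cfg2 <- small_sim_config(17)
  cat2 <- generate_catalog(cfg2)
  vcfg <- variant_filter_config()
  surv2 <- dedupe_variants(filter_associations(cat2$associations, vcfg))
  expect_identical(sort(surv2$rsid), cat2$truth$kept_rsids)
  expect_identical(sum(surv2$n_hits), cat2$truth$n_hits)
  ex <- expand_ld(surv2$rsid, cat2$ld_proxies, vcfg)
  expect_identical(sort(ex$rsids), cat2$truth$expanded_rsids)
  genes <- collect_genes(surv2, ex$genes)
  expect_identical(as.character(genes), cat2$truth$genes)
  expect_identical(length(genes), 20L)   # every planted gene recovered
})

test_that("annotation generator plants a recoverable evidence matrix", {
  cfg <- small_sim_config(23)
  genes <- sprintf("GENE%03d", 1:20)
  ann_out <- generate_annotations(cfg, genes)
  enr <- enrich_sets(genes, ann_out$kegg_sets, ann_out$ann$background)
  ev <- assemble_evidence(genes, ann_out$ann, enr)
  expect_equal(ev, ann_out$truth_evidence)

  # degenerate probabilities: all-zero and all-one score vectors
  cfg0 <- small_sim_config(2)
  cfg0$criterion_probs[] <- 0
  out0 <- generate_annotations(cfg0, genes)
  expect_true(all(score_genes(out0$truth_evidence)$score == 0L))
  cfg1 <- small_sim_config(2)
  cfg1$criterion_probs[] <- 1
  out1 <- generate_annotations(cfg1, genes)
  expect_true(all(score_genes(out1$truth_evidence)$score == 6L))
})

test_that("criterion marginals concentrate at the configured probabilities", {
  cfg <- sim_config(seed = 99, n_genes = 10000, n_background_genes = 2000)
  out <- generate_annotations(cfg, sprintf("BIG%05d", 1:10000))
  ev <- out$truth_evidence
  p <- cfg$criterion_probs
  for (cr in names(p)) {
    se <- sqrt(p[[cr]] * (1 - p[[cr]]) / 10000)
    expect_lt(abs(mean(ev[[cr]]) - p[[cr]]), 3 * se + 1e-9, label = cr)
  }
})

test_that("network generator plants the exact top-ranked interactor shell", {
  cfg <- small_sim_config(41)
  risk <- sprintf("RISK%02d", 1:10)
  net <- generate_network_drugs_scores(cfg, risk)
  ex <- expand_network(risk, net$edges,
                       expansion_config(max_interactors = cfg$n_planted_interactors))
  expect_identical(sort(ex$gene), net$truth$expanded_genes)
  expect_identical(sort(ex$gene[ex$role == "interactor"]),
                   net$truth$interactors)
  expect_identical(nrow(ex), 10L + 12L)

  # druggability and ranking recover the planted drugs exactly
  filt <- filter_drug_targets(net$drug_targets)
  ov <- overlap_druggable(ex$gene, filt)
  expect_identical(ov$map, net$truth$drug_map)
  ranked <- suppressMessages(rank_candidates(net$connectivity))
  expect_identical(ranked$drug, net$truth$strong_drugs)
})
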