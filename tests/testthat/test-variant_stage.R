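mk_assoc <- function(p, or) {
  data.frame(rsid = sprintf("rs%d", seq_along(p)),
             genes = "A", p_value = p, odds_ratio = or,
             source_id = "s", stringsAsFactors = FALSE)
}

test_that("association filter honors inclusive p and exclusive OR bounds", {
  df <- mk_assoc(p = c(2e-6, 1e-4, 1e-5, 1e-5), or = c(1.3, 1.3, 1.0, NA))
  kept <- filter_associations(df)
  expect_identical(kept$rsid, "rs1")              # only (2e-6, 1.3) survives
  drops <- attr(kept, "dropped")
  expect_identical(unname(drops["p_value"]), 1L)
  expect_identical(unname(drops["odds_ratio_low"]), 1L)
  expect_identical(unname(drops["odds_ratio_missing"]), 1L)
  # boundary: p exactly at the ceiling is kept, OR exactly 1 is not
  expect_identical(nrow(filter_associations(mk_assoc(1e-5, 1.0001))), 1L)
})

test_that("filter matches the brute-force predicate on random tables", {
  set.seed(101)
  cfg <- variant_filter_config()
  df <- rand_associations(500)
  got <- filter_associations(df, cfg)
  attr(got, "dropped") <- NULL
  expect_equal(got, oracle_filter_associations(df, cfg))
})

test_that("duplicate collapse keeps first occurrence, unions genes, counts hits", {
  df <- data.frame(
    rsid = c("rs1", "rs2", "rs1", "rs1"),
    genes = c("A", "C", "A", "B"),
    p_value = 1e-6, odds_ratio = 1.5,
    source_id = sprintf("s%d", 1:4), stringsAsFactors = FALSE)
  dd <- dedupe_variants(df)
  expect_identical(dd$rsid, c("rs1", "rs2"))
  expect_identical(dd$genes[1], "A, B")
  expect_identical(dd$n_hits, c(3L, 1L))
  expect_identical(dd$source_id[1], "s1")

  # all-unique input is the identity apart from the added hit counter
  uniq <- mk_assoc(rep(1e-6, 4), rep(1.5, 4))
  dd2 <- dedupe_variants(uniq)
  expect_identical(dd2[names(uniq)], uniq)
  expect_true(all(dd2$n_hits == 1L))

  # random duplicated input: output rsid set == input rsid set
  set.seed(5)
  r <- rand_associations(200)
  expect_setequal(dedupe_variants(r)$rsid, unique(r$rsid))
})

test_that("LD expansion is single-hop, threshold-gated, and matches the oracle", {
  cfg <- variant_filter_config()
  empty <- data.frame(index_rsid = character(), proxy_rsid = character(),
                      r2 = numeric(), proxy_genes = character())
  expect_identical(expand_ld(c("rs1", "rs2"), empty, cfg)$rsids,
                   c("rs1", "rs2"))

  px <- data.frame(index_rsid = c("rs1", "rs9", "rs1"),
                   proxy_rsid = c("rs10", "rs11", "rs12"),
                   r2 = c(0.8, 0.95, 0.5),
                   proxy_genes = c("GX", "GY", "GZ"),
                   stringsAsFactors = FALSE)
  got <- expand_ld("rs1", px, cfg)
  expect_identical(got$rsids, c("rs1", "rs10"))   # rs11: index not in set (no chaining)
  expect_identical(got$genes, "GX")
  strict <- variant_filter_config(r2_inclusive = FALSE)
  expect_identical(expand_ld("rs1", px, strict)$rsids, "rs1")  # 0.8 excluded

  set.seed(202)
  for (i in 1:25) {
    vars <- sprintf("rs%d", sample(1:9, 4))
    tab <- rand_proxies(20, sprintf("rs%d", 1:12))
    expect_setequal(expand_ld(vars, tab, cfg)$rsids,
                    oracle_expand_ld(vars, tab, cfg))
  }
})

test_that("gene collection dedupes, sorts, and counts unknown mappings", {
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   genes = c("IKZF1", "IKZF1, ARID5B", ""),
                   p_value = 1e-6, odds_ratio = 1.5, source_id = "s",
                   stringsAsFactors = FALSE)
  g <- collect_genes(df, extra_genes = "zzz1")
  expect_identical(as.character(g), c("ARID5B", "IKZF1", "ZZZ1"))
  expect_identical(attr(g, "n_unknown"), 1L)
})

test_that("hit summary counts distinct SNPs and summed multiplicities per group", {
  one <- dedupe_variants(mk_assoc(1e-6, 1.5)[1, ])
  s <- summarize_gene_hits(one)
  expect_identical(s$rows$n_snps, 1L)
  expect_identical(s$rows$n_hits, 1L)
  expect_identical(s$total_snps, 1L)
  expect_identical(s$total_hits, 1L)
  expect_error(summarize_gene_hits(mk_assoc(1e-6, 1.5)), "dedupe")
})

test_that("the variant stage is idempotent and totals equal distinct rsids", {
  set.seed(303)
  cfg <- variant_filter_config()
  for (i in 1:10) {
    df <- rand_associations(120)
    once <- dedupe_variants(filter_associations(df, cfg))
    twice <- dedupe_variants(filter_associations(once[names(df)], cfg))
    expect_identical(twice$rsid, once$rsid)
    expect_identical(twice$genes, once$genes)
    s <- summarize_gene_hits(once)
    expect_identical(s$total_snps, length(unique(once$rsid)))
    expect_identical(s$total_hits, sum(once$n_hits))
  }
})
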