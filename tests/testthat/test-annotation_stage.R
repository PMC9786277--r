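test_that("EASE probability: degenerate overlaps return exactly 1", {
  expect_identical(ease_score(0, 10, 5, 100), 1.0)
  expect_identical(ease_score(1, 10, 5, 100), 1.0)
  expect_lt(ease_score(2, 10, 5, 100), 1.0)
  # plain Fisher keeps the k = 1 overlap informative
  expect_lt(ease_score(1, 10, 5, 100, ease = FALSE), 1.0)
  expect_error(ease_score(6, 5, 4, 20), "invalid")
  expect_error(ease_score(3, 5, 4, 4), "invalid")
})

test_that("EASE matches exhaustive enumeration on the worked example", {
  # P(X >= 2), X ~ Hypergeometric(N = 20, K = 4, n = 5), by direct summation
  expected <- (choose(4, 2) * choose(16, 3) +
               choose(4, 3) * choose(16, 2) +
               choose(4, 4) * choose(16, 1)) / choose(20, 5)
  expect_equal(expected, 3856 / 15504)
  expect_equal(ease_score(3, 5, 4, 20), expected, tolerance = 1e-14)
})

test_that("EASE is monotonically non-increasing in the overlap count", {
  for (k in 2:9)
    expect_lte(ease_score(k + 1, 10, 10, 40), ease_score(k, 10, 10, 40))
})

test_that("enrichment scan filters, sorts, and matches the enumeration oracle", {
  bg <- sprintf("B%02d", 1:20)
  lst <- bg[1:5]
  sets <- list(whole = lst, off = bg[10:14], graze = c(bg[1], bg[15:18]))
  expect_error(enrich_sets(lst, sets, character()), "empty")
  expect_error(enrich_sets(c(lst, "NOTINBG"), sets, bg), "subset")

  res <- enrich_sets(lst, sets, bg, p_cut = 0.05)
  expect_identical(res$set_id, "whole")   # k=5,K=5: strongly enriched
  expect_equal(res$ease_p, ease_enum(5, 5, 5, 20), tolerance = 1e-14)

  # p_cut = 1 returns every overlapping set, sorted by p then id
  all_res <- enrich_sets(lst, sets, bg, p_cut = 1)
  expect_setequal(all_res$set_id, c("whole", "graze"))
  expect_true(!is.unsorted(all_res$ease_p))
  # disjoint list: nothing to report
  expect_identical(nrow(enrich_sets(bg[15:17], list(s = bg[1:3]), bg)), 0L)
})

test_that("evidence assembly applies the tissue gate and table memberships", {
  ann <- annotation_table(
    missense_genes = "G1",
    eqtl = data.frame(gene = c("G2", "G3"), tissue = c("Whole Blood", "liver"),
                      significant = c(TRUE, TRUE)),
    go = data.frame(gene = c("G1", "G1", "G4"),
                    term = c("GO:1", "GO:2", "GO:3"),
                    namespace = c("BP", "MF", "CC")),
    kegg_sets = list(p1 = c("G5", "G6")),
    background = sprintf("G%d", 1:8)
  )
  enr <- data.frame(set_id = "p1", k = 2, n = 5, K = 2, N = 8, ease_p = 0.01)
  ev <- assemble_evidence(sprintf("G%d", 1:6), ann, enr)
  expect_identical(ev$gene, sprintf("G%d", 1:6))
  expect_identical(ev$missense, c(TRUE, rep(FALSE, 5)))
  expect_identical(ev$cis_eqtl, c(FALSE, TRUE, rep(FALSE, 4)))  # liver gated out
  expect_identical(ev$go_bp[1], TRUE)
  expect_identical(ev$go_mf[1], TRUE)
  expect_identical(ev$go_cc, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(ev$kegg, c(rep(FALSE, 4), TRUE, TRUE))
  # a gene absent from every table has an all-false row
  expect_identical(sum(unlist(ev[ev$gene == "G6", -1])), 1L)  # only kegg
  ev0 <- assemble_evidence("G7", ann, NULL)
  expect_false(any(unlist(ev0[, -1])))
  expect_error(annotation_table(missense_genes = "X1", background = "Y1"),
               "background")
})

test_that("scoring counts criteria, classifies at the threshold, sorts stably", {
  ev <- data.frame(gene = c("B", "A", "C"),
                   missense = c(TRUE, FALSE, TRUE),
                   cis_eqtl = c(TRUE, FALSE, TRUE),
                   go_bp = c(TRUE, FALSE, TRUE),
                   go_cc = c(TRUE, FALSE, TRUE),
                   go_mf = c(TRUE, FALSE, TRUE),
                   kegg = c(FALSE, FALSE, TRUE))
  sc <- score_genes(ev)
  expect_identical(sc$score, c(6L, 5L, 0L))
  expect_identical(sc$gene, c("C", "B", "A"))
  expect_identical(sc$is_risk_gene, c(TRUE, TRUE, FALSE))
  expect_identical(classify_risk_genes(sc), c("B", "C"))
  expect_identical(classify_risk_genes(sc[0, ]), character(0))

  set.seed(7)
  rnd <- data.frame(gene = sprintf("R%02d", 1:40),
                    missense = runif(40) < .5, cis_eqtl = runif(40) < .5,
                    go_bp = runif(40) < .5, go_cc = runif(40) < .5,
                    go_mf = runif(40) < .5, kegg = runif(40) < .5)
  sc2 <- score_genes(rnd, threshold = 3)
  brute <- sort(rnd$gene[rowSums(rnd[, -1]) >= 3])
  expect_identical(classify_risk_genes(sc2), brute)
})

test_that("coverage percentages use half-up rounding to one decimal", {
  ev <- data.frame(gene = sprintf("G%02d", 1:57),
                   missense = c(rep(TRUE, 7), rep(FALSE, 50)),
                   cis_eqtl = c(rep(TRUE, 12), rep(FALSE, 45)),
                   go_bp = FALSE, go_cc = FALSE, go_mf = FALSE,
                   kegg = c(rep(TRUE, 5), rep(FALSE, 52)))
  cov <- criterion_coverage(ev)
  expect_equal(cov$percentage[cov$criterion == "kegg"], 8.8)
  expect_equal(cov$percentage[cov$criterion == "missense"], 12.3)
  expect_equal(cov$percentage[cov$criterion == "cis_eqtl"], 21.1)
  expect_equal(cov$percentage[cov$criterion == "go_bp"], 0.0)
  expect_error(criterion_coverage(ev[0, ]), "non-empty")
  # the half-up rule itself, where banker's rounding would differ
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(0.35, 1), 0.4)
})

test_that("only one count in 0..57 rounds to each printed GO percentage", {
  pct <- round_half_up(100 * (0:57) / 57, 1)
  expect_identical(which(pct == 52.6) - 1L, 30L)
  expect_identical(which(pct == 63.2) - 1L, 36L)
  expect_identical(which(pct == 82.5) - 1L, 47L)
})
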