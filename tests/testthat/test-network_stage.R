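test_that("expansion keeps seeds, respects the budget, handles empty graphs", {
  edges <- data.frame(gene_a = c("A", "A", "B"),
                      gene_b = c("X", "Y", "X"),
                      confidence = c(0.9, 0.5, 0.7))
  out <- expand_network(c("A", "B"), edges, expansion_config(max_interactors = 1))
  expect_identical(out$gene, c("A", "B", "X"))   # X: max conf 0.9 beats Y
  expect_identical(out$role, c("seed", "seed", "interactor"))

  out0 <- expand_network(c("A", "B"), edges, expansion_config(max_interactors = 0))
  expect_identical(out0$gene, c("A", "B"))
  expect_warning(e <- expand_network("A", edges[0, ], expansion_config()),
                 "empty edge list")
  expect_identical(e$gene, "A")
  # below-threshold edges never qualify an interactor
  lo <- expand_network("B", edges, expansion_config(min_confidence = 0.75))
  expect_identical(lo$gene, "B")
})

test_that("interactor ranking matches the brute-force oracle on random graphs", {
  set.seed(404)
  for (i in 1:50) {
    edges <- rand_edges(10, sample(8:20, 1))
    seeds <- sample(sprintf("N%02d", 1:10), sample(1:3, 1))
    cfg <- expansion_config(max_interactors = sample(0:5, 1),
                            min_confidence = runif(1, 0, 0.6))
    got <- expand_network(seeds, edges, cfg)
    expect_identical(got$gene, oracle_expand_network(seeds, edges, cfg),
                     label = sprintf("trial %d", i))
    expect_true(all(sort(unique(toupper(seeds))) %in% got$gene))
    expect_lte(nrow(got), length(unique(toupper(seeds))) + cfg$max_interactors)
  }
})

test_that("expansion output is invariant under edge-list permutation", {
  set.seed(505)
  edges <- rand_edges(12, 30)
  seeds <- c("N01", "N02", "N03")
  base <- expand_network(seeds, edges, expansion_config(max_interactors = 4))
  for (i in 1:5) {
    perm <- edges[sample(nrow(edges)), , drop = FALSE]
    expect_identical(expand_network(seeds, perm,
                                    expansion_config(max_interactors = 4)),
                     base)
  }
})
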