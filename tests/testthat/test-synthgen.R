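test_that("configs validate their probability vectors and strength", {
  expect_error(synthetic_config(group_probs = c(`16E1` = 0.5, `17E2` = 0.4)),
               "summing to 1")
  expect_error(synthetic_config(association_strength = 0.5), ">= 1")
  expect_error(
    synthetic_config(enriched_injury = data.frame(group = "16E1",
                                                  category = "nope")),
    "outside the declared vocabularies")
  cfg <- synthetic_config()
  expect_equal(unname(rowSums(cfg$injury_probs_by_group)), rep(1, 6),
               tolerance = 1e-12)
  # enrichment concentrates the named cells
  expect_gt(cfg$injury_probs_by_group["16E1", "ASH"],
            cfg$injury_probs_by_group["18EM", "ASH"])
})

test_that("generation is reproducible under the config seed", {
  cfg <- synthetic_config(n_records = 100, seed = 77)
  expect_identical(generate_registry(cfg), generate_registry(cfg))
  cfg2 <- synthetic_config(n_records = 100, seed = 78)
  expect_false(identical(generate_registry(cfg), generate_registry(cfg2)))
  empty <- generate_registry(synthetic_config(n_records = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("allocation mode reproduces the requested marginals exactly", {
  # the packaged head registry's group marginals: 16/10/9/6/4/3 of 48
  cfg <- synthetic_config(n_records = 48, association_strength = 1)
  recs <- generate_registry(cfg, mode = "allocate")
  tab <- crosstab(recs, "injury", "group")
  expect_equal(unname(colSums(tab$counts)[c("16E1", "17E2", "18E3",
                                            "16EM", "17EM", "18EM")]),
               c(16L, 10L, 9L, 6L, 4L, 3L))
  expect_identical(generate_registry(cfg, mode = "allocate"), recs)
})

test_that("sampling mode matches the marginals in expectation", {
  n <- 10000
  cfg <- synthetic_config(n_records = n, association_strength = 1, seed = 5)
  recs <- generate_registry(cfg)
  tab <- crosstab(recs, "injury", "group")
  p <- cfg$group_probs
  got <- colSums(tab$counts)[names(p)]
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(got - n * p) <= 3 * se))
})

test_that("strength 1 leaves group and injury independent", {
  nonsig <- 0
  runs <- 30
  for (s in seq_len(runs)) {
    cfg <- synthetic_config(n_records = 10000, association_strength = 1,
                            seed = 1000 + s)
    recs <- generate_registry(cfg)
    tab <- crosstab(recs, "injury", "group")
    counts <- tab$counts[rowSums(tab$counts) > 0, colSums(tab$counts) > 0]
    pval <- suppressWarnings(chisq.test(counts)$p.value)
    if (pval > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, ceiling(0.9 * runs))
})

test_that("a strong association is detectable in the cross-tabulation", {
  cfg <- synthetic_config(n_records = 10000, association_strength = 5,
                          seed = 9)
  recs <- generate_registry(cfg)
  tab <- crosstab(recs, "injury", "group")
  pval <- suppressWarnings(chisq.test(tab$counts)$p.value)
  expect_lt(pval, 1e-6)
})

test_that("planted bipartite graphs have the declared edge statistics", {
  # degenerate case: equal probabilities, expected edge count n_l * n_r * p
  m <- vapply(1:40, function(s) {
    nrow(planted_partition_graph(10, 10, 2, 0.3, 0.3, seed = s)$graph$edges)
  }, numeric(1))
  expect_lt(abs(mean(m) - 100 * 0.3), 3 * sqrt(100 * 0.3 * 0.7 / 40))
  # p_between = 0 with 2 blocks splits the graph
  pg <- planted_partition_graph(8, 8, 2, 0.9, 0, seed = 1)
  expect_gte(max(graph_components(pg$graph)), 2L)
  expect_identical(planted_partition_graph(8, 8, 2, 0.9, 0.05, seed = 4),
                   planted_partition_graph(8, 8, 2, 0.9, 0.05, seed = 4))
  expect_error(planted_partition_graph(8, 8, 2, 0.1, 0.5), "p_between <= p_within")
})
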