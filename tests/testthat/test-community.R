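test_that("edge betweenness matches the analytic small cases", {
  expect_equal(edge_betweenness(path3_graph())$betweenness, c(2, 2))
  expect_equal(edge_betweenness(star4_graph())$betweenness, c(3, 3, 3))
  eb <- edge_betweenness(two_triangles_graph())
  bridge <- eb$betweenness[eb$from == "c" & eb$to == "d"]
  expect_equal(bridge, 9)
  expect_true(all(eb$betweenness[!(eb$from == "c" & eb$to == "d")] < 9))
})

test_that("edge betweenness equals exhaustive path enumeration on random graphs", {
  withr::local_seed(2024)
  checked <- 0
  while (checked < 60) {
    g <- random_ugraph(sample(3:7, 1), runif(1, 0.3, 0.9))
    if (is.null(g)) next
    checked <- checked + 1
    expect_equal(edge_betweenness(g)$betweenness,
                 brute_force_edge_betweenness(g), tolerance = 1e-12)
  }
})

test_that("weighted betweenness agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  withr::local_seed(7)
  checked <- 0
  while (checked < 20) {
    g <- random_ugraph(6, 0.6, weighted = TRUE)
    if (is.null(g)) next
    checked <- checked + 1
    ours <- edge_betweenness(g, weighted = TRUE)$betweenness
    ref <- igraph::edge_betweenness(to_igraph(g))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
  }
  bad <- two_triangles_graph()
  bad$weight[1] <- -1
  expect_error(edge_betweenness(bad, weighted = TRUE), "positive distances")
})

test_that("divisive clustering removes the bridge first and splits the triangles", {
  g <- two_triangles_graph()
  d <- girvan_newman(g)
  expect_equal(unlist(d$removals[1, c("from", "to")], use.names = FALSE),
               c("c", "d"))
  expect_equal(d$removals$betweenness[1], 9)
  two <- d$partitions[[2]]
  expect_equal(unname(two[c("a", "b", "c")]), rep(1L, 3))
  expect_equal(unname(two[c("d", "e", "f")]), rep(2L, 3))
  # community count is non-decreasing; last partition is all singletons
  ks <- vapply(d$partitions, max, integer(1))
  expect_true(all(diff(ks) > 0))
  expect_equal(ks[1], 1L)
  expect_equal(ks[length(ks)], 6L)
})

test_that("a single-edge graph yields the two expected partitions", {
  g <- graph_from_edges(data.frame(from = "a", to = "b"))
  d <- girvan_newman(g)
  expect_equal(nrow(d$removals), 1L)
  expect_equal(length(d$partitions), 2L)
  expect_equal(max(d$partitions[[1]]), 1L)
  expect_equal(max(d$partitions[[2]]), 2L)
  expect_equal(d$modularity[2], -0.5)
  expect_error(girvan_newman(crosstab(small_records()[0, ], "injury", "group") |>
                               from_crosstab() |> suppressWarnings()),
               "at least one edge")
})

test_that("identical inputs give identical dendrograms", {
  g <- two_triangles_graph()
  expect_identical(girvan_newman(g), girvan_newman(g))
  pg <- planted_partition_graph(8, 8, 2, 0.9, 0.1, seed = 3)$graph
  expect_identical(girvan_newman(pg), girvan_newman(pg))
})

test_that("the partition sequence matches a reference divisive loop", {
  skip_if_not_installed("igraph")
  # independent scorer (igraph betweenness), same removal harness and
  # tie-break: earliest canonical edge among the maxima
  reference_gn <- function(g) {
    active <- rep(TRUE, length(g$from))
    parts <- list(graph_components_active(g, active))
    while (any(active)) {
      sub <- graph_from_edges(data.frame(
        from = g$nodes[g$from[active]], to = g$nodes[g$to[active]]),
        nodes = g$nodes)
      eb <- igraph::edge_betweenness(
        igraph::graph_from_data_frame(
          data.frame(from = sub$nodes[sub$from], to = sub$nodes[sub$to]),
          directed = FALSE,
          vertices = data.frame(name = g$nodes)))
      idx_active <- which(active)
      mx <- max(eb)
      pick <- idx_active[which(eb >= mx - 1e-9 * max(1, mx))[1]]
      active[pick] <- FALSE
      memb <- graph_components_active(g, active)
      if (max(memb) > max(parts[[length(parts)]])) {
        parts[[length(parts) + 1]] <- memb
      }
    }
    parts
  }
  graph_components_active <- function(g, active) {
    keep <- data.frame(from = g$nodes[g$from[active]],
                       to = g$nodes[g$to[active]])
    graph_components(graph_from_edges(keep, nodes = g$nodes))
  }
  withr::local_seed(11)
  checked <- 0
  while (checked < 30) {
    g <- random_ugraph(8, 0.4)
    if (is.null(g)) next
    checked <- checked + 1
    ours <- girvan_newman(g)$partitions
    ref <- reference_gn(g)
    expect_equal(length(ours), length(ref))
    for (i in seq_along(ours)) expect_equal(ours[[i]], ref[[i]])
  }
})

test_that("modularity matches hand-computed closed forms and stays bounded", {
  g <- two_triangles_graph()
  all_one <- setNames(rep(1L, 6), g$nodes)
  expect_equal(modularity(g, all_one), 0)
  two <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), g$nodes)
  expect_equal(modularity(g, two), 2 * (3 / 7 - (7 / 14)^2))
  single <- graph_from_edges(data.frame(from = "a", to = "b"))
  expect_equal(modularity(single, c(a = 1, b = 2)), -0.5)
  withr::local_seed(5)
  for (rep in 1:20) {
    rg <- random_ugraph(7, 0.5)
    if (is.null(rg)) next
    memb <- setNames(sample(1:3, length(rg$nodes), TRUE), rg$nodes)
    expect_lte(modularity(rg, memb), 1)
    expect_equal(modularity(rg, setNames(rep(1, 7), rg$nodes)), 0)
  }
  expect_error(modularity(g, setNames(rep(1, 5), g$nodes[1:5])),
               "cover exactly")
})

test_that("modularity agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  withr::local_seed(13)
  checked <- 0
  while (checked < 25) {
    g <- random_ugraph(7, 0.5, weighted = TRUE)
    if (is.null(g)) next
    checked <- checked + 1
    memb <- setNames(sample(1:3, 7, TRUE), g$nodes)
    ig <- to_igraph(g)
    ref <- igraph::modularity(ig, memb[igraph::V(ig)$name],
                              weights = igraph::E(ig)$weight)
    expect_equal(modularity(g, memb), ref, tolerance = 1e-12)
  }
})

test_that("the maximum-Q cut picks the right level", {
  g <- two_triangles_graph()
  bp <- best_partition(g)
  expect_equal(bp$Q, 2 * (3 / 7 - (7 / 14)^2))
  expect_equal(bp$n_communities, 2L)
  # complete graph: no split improves on the single community
  bk <- best_partition(k4_graph())
  expect_equal(bk$Q, 0)
  expect_equal(bk$n_communities, 1L)
  # two components with no bridge: the step-0 components partition
  gg <- graph_from_edges(data.frame(from = c("a", "b", "c", "x", "y", "z"),
                                    to = c("b", "c", "a", "y", "z", "x")))
  b2 <- best_partition(gg)
  expect_equal(b2$level, 1L)
  expect_equal(b2$n_communities, 2L)
})

test_that("cohesion matches its formula, brute force, and edge cases", {
  g <- two_triangles_graph()
  expect_equal(cohesion(g, c("a", "b", "c")), 9)
  expect_equal(cohesion(g, c("d", "e", "f")), 9)
  withr::local_seed(21)
  checked <- 0
  while (checked < 30) {
    rg <- random_ugraph(7, 0.5, weighted = TRUE)
    if (is.null(rg)) next
    sub <- sample(rg$nodes, sample(2:6, 1))
    ours <- cohesion(rg, sub)
    ref <- brute_force_cohesion(rg, sub)
    if (is.nan(ref)) { expect_true(is.nan(ours) || is.infinite(ours)) }
    else expect_equal(ours, ref, tolerance = 1e-12)
    checked <- checked + 1
  }
  # no external edges -> flagged infinite
  iso <- graph_from_edges(data.frame(from = "a", to = "b"),
                          nodes = c("a", "b", "c"))
  expect_identical(cohesion(iso, c("a", "b")), Inf)
  expect_error(cohesion(g, "a"), "2 <= n_s < n")
  expect_error(cohesion(g, g$nodes), "2 <= n_s < n")
})
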