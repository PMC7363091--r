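# Shared graph fixtures and independent brute-force oracles.

two_triangles_graph <- function() {
  graph_from_edges(data.frame(
    from = c("a", "a", "b", "c", "d", "d", "e"),
    to   = c("b", "c", "c", "d", "e", "f", "f")))
}

path3_graph <- function() {
  graph_from_edges(data.frame(from = c("a", "b"), to = c("b", "c")))
}

star4_graph <- function() {
  graph_from_edges(data.frame(from = rep("c", 3), to = c("l1", "l2", "l3")))
}

k4_graph <- function() {
  pairs <- t(combn(letters[1:4], 2))
  graph_from_edges(data.frame(from = pairs[, 1], to = pairs[, 2]))
}

# Erdos-Renyi graph on n nodes; NULL when the draw has no edges.
random_ugraph <- function(n, p, weighted = FALSE) {
  pairs <- t(combn(seq_len(n), 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) return(NULL)
  nodes <- paste0("v", seq_len(n))
  edges <- data.frame(from = nodes[pairs[keep, 1]],
                      to = nodes[pairs[keep, 2]],
                      weight = if (weighted)
                        round(runif(sum(keep), 0.5, 3), 2) else 1)
  graph_from_edges(edges, nodes = nodes)
}

# Exhaustive edge betweenness: for every node pair enumerate all shortest
# paths explicitly and credit each edge 1/(number of shortest paths) per
# path it lies on. Independent of the Brandes accumulation in the package.
brute_force_edge_betweenness <- function(g) {
  n <- length(g$nodes)
  m <- length(g$from)
  adj <- vector("list", n)
  for (e in seq_len(m)) {
    adj[[g$from[e]]] <- rbind(adj[[g$from[e]]], c(g$to[e], e))
    adj[[g$to[e]]] <- rbind(adj[[g$to[e]]], c(g$from[e], e))
  }
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        w <- adj[[v]][k, 1]
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
    }
    d
  }
  eb <- numeric(m)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in seq(s + 1, n)) {
      if (is.infinite(d[t])) next
      # walk backwards from t along distance-decreasing edges
      paths <- list()
      walk <- function(v, edges_so_far) {
        if (v == s) { paths[[length(paths) + 1]] <<- edges_so_far; return() }
        for (k in seq_len(NROW(adj[[v]]))) {
          u <- adj[[v]][k, 1]; eid <- adj[[v]][k, 2]
          if (d[u] == d[v] - 1) walk(u, c(edges_so_far, eid))
        }
      }
      walk(t, integer(0))
      for (pth in paths) eb[pth] <- eb[pth] + 1 / length(paths)
    }
  }
  eb
}

# Cohesion by a literal double loop over ordered pairs of the adjacency
# matrix, independent of the package's edge-based accumulation.
brute_force_cohesion <- function(g, subgroup) {
  n <- length(g$nodes)
  a <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (e in seq_along(g$from)) {
    a[g$from[e], g$to[e]] <- g$weight[e]
    a[g$to[e], g$from[e]] <- g$weight[e]
  }
  inS <- g$nodes %in% subgroup
  internal <- 0; external <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (inS[i] && inS[j]) internal <- internal + a[i, j]
    if (inS[i] && !inS[j]) external <- external + a[i, j]
  }
  ns <- sum(inS)
  (internal / (ns * (ns - 1))) / (external / (ns * (n - ns)))
}

to_igraph <- function(g) {
  el <- cbind(g$nodes[g$from], g$nodes[g$to])
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(ig)$weight <- g$weight
  ig
}

with_seed_sample <- function(n) withr::with_seed(99, sample(n))

small_records <- function() {
  injury_records(data.frame(
    age = c(16L, 17L, 18L),
    experience_years = c(1L, 2L, 10L),
    body_system = c("head", "head", "spine"),
    injury = c("ASH", "FR", "VF"),
    cause = c("T", NA, "SC"),
    site = c("H-G", NA, NA),
    month = c(8L, NA, 2L),
    outcome = c("recovered", "unknown", NA)
  ))
}
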