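#' General undirected graph from an edge list
#'
#' Light-weight container used by the community-detection and layout
#' routines. Edges are stored once per unordered pair in canonical order
#' (by first, then second endpoint, endpoints ordered by node index),
#' which fixes the deterministic tie-break order of the divisive
#' clustering.
#'
#' @param edges Data frame (or 2/3-column matrix) with columns `from`,
#'   `to` and optionally `weight` (default 1). Self loops are not allowed.
#' @param nodes Optional character vector fixing the node order; defaults
#'   to the nodes appearing in `edges`, in order of first appearance.
#' @return An object of class `ugraph`: `nodes`, integer endpoint vectors
#'   `from`/`to` (`from < to`), `weight`.
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) == 2L) edges$weight <- rep(1, nrow(edges))
  names(edges) <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  }
  nodes <- as.character(nodes)
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  if (anyNA(fi) || anyNA(ti)) stop("edge endpoint not in `nodes`")
  if (any(fi == ti)) stop("self loops are not allowed")
  swap <- fi > ti
  tmp <- fi[swap]; fi[swap] <- ti[swap]; ti[swap] <- tmp
  o <- order(fi, ti)
  fi <- fi[o]; ti <- ti[o]; w <- as.numeric(edges$weight)[o]
  if (anyDuplicated(cbind(fi, ti))) stop("duplicate edges")
  if (any(w <= 0)) stop("edge weights must be strictly positive")
  structure(list(nodes = nodes, from = fi, to = ti, weight = w),
            class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat(sprintf("<ugraph> %d nodes, %d edges\n", length(x$nodes),
              length(x$from)))
  invisible(x)
}

#' Coerce to the internal undirected graph representation
#' @param graph A `ugraph` or [bipartite_graph()].
#' @return A `ugraph`; bipartite left nodes precede right nodes, so the
#'   canonical edge order is left-major.
#' @export
as_ugraph <- function(graph) UseMethod("as_ugraph")

#' @export
as_ugraph.ugraph <- function(graph) graph

#' @export
as_ugraph.bipartite_graph <- function(graph) {
  graph_from_edges(
    data.frame(from = graph$edges$left, to = graph$edges$right,
               weight = graph$edges$weight),
    nodes = graph_nodes(graph)
  )
}

adjacency_index <- function(g, active = NULL) {
  n <- length(g$nodes)
  if (is.null(active)) active <- rep(TRUE, length(g$from))
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- cbind(nb = integer(0), eid = integer(0))
  for (e in which(active)) {
    u <- g$from[e]; v <- g$to[e]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  # neighbor order fixed for determinism
  lapply(adj, function(a) a[order(a[, 1L]), , drop = FALSE])
}

#' Edge-betweenness centrality
#'
#' For every edge, the sum over unordered node pairs of the fraction of
#' shortest paths between the pair that traverse the edge (Brandes'
#' single-source accumulation). Edges bridging otherwise weakly connected
#' regions score highest, which is what the divisive clustering exploits.
#'
#' @param graph A `ugraph` or [bipartite_graph()].
#' @param weighted Use edge weights as distances? Default `FALSE`
#'   (hop counts).
#' @return Data frame `from`, `to`, `betweenness` in canonical edge order.
#' @export
edge_betweenness <- function(graph, weighted = FALSE) {
  g <- as_ugraph(graph)
  eb <- edge_betweenness_values(g, rep(TRUE, length(g$from)), weighted)
  data.frame(from = g$nodes[g$from], to = g$nodes[g$to], betweenness = eb,
             stringsAsFactors = FALSE)
}

edge_betweenness_values <- function(g, active, weighted) {
  if (weighted && any(g$weight[active] <= 0)) {
    stop("weighted betweenness requires strictly positive distances")
  }
  n <- length(g$nodes)
  m <- length(g$from)
  adj <- adjacency_index(g, active)
  eb <- numeric(m)
  for (s in seq_len(n)) {
    if (nrow(adj[[s]]) == 0L) next
    if (weighted) {
      sp <- sssp_dijkstra(g, adj, s)
    } else {
      sp <- sssp_bfs(adj, s, n)
    }
    # reverse-order dependency accumulation
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      pw <- sp$preds[[w]]
      if (is.null(pw)) next
      for (k in seq_len(nrow(pw))) {
        v <- pw[k, 1L]; eid <- pw[k, 2L]
        c_ <- sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
        eb[eid] <- eb[eid] + c_
        delta[v] <- delta[v] + c_
      }
    }
  }
  eb[!active] <- NA_real_
  eb[active] <- eb[active] / 2
  eb
}

sssp_bfs <- function(adj, s, n) {
  sigma <- numeric(n); sigma[s] <- 1
  dist <- rep(-1L, n); dist[s] <- 0L
  preds <- vector("list", n)
  queue <- integer(n); queue[1L] <- s; qh <- 1L; qt <- 1L
  ord <- integer(0)
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    ord <- c(ord, v)
    a <- adj[[v]]
    for (k in seq_len(nrow(a))) {
      w <- a[k, 1L]; eid <- a[k, 2L]
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        qt <- qt + 1L; queue[qt] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- rbind(preds[[w]], c(v, eid))
      }
    }
  }
  list(order = ord, sigma = sigma, preds = preds)
}

sssp_dijkstra <- function(g, adj, s) {
  n <- length(g$nodes)
  sigma <- numeric(n); sigma[s] <- 1
  dist <- rep(Inf, n); dist[s] <- 0
  done <- rep(FALSE, n)
  preds <- vector("list", n)
  ord <- integer(0)
  tol <- 1e-12
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    ord <- c(ord, v)
    a <- adj[[v]]
    for (k in seq_len(nrow(a))) {
      w <- a[k, 1L]; eid <- a[k, 2L]
      alt <- dist[v] + g$weight[eid]
      scale <- max(1, abs(alt))
      if (alt < dist[w] - tol * scale) {
        dist[w] <- alt
        sigma[w] <- sigma[v]
        preds[[w]] <- matrix(c(v, eid), 1L)
      } else if (abs(alt - dist[w]) <= tol * scale) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- rbind(preds[[w]], c(v, eid))
      }
    }
  }
  list(order = ord, sigma = sigma, preds = preds)
}

components_membership <- function(g, active) {
  n <- length(g$nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in which(active)) {
    ru <- find(g$from[e]); rv <- find(g$to[e])
    if (ru != rv) parent[max(ru, rv)] <- min(ru, rv)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Connected components
#' @param graph A `ugraph` or [bipartite_graph()].
#' @return Integer membership vector named by node (ids numbered by first
#'   occurrence in node order).
#' @export
graph_components <- function(graph) {
  g <- as_ugraph(graph)
  setNames(components_membership(g, rep(TRUE, length(g$from))), g$nodes)
}

#' Divisive edge-betweenness (Girvan-Newman) clustering
#'
#' Repeatedly recomputes edge betweenness on the residual graph and
#' removes one maximum-betweenness edge, running to edge exhaustion.
#' A new partition (the residual graph's connected components) is recorded
#' whenever the component structure changes, starting from the intact
#' graph's components and ending with all singletons. Ties on the maximum
#' betweenness are broken toward the earliest edge in canonical
#' (left-major) order, making the dendrogram deterministic.
#'
#' @param graph A `ugraph` or [bipartite_graph()] with at least one edge.
#' @param weighted Use edge weights as shortest-path distances? Default
#'   `FALSE`.
#' @return An object of class `gn_dendrogram`: `removals` (one row per
#'   removed edge with its betweenness at removal), `partitions` (list of
#'   named membership vectors), `modularity` (the modularity of each
#'   partition on the original graph) and `graph`.
#' @export
girvan_newman <- function(graph, weighted = FALSE) {
  g <- as_ugraph(graph)
  m <- length(g$from)
  if (m == 0L) stop("girvan_newman() requires a graph with at least one edge")
  active <- rep(TRUE, m)
  memb <- components_membership(g, active)
  partitions <- list(setNames(memb, g$nodes))
  qs <- modularity(g, memb)
  removals <- data.frame(step = integer(0), from = character(0),
                         to = character(0), betweenness = numeric(0),
                         stringsAsFactors = FALSE)
  n_comm <- max(memb)
  step <- 0L
  while (any(active)) {
    step <- step + 1L
    eb <- edge_betweenness_values(g, active, weighted)
    mx <- max(eb, na.rm = TRUE)
    tol <- 1e-9 * max(1, mx)
    pick <- which(active & eb >= mx - tol)[1L]
    active[pick] <- FALSE
    removals <- rbind(removals, data.frame(
      step = step, from = g$nodes[g$from[pick]], to = g$nodes[g$to[pick]],
      betweenness = eb[pick], stringsAsFactors = FALSE))
    memb <- components_membership(g, active)
    if (max(memb) > n_comm) {
      n_comm <- max(memb)
      partitions <- c(partitions, list(setNames(memb, g$nodes)))
      qs <- c(qs, modularity(g, memb))
    }
  }
  structure(list(removals = removals, partitions = partitions,
                 modularity = qs, graph = g),
            class = "gn_dendrogram")
}

#' @export
print.gn_dendrogram <- function(x, ...) {
  cat(sprintf("<gn_dendrogram> %d removals, %d partitions, max Q = %.4f\n",
              nrow(x$removals), length(x$partitions), max(x$modularity)))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities c of intra-edge fraction minus squared
#' degree fraction: `Q = sum_c [ L_c / m - (D_c / (2 m))^2 ]`, with `L_c`
#' the total weight of edges inside community c, `D_c` the community's
#' (weighted) degree sum and `m` the graph's total edge weight. Always
#' evaluated against the *original* graph, whatever residual stage
#' produced the partition. The one-community partition scores 0; Q never
#' exceeds 1.
#'
#' @param graph A `ugraph` or [bipartite_graph()] with at least one edge.
#' @param membership Integer community ids, named by node or given in node
#'   order.
#' @param use_weights Use edge weights? Default `TRUE` (for binary graphs
#'   the two are identical).
#' @return Modularity Q, a number in \[-1, 1\].
#' @export
modularity <- function(graph, membership, use_weights = TRUE) {
  g <- as_ugraph(graph)
  memb <- align_membership(g, membership)
  w <- if (use_weights) g$weight else rep(1, length(g$from))
  m <- sum(w)
  if (m <= 0) stop("undefined modularity: graph has no edges")
  deg <- numeric(length(g$nodes))
  for (e in seq_along(g$from)) {
    deg[g$from[e]] <- deg[g$from[e]] + w[e]
    deg[g$to[e]] <- deg[g$to[e]] + w[e]
  }
  q <- 0
  for (comm in unique(memb)) {
    l_c <- sum(w[memb[g$from] == comm & memb[g$to] == comm])
    d_c <- sum(deg[memb == comm])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

align_membership <- function(g, membership) {
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), g$nodes)) {
      stop("membership must cover exactly the graph's nodes")
    }
    membership <- membership[g$nodes]
  } else if (length(membership) != length(g$nodes)) {
    stop("membership must cover exactly the graph's nodes")
  }
  as.integer(membership)
}

#' Maximum-modularity cut of a divisive dendrogram
#'
#' Scans the recorded partitions and returns the one with maximal Q on the
#' original graph; ties (within 1e-12) are broken toward fewer
#' communities, then toward the earlier dendrogram level.
#'
#' @param graph The graph the dendrogram was built from.
#' @param dendrogram A [girvan_newman()] result; computed if `NULL`.
#' @param weighted Passed to [girvan_newman()] when it must be run.
#' @return List with `membership` (named), `Q`, `n_communities`, `level`.
#' @export
best_partition <- function(graph, dendrogram = NULL, weighted = FALSE) {
  if (is.null(dendrogram)) dendrogram <- girvan_newman(graph, weighted)
  qs <- dendrogram$modularity
  ks <- vapply(dendrogram$partitions, max, integer(1))
  best <- order(-qs, ks, seq_along(qs))[1L]
  # ties within numerical tolerance resolved toward fewer communities
  near <- which(qs >= qs[best] - 1e-12)
  best <- near[order(ks[near], near)][1L]
  list(membership = dendrogram$partitions[[best]], Q = qs[best],
       n_communities = ks[best], level = best)
}

#' Subgroup cohesion
#'
#' Ratio of the subgroup's internal ordered-pair connection density to its
#' external density:
#' `S = [sum_{i,j in S} a_ij / (n_s (n_s - 1))] / [sum_{i in S, j notin S} a_ij / (n_s (n - n_s))]`
#' where `a_ij` is the (weighted) adjacency matrix, `n_s` the subgroup
#' size and `n` the graph order. S > 1 means the subgroup is denser inside
#' than toward the rest of the graph.
#'
#' @param graph A `ugraph` or [bipartite_graph()].
#' @param subgroup Character vector of node names, with
#'   `2 <= length(subgroup) < n`.
#' @return S as a number; `Inf` when the subgroup has internal edges but
#'   no external ones, `NaN` when it has neither.
#' @export
cohesion <- function(graph, subgroup) {
  g <- as_ugraph(graph)
  subgroup <- unique(as.character(subgroup))
  if (!all(subgroup %in% g$nodes)) stop("subgroup contains unknown nodes")
  n <- length(g$nodes)
  ns <- length(subgroup)
  if (ns < 2L || ns >= n) {
    stop("subgroup size must satisfy 2 <= n_s < n")
  }
  inS <- g$nodes %in% subgroup
  internal <- 0; external <- 0
  for (e in seq_along(g$from)) {
    fi <- inS[g$from[e]]; ti <- inS[g$to[e]]
    if (fi && ti) {
      internal <- internal + 2 * g$weight[e]  # both ordered pairs
    } else if (fi || ti) {
      external <- external + g$weight[e]      # one ordered pair i in S
    }
  }
  internal_density <- internal / (ns * (ns - 1))
  external_density <- external / (ns * (n - ns))
  if (external_density == 0) {
    return(if (internal_density > 0) Inf else NaN)
  }
  internal_density / external_density
}
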