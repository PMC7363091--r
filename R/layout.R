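#' Fruchterman-Reingold force-directed layout
#'
#' Classic spring-embedder placement: every node pair repels with
#' `f_r(d) = k^2 / d` and every edge attracts with `f_a(d) = d^2 / k`,
#' where `k = sqrt(area / n)` is the ideal inter-node distance.
#' Displacements are capped by a temperature that cools linearly to zero,
#' and positions are clamped to the frame. Initial positions are seeded
#' uniform draws in the unit square, so identical inputs and seed give
#' bit-identical coordinates; the caller's random-number state is left
#' untouched.
#'
#' @param graph A `ugraph` or [bipartite_graph()].
#' @param iterations Number of cooling steps, >= 1. Default 200.
#' @param seed Integer seed for the initial placement. Default 1.
#' @param area Area of the square frame. Default 1 (unit square).
#' @return Data frame `node`, `x`, `y` with attributes `bbox`,
#'   `iterations`, `seed`; coordinates are finite and lie inside `bbox`.
#' @export
fruchterman_reingold <- function(graph, iterations = 200L, seed = 1L,
                                 area = 1) {
  stopifnot(iterations >= 1L, area > 0)
  g <- as_ugraph(graph)
  n <- length(g$nodes)
  side <- sqrt(area)
  out <- data.frame(node = character(0), x = numeric(0), y = numeric(0))
  if (n == 0L) {
    attr(out, "bbox") <- c(0, side)
    return(out)
  }
  pos <- with_local_seed(seed, matrix(runif(2L * n, 0, side), ncol = 2L))
  k <- sqrt(area / n)
  t0 <- side / 10
  eps <- 1e-9
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2L)
    # pairwise repulsion
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        dv <- sweep(pos[(i + 1L):n, , drop = FALSE], 2L, pos[i, ])
        d <- pmax(sqrt(rowSums(dv^2)), eps)
        f <- k^2 / d^2  # f_r(d)/d, applied to the difference vector
        push <- dv * f
        disp[i, ] <- disp[i, ] - colSums(push)
        disp[(i + 1L):n, ] <- disp[(i + 1L):n, ] + push
      }
    }
    # attraction along edges
    for (e in seq_along(g$from)) {
      u <- g$from[e]; v <- g$to[e]
      dv <- pos[v, ] - pos[u, ]
      d <- max(sqrt(sum(dv^2)), eps)
      pull <- dv * (d / k)  # f_a(d)/d
      disp[u, ] <- disp[u, ] + pull
      disp[v, ] <- disp[v, ] - pull
    }
    temp <- t0 * (1 - (it - 1L) / iterations)
    len <- pmax(sqrt(rowSums(disp^2)), eps)
    scale <- pmin(len, temp) / len
    pos <- pos + disp * scale
    pos[] <- pmin(pmax(pos, 0), side)
  }
  out <- data.frame(node = g$nodes, x = pos[, 1L], y = pos[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "bbox") <- c(0, side)
  attr(out, "iterations") <- as.integer(iterations)
  attr(out, "seed") <- as.integer(seed)
  out
}

# Run `code` under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Write layout coordinates as delimited text
#' @param layout A [fruchterman_reingold()] result.
#' @param path Output path; written as `node,x,y` with full precision.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  df <- layout
  df$x <- format(df$x, digits = 17, trim = TRUE, scientific = FALSE)
  df$y <- format(df$y, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
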