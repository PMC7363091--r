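#' Undirected weighted bipartite graph
#'
#' Nodes split into two classes (left, e.g. injury or cause categories;
#' right, e.g. player groups) and every edge joins a left node to a right
#' node. Edge weights are strictly positive. When the same label occurs on
#' both sides it is disambiguated by prefixing the side's axis name
#' (`"injury:O"` vs `"group:O"`).
#'
#' @param left,right Character vectors of node labels (disjoint after
#'   disambiguation); isolated labels are allowed.
#' @param edges Data frame with columns `left`, `right`, `weight`
#'   (node *names*, i.e. after any disambiguation).
#' @param left_axis,right_axis Axis names used for disambiguation.
#' @return An object of class `bipartite_graph` with fields `left`,
#'   `right`, `edges` (left-major canonical order) and `axes`.
#' @export
bipartite_graph <- function(left, right, edges,
                            left_axis = "left", right_axis = "right") {
  left <- as.character(left); right <- as.character(right)
  if (anyDuplicated(left) || anyDuplicated(right)) {
    stop("duplicate labels within a side")
  }
  clash <- intersect(left, right)
  if (length(clash) > 0L) {
    rename <- function(v, axis) ifelse(v %in% clash, paste0(axis, ":", v), v)
    edges$left <- rename(as.character(edges$left), left_axis)
    edges$right <- rename(as.character(edges$right), right_axis)
    left <- rename(left, left_axis)
    right <- rename(right, right_axis)
  }
  stopifnot(is.data.frame(edges),
            all(c("left", "right", "weight") %in% names(edges)))
  edges$left <- as.character(edges$left)
  edges$right <- as.character(edges$right)
  edges$weight <- as.numeric(edges$weight)
  if (any(!edges$left %in% left)) stop("edge endpoint not a left node")
  if (any(!edges$right %in% right)) stop("edge endpoint not a right node")
  if (any(edges$weight <= 0)) stop("edge weights must be strictly positive")
  if (anyDuplicated(edges[c("left", "right")])) stop("duplicate edges")
  # canonical left-major order
  edges <- edges[order(match(edges$left, left), match(edges$right, right)),
                 c("left", "right", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(left = left, right = right, edges = edges,
                 axes = c(left = left_axis, right = right_axis)),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d + %d nodes (%s x %s), %d edges\n",
              length(x$left), length(x$right),
              x$axes[["left"]], x$axes[["right"]], nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / node names of a bipartite graph
#' @param graph A [bipartite_graph()].
#' @return `graph_nodes()`: character vector (left nodes first);
#'   `graph_order()`: integer node count.
#' @export
graph_nodes <- function(graph) c(graph$left, graph$right)

#' @rdname graph_nodes
#' @export
graph_order <- function(graph) length(graph$left) + length(graph$right)

#' Build a bipartite graph from a contingency table
#'
#' Table rows become left nodes and columns right nodes; an edge joins
#' row r to column c when `counts[r, c] >= min_count`. Binary mode gives
#' every edge weight 1; count mode uses the cell count as the weight.
#' Labels whose cells all fall below `min_count` are retained as
#' degree-zero nodes unless `drop_isolated`.
#'
#' @param table A [contingency_table()].
#' @param weight_mode `"binary"` (default) or `"count"`.
#' @param min_count Minimum cell count for an edge; integer >= 1.
#' @param drop_isolated Drop degree-zero labels? Default `FALSE`.
#' @return A [bipartite_graph()].
#' @export
from_crosstab <- function(table, weight_mode = c("binary", "count"),
                          min_count = 1L, drop_isolated = FALSE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(table, "contingency_table"), min_count >= 1L)
  m <- table$counts
  m[is.na(m)] <- 0
  hit <- which(m >= min_count, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    warning("no cell reaches min_count; returning an empty graph")
    edges <- data.frame(left = character(0), right = character(0),
                        weight = numeric(0))
  } else {
    edges <- data.frame(
      left = rownames(m)[hit[, 1L]],
      right = colnames(m)[hit[, 2L]],
      weight = if (weight_mode == "binary") rep(1, nrow(hit)) else m[hit],
      stringsAsFactors = FALSE
    )
  }
  left <- rownames(m); right <- colnames(m)
  if (drop_isolated) {
    left <- intersect(left, edges$left)
    right <- intersect(right, edges$right)
  }
  bipartite_graph(left, right, edges,
                  left_axis = table$row_axis, right_axis = table$col_axis)
}

#' Check the bipartite condition by breadth-first 2-coloring
#'
#' @param graph A [bipartite_graph()].
#' @return `TRUE` when a proper 2-coloring by side exists (always the case
#'   for graphs built by the constructors; exposed for property testing).
#' @export
is_bipartite_colorable <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  if (n == 0L) return(TRUE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  li <- match(graph$edges$left, nodes)
  ri <- match(graph$edges$right, nodes)
  for (k in seq_along(li)) {
    adj[[li[k]]] <- c(adj[[li[k]]], ri[k])
    adj[[ri[k]]] <- c(adj[[ri[k]]], li[k])
  }
  color <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(color[start])) next
    color[start] <- if (nodes[start] %in% graph$left) 0L else 1L
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(color[w])) {
          color[w] <- 1L - color[v]
          queue <- c(queue, w)
        } else if (color[w] == color[v]) {
          return(FALSE)
        }
      }
    }
  }
  all(color[match(graph$left, nodes)] == 0L) &&
    all(color[match(graph$right, nodes)] == 1L)
}

#' Serialize a bipartite graph
#'
#' GraphML output carries a node attribute `side` (left/right) and an edge
#' attribute `weight`. The edge list is `left<TAB>right<TAB>weight`, one
#' edge per line in canonical (left-major) order, after a `#`-prefixed
#' header declaring the nodes so empty graphs and isolated nodes survive a
#' round trip.
#'
#' @param graph A [bipartite_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly; `read_graph()` returns a [bipartite_graph()].
#' @export
write_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    write_graphml(graph, path)
  } else {
    header <- c(paste0("# left: ", paste(graph$left, collapse = "\t")),
                paste0("# right: ", paste(graph$right, collapse = "\t")))
    lines <- sprintf("%s\t%s\t%s", graph$edges$left, graph$edges$right,
                     format(graph$edges$weight, trim = TRUE))
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") return(read_graphml(path))
  lines <- readLines(path)
  left <- strsplit(sub("^# left: ?", "", lines[1L]), "\t")[[1L]]
  right <- strsplit(sub("^# right: ?", "", lines[2L]), "\t")[[1L]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    edges <- data.frame(left = character(0), right = character(0),
                        weight = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(body, "\t"))
    edges <- data.frame(left = parts[, 1L], right = parts[, 2L],
                        weight = as.numeric(parts[, 3L]),
                        stringsAsFactors = FALSE)
  }
  bipartite_graph(left, right, edges)
}

write_graphml <- function(graph, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  key_side <- xml2::xml_add_child(doc, "key", id = "side", `for` = "node",
                                  attr.name = "side", attr.type = "string")
  key_w <- xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                               attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  add_node <- function(name, side) {
    nd <- xml2::xml_add_child(g, "node", id = name)
    d <- xml2::xml_add_child(nd, "data", key = "side")
    xml2::xml_text(d) <- side
  }
  for (nm in graph$left) add_node(nm, "left")
  for (nm in graph$right) add_node(nm, "right")
  for (i in seq_len(nrow(graph$edges))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = graph$edges$left[i],
                             target = graph$edges$right[i])
    d <- xml2::xml_add_child(e, "data", key = "weight")
    xml2::xml_text(d) <- format(graph$edges$weight[i], trim = TRUE)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//graph/node")
  ids <- xml2::xml_attr(nodes, "id")
  sides <- vapply(nodes, function(nd) {
    xml2::xml_text(xml2::xml_find_first(nd, "./data[@key='side']"))
  }, character(1))
  eds <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- data.frame(
    left = xml2::xml_attr(eds, "source"),
    right = xml2::xml_attr(eds, "target"),
    weight = vapply(eds, function(e) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(e, "./data[@key='weight']")))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  bipartite_graph(ids[sides == "left"], ids[sides == "right"], edges)
}
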