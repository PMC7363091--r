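#' Built-in analysis presets
#'
#' Five preset configurations mirroring the published bipartite-network
#' figures: head-injury categories by age/experience group, head-injury
#' causes by collision site, acute-subdural-hematoma cause plays by group,
#' spinal injuries by group, and spinal cause plays by group. Each preset
#' names its fixture table, default graph construction (binary edges,
#' disaggregated E/EM group nodes where the table has group columns) and
#' the modularity value the source reports for its figure, so a run can
#' state how close it comes under each documented construction variant.
#'
#' @return Named list of preset configurations (plain lists).
#' @export
analysis_presets <- function() {
  list(
    fig1_head_injuries = list(
      id = "fig1_head_injuries", fixture = "table2_head_injuries",
      node_set = "separate", weight_mode = "binary", min_count = 1L,
      published_q = 0.5),
    fig2_head_causes_sites = list(
      id = "fig2_head_causes_sites", fixture = "table3_sites",
      node_set = NA_character_, weight_mode = "binary", min_count = 1L,
      published_q = 0.23),
    fig3_ash_causes = list(
      id = "fig3_ash_causes", fixture = "table2_ash_causes",
      node_set = "separate", weight_mode = "binary", min_count = 1L,
      published_q = 0.37),
    fig4_spine_injuries = list(
      id = "fig4_spine_injuries", fixture = "table2_spine_injuries",
      node_set = "separate", weight_mode = "binary", min_count = 1L,
      published_q = 0.14),
    fig5_spine_causes = list(
      id = "fig5_spine_causes", fixture = "table2_spine_causes",
      node_set = "separate", weight_mode = "binary", min_count = 1L,
      published_q = 0.1)
  )
}

resolve_config_table <- function(config) {
  if (!is.null(config$fixture)) {
    tab <- fixture_table(config$fixture)
    ns <- config$node_set
    if (!is.null(ns) && !is.na(ns)) tab <- group_table_variant(tab, ns)
    return(tab)
  }
  if (!is.null(config$records)) {
    recs <- if (is.character(config$records)) {
      load_records(config$records, sep = config$sep %||% ",")
    } else {
      injury_records(config$records)
    }
    if (is.null(config$row_axis) || is.null(config$col_axis)) {
      stop("config error [input]: record input requires row_axis and col_axis")
    }
    return(crosstab(recs, config$row_axis, config$col_axis))
  }
  stop("config error [input]: config must name a `fixture` or `records` input")
}

#' Run the full registry-to-network analysis
#'
#' Orchestrates one analysis: resolve the input (a packaged fixture table,
#' a records file, or an in-memory registry cross-tabulated over the
#' configured axes), build the bipartite graph, run divisive
#' edge-betweenness clustering with the maximum-modularity cut, score the
#' central (maximum-cohesion) subgroup, and compute a seeded
#' force-directed layout. The returned report is a plain list;
#' with `out_dir` the report (JSON), partition (TSV), graph (GraphML),
#' dendrogram (JSON) and layout (CSV) are also written, deterministically,
#' so identical configurations produce byte-identical artifacts.
#'
#' @param config A preset from [analysis_presets()] or a list with the
#'   same fields (`fixture` or `records`(+`row_axis`/`col_axis`),
#'   `weight_mode`, `min_count`, optional `node_set`, `layout_seed`,
#'   `layout_iterations`).
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Log stage progress to standard error. Default `FALSE`.
#' @return The analysis report, invisibly classed `analysis_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  id <- config$id %||% "analysis"
  log_stage <- function(...) {
    if (verbose) message(sprintf("[%s] ", id), sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for config '%s': %s",
                   name, id, conditionMessage(e)), call. = FALSE)
    })
  }
  tab <- stage("input", resolve_config_table(config))
  log_stage("input: %d x %d table, n = %s", nrow(tab$counts),
            ncol(tab$counts), format(sum(tab$counts, na.rm = TRUE)))
  report <- list(
    id = id,
    config = list(
      fixture = config$fixture %||% NA_character_,
      node_set = config$node_set %||% NA_character_,
      weight_mode = config$weight_mode %||% "binary",
      min_count = config$min_count %||% 1L,
      layout_seed = config$layout_seed %||% 1L,
      layout_iterations = config$layout_iterations %||% 200L
    ),
    input = list(
      row_axis = tab$row_axis, col_axis = tab$col_axis,
      rows = rownames(tab$counts), cols = colnames(tab$counts),
      n_cases = sum(tab$counts, na.rm = TRUE)
    )
  )
  if (sum(tab$counts, na.rm = TRUE) == 0) {
    report$empty_input <- TRUE
    log_stage("empty input: no clustering performed")
    class(report) <- "analysis_report"
    if (!is.null(out_dir)) write_report_artifacts(report, NULL, NULL, NULL,
                                                  NULL, out_dir)
    return(invisible(report))
  }
  report$empty_input <- FALSE
  graph <- stage("graph", from_crosstab(
    tab, weight_mode = report$config$weight_mode,
    min_count = report$config$min_count))
  log_stage("graph: %d + %d nodes, %d edges", length(graph$left),
            length(graph$right), nrow(graph$edges))
  report$graph <- list(
    left = graph$left, right = graph$right, n_edges = nrow(graph$edges),
    total_weight = sum(graph$edges$weight)
  )
  dendro <- stage("clustering", girvan_newman(graph))
  best <- best_partition(graph, dendro)
  log_stage("clustering: best Q = %.4f with %d communities", best$Q,
            best$n_communities)
  report$clustering <- list(
    n_levels = length(dendro$partitions),
    modularity_by_level = dendro$modularity,
    best_level = best$level,
    Q = best$Q,
    n_communities = best$n_communities,
    membership = as.list(best$membership)
  )
  sub <- stage("subgroup", central_subgroup(graph, best))
  report$subgroup <- sub
  if (identical(report$config$fixture %||% NA_character_, NA_character_) ||
      grepl("^table2", report$config$fixture %||% "")) {
    report$descriptives <- fixture_descriptives(config$fixture, tab)
  }
  layout <- stage("layout", fruchterman_reingold(
    graph, iterations = report$config$layout_iterations,
    seed = report$config$layout_seed))
  report$layout <- list(node = layout$node, x = layout$x, y = layout$y)
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    write_report_artifacts(report, graph, dendro, best, layout, out_dir)
  }
  invisible(report)
}

fixture_descriptives <- function(fixture, tab) {
  e_cols <- c("16E1", "17E2", "18E3")
  if (is.null(fixture) || !all(e_cols %in% colnames(tab$counts))) return(NULL)
  full <- fixture_table(fixture)  # printed margins live on the full table
  ps <- proportion_summary(full, cols = e_cols, margins = "printed")
  list(inexperienced_count = ps$count, total = ps$total,
       inexperienced_fraction = ps$fraction,
       inexperienced_percent = ps$percent)
}

#' Central subgroup of a partition
#'
#' Among the communities of a partition, returns the one with maximal
#' cohesion S — the subgroup sitting in the densest part of the network
#' relative to its surroundings. Ties go to the larger community, then to
#' node order. Degenerate partitions are flagged: with a single community
#' the subgroup has no external edges (infinite S); with all singletons
#' there is no subgroup.
#'
#' @param graph The graph the partition was computed on.
#' @param partition A [best_partition()] result (or a list with
#'   `membership` and `Q`).
#' @return List: `nodes`, `n_s`, `S` (may be `Inf`), `Q`, and flags
#'   `infinite_s`, `no_subgroup`.
#' @export
central_subgroup <- function(graph, partition) {
  memb <- partition$membership
  g <- as_ugraph(graph)
  comms <- split(names(memb), memb)
  sizes <- lengths(comms)
  n <- length(memb)
  if (length(comms) == 1L) {
    return(list(nodes = names(memb), n_s = n, S = Inf, Q = partition$Q,
                infinite_s = TRUE, no_subgroup = FALSE))
  }
  if (all(sizes < 2L)) {
    return(list(nodes = character(0), n_s = 0L, S = NA_real_,
                Q = partition$Q, infinite_s = FALSE, no_subgroup = TRUE))
  }
  cand <- unname(which(sizes >= 2L))
  s_vals <- vapply(cand, function(i) cohesion(g, comms[[i]]), numeric(1))
  s_rank <- ifelse(is.nan(s_vals), -Inf, s_vals)
  best <- cand[order(-s_rank, -sizes[cand], cand)][1L]
  s_best <- s_vals[match(best, cand)]
  list(nodes = comms[[best]], n_s = unname(sizes[best]), S = s_best,
       Q = partition$Q, infinite_s = is.infinite(s_best),
       no_subgroup = FALSE)
}

#' Modularity under the documented construction variants
#'
#' The source figures do not state exactly how their bipartite graphs
#' were built from the printed tables (whether counts weighted the edges,
#' and which group columns became nodes). This scan runs the divisive
#' clustering with maximum-modularity cut under every documented variant
#' — node set `separate` (E/EM), `printed` (aggregate and E columns) or
#' `inexperienced`, crossed with binary/count weights — and compares each
#' Q with the figure's published value at the printed precision
#' (two decimals). When no variant matches, the nearest is reported and
#' flagged, which is itself a finding about the construction ambiguity.
#'
#' @param preset A preset from [analysis_presets()] (or its name).
#' @return List of class `published_q_match`: `scan` (data frame of
#'   variant, Q, graph size), `published_q`, `matched`, `variant` (the
#'   matching, else nearest, row) and `Q`.
#' @export
published_q_scan <- function(preset) {
  if (is.character(preset)) preset <- analysis_presets()[[preset]]
  stopifnot(!is.null(preset$fixture))
  tab0 <- fixture_table(preset$fixture)
  has_groups <- all(c("16all", "16E1") %in% colnames(tab0$counts))
  node_sets <- if (has_groups) c("separate", "printed", "inexperienced")
               else NA_character_
  grid <- expand.grid(node_set = node_sets,
                      weight_mode = c("binary", "count"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$node_set, node_sets)), ]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- if (is.na(grid$node_set[i])) tab0 else
      group_table_variant(tab0, grid$node_set[i])
    graph <- from_crosstab(tab, weight_mode = grid$weight_mode[i])
    best <- best_partition(graph)
    data.frame(node_set = grid$node_set[i],
               weight_mode = grid$weight_mode[i],
               n_nodes = graph_order(graph), n_edges = nrow(graph$edges),
               Q = best$Q, n_communities = best$n_communities)
  })
  scan <- do.call(rbind, res)
  published <- preset$published_q
  delta <- abs(scan$Q - published)
  matched <- delta < 0.005  # agreement at the printed two decimals
  pick <- if (any(matched)) which(matched)[1L] else which.min(delta)
  structure(list(
    preset = preset$id, scan = scan, published_q = published,
    matched = any(matched), variant = scan[pick, , drop = FALSE],
    Q = scan$Q[pick], discrepancy = scan$Q[pick] - published
  ), class = "published_q_match")
}

#' @export
print.published_q_match <- function(x, ...) {
  cat(sprintf("<published_q_match> %s: published Q = %.2f, %s (Q = %.4f, %s/%s)\n",
              x$preset, x$published_q,
              if (x$matched) "matched" else "no variant matches; nearest",
              x$Q, x$variant$node_set, x$variant$weight_mode))
  invisible(x)
}

report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 12,
                   pretty = TRUE, na = "null")
}

write_report_artifacts <- function(report, graph, dendro, best, layout,
                                   out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, report$id)
  writeLines(report_json(report), paste0(pre, "_report.json"))
  if (is.null(graph)) return(invisible(out_dir))
  write_graph(graph, paste0(pre, "_graph.graphml"), "graphml")
  part <- data.frame(node = names(best$membership),
                     community_id = as.integer(best$membership))
  write.table(part, paste0(pre, "_partition.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  dj <- list(removals = dendro$removals,
             modularity_by_level = dendro$modularity)
  writeLines(jsonlite::toJSON(dj, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, dataframe = "rows"),
             paste0(pre, "_dendrogram.json"))
  write_layout(layout, paste0(pre, "_layout.csv"))
  invisible(out_dir)
}
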