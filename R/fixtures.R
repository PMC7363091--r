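#' Packaged registry tables
#'
#' The package ships, as plain-text fixtures, the four printed summary
#' tables of a 14-year Japanese youth-rugby serious-injury registry:
#' rugby population and injuries by age grade and month (`table1`),
#' high-school head and spinal-cord injuries and their cause plays by
#' age/experience group (`table2`), causes of injury by collision site and
#' load (`table3`), and junior (elementary / junior-high) injuries
#' (`table4`). Cells and the printed `Total` rows/columns are mirrored
#' verbatim; the printed totals are stored as *printed margins* on the
#' returned [contingency_table()] objects. Two margins of the source
#' tables are internally inconsistent (the spinal 16E1 column total and
#' the body-area "O" row total); see [table_consistency()].
#'
#' @param name Fixture id: file and block, e.g. `"table2_head_injuries"`,
#'   `"table2_ash_causes"`, `"table3_sites"`; see [list_fixtures()] for all.
#' @return A [contingency_table()] with printed margins where the source
#'   prints them.
#' @examples
#' tab <- fixture_table("table2_head_injuries")
#' proportion_summary(tab, cols = c("16E1", "17E2", "18E3"))
#' @export
fixture_table <- function(name) {
  if (!name %in% injurynet_fixture_names) {
    stop("unknown fixture '", name, "'; see list_fixtures()")
  }
  parts <- strsplit(name, "_")[[1L]]
  file <- parts[1L]
  block <- paste(parts[-1L], collapse = "_")
  path <- fixture_path(paste0(file, ".csv"))
  if (file == "table2") {
    load_table2_block(path, block)
  } else {
    load_long_block(path, file, block)
  }
}

injurynet_fixture_names <- c(
  "table1_population", "table1_serious_injuries", "table1_months",
  "table2_head_injuries", "table2_ash_causes",
  "table2_spine_injuries", "table2_spine_causes",
  "table3_sites", "table3_load",
  "table4_by_year", "table4_by_age", "table4_causes", "table4_sequelae"
)

#' @rdname fixture_table
#' @export
list_fixtures <- function() injurynet_fixture_names

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "injurynet")
  if (path == "") stop("packaged fixture not found: ", file)
  path
}

load_table2_block <- function(path, block) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  raw <- raw[raw$block == block, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no such block in table2: ", block)
  cols <- c("16all", "16E1", "17all", "17E2", "18all", "18E3")
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", 0, v)))
  body <- raw[raw$row != "Total", , drop = FALSE]
  totals <- raw[raw$row == "Total", , drop = FALSE]
  m <- as.matrix(vapply(cols, function(cl) num(body[[cl]]), numeric(nrow(body))))
  storage.mode(m) <- "integer"
  rownames(m) <- body$row
  row_axis <- if (grepl("injuries", block)) "injury" else "cause_site"
  contingency_table(
    m, row_axis = row_axis, col_axis = "group",
    row_totals = setNames(as.integer(num(body$Total)), body$row),
    col_totals = setNames(as.integer(num(unlist(totals[1L, cols]))), cols),
    grand_total = as.integer(num(totals$Total[1L])),
    total_cols = c("16all", "17all", "18all")
  )
}

load_long_block <- function(path, file, block) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  raw <- raw[raw$block == block, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no such block in ", file, ": ", block)
  rows <- unique(raw$row)
  cols <- unique(raw$col)
  drop_cols <- c("Total", "-18_percent")
  body_cols <- setdiff(cols, drop_cols)
  m <- matrix(NA_real_, length(rows), length(body_cols),
              dimnames = list(rows, body_cols))
  for (i in seq_len(nrow(raw))) {
    if (raw$col[i] %in% body_cols) {
      m[raw$row[i], raw$col[i]] <- as.numeric(raw$value[i])
    }
  }
  row_totals <- NULL
  if ("Total" %in% cols) {
    tot <- raw[raw$col == "Total", , drop = FALSE]
    row_totals <- setNames(rep(NA_real_, length(rows)), rows)
    row_totals[tot$row] <- as.numeric(tot$value)
  }
  grand <- if (!is.null(row_totals) && !anyNA(row_totals)) sum(row_totals)
  axes <- list(
    population = c("measure", "age_grade"),
    serious_injuries = c("body_region", "age_grade"),
    months = c("series", "month"),
    by_year = c("body_region", "year"),
    by_age = c("body_region", "age"),
    causes = c("body_region", "cause"),
    sequelae = c("injury", "disposition")
  )[[block]] %||% c("row", "col")
  contingency_table(m, row_axis = axes[1L], col_axis = axes[2L],
                    row_totals = row_totals, grand_total = grand)
}

#' Record-level head-injury fixture
#'
#' The 48 high-school head-injury cases expanded to one row per case from
#' the packaged `table2` counts: group code (age and experience), injury
#' category, and for the acute-subdural-hematoma cases the cause play and
#' collision site (the combined printed tokens OTHG/THG/THB are stored as
#' cause + site pairs) and the outcome (reported only in aggregate:
#' 13 recovered, 6 sequelae, 2 deaths, 7 unknown, assigned in record
#' order). Months are unknown at record level.
#'
#' @return An [injury_records()] data frame with 48 rows.
#' @export
head_injury_records <- function() {
  load_records(fixture_path("head_records.csv"))
}

#' Group-column variants of a published group table
#'
#' The published tables print per-age aggregate columns (`16all`, `17all`,
#' `18all`) alongside the inexperienced columns (`16E1`, `17E2`, `18E3`).
#' For network construction three documented node sets are supported:
#' `"separate"` disaggregates each age into inexperienced and many-years
#' columns (`16EM = 16all - 16E1`, ...), `"printed"` keeps the columns as
#' printed, and `"inexperienced"` keeps only the `E` columns.
#'
#' @param table A [contingency_table()] with the printed group columns.
#' @param node_set `"separate"`, `"printed"` or `"inexperienced"`.
#' @return A [contingency_table()] with the requested group columns
#'   (printed margins are dropped for derived column sets).
#' @export
group_table_variant <- function(table,
                                node_set = c("separate", "printed",
                                             "inexperienced")) {
  node_set <- match.arg(node_set)
  m <- table$counts
  need <- c("16all", "16E1", "17all", "17E2", "18all", "18E3")
  if (!all(need %in% colnames(m))) {
    stop("table does not have the printed group columns")
  }
  if (node_set == "printed") return(table)
  e <- m[, c("16E1", "17E2", "18E3"), drop = FALSE]
  if (node_set == "inexperienced") {
    return(contingency_table(e, table$row_axis, table$col_axis))
  }
  em <- m[, c("16all", "17all", "18all"), drop = FALSE] - e
  if (any(em < 0)) stop("aggregate columns smaller than inexperienced columns")
  colnames(em) <- c("16EM", "17EM", "18EM")
  contingency_table(cbind(e, em), table$row_axis, table$col_axis)
}

#' Descriptive proportions of the packaged registry
#'
#' Recomputes the registry's headline descriptive figures from the
#' packaged fixtures: the inexperienced-player shares of head, spinal and
#' acute-subdural-hematoma cases, the tackle share of head-injury causes,
#' the high-school share of all head injuries, and the share of
#' high-school players who started rugby in high school (high-school
#' population minus the next age grade, over the high-school population).
#' All use the tables' printed margins, i.e. the published denominators.
#'
#' @return A data frame with one row per quantity: `count`, `total`,
#'   `fraction`, `percent`.
#' @export
published_descriptives <- function() {
  e_cols <- c("16E1", "17E2", "18E3")
  head_tab <- fixture_table("table2_head_injuries")
  spine_tab <- fixture_table("table2_spine_injuries")
  ash_tab <- fixture_table("table2_ash_causes")
  sites <- fixture_table("table3_sites")
  hs <- fixture_table("table1_serious_injuries")
  pop <- fixture_table("table1_population")

  rows <- list(
    inexperienced_head = proportion_summary(head_tab, cols = e_cols,
                                            margins = "printed"),
    inexperienced_spine = proportion_summary(spine_tab, cols = e_cols,
                                             margins = "printed"),
    inexperienced_ash = proportion_summary(ash_tab, cols = e_cols,
                                           margins = "printed"),
    tackle_share_head_causes = proportion_summary(sites, rows = c("T", "OT"),
                                                  margins = "printed"),
    high_school_head_share = proportion_summary(hs, rows = "Head",
                                                cols = "-18",
                                                denom_rows = "Head",
                                                margins = "printed")
  )
  hs_pop <- proportion_summary(pop, rows = "count", cols = "-18")$count
  univ_pop <- proportion_summary(pop, rows = "count", cols = "-22")$count
  started <- hs_pop - univ_pop
  rows$high_school_start_share <- list(count = started, total = hs_pop,
                                       fraction = started / hs_pop,
                                       percent = percent_half_up(started / hs_pop))
  data.frame(
    quantity = names(rows),
    count = vapply(rows, `[[`, numeric(1), "count"),
    total = vapply(rows, `[[`, numeric(1), "total"),
    fraction = vapply(rows, `[[`, numeric(1), "fraction"),
    percent = vapply(rows, `[[`, integer(1), "percent"),
    row.names = NULL
  )
}
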