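#' @importFrom stats runif setNames
#' @importFrom utils read.csv write.csv head
NULL

record_columns <- c("age", "experience_years", "body_system", "injury",
                    "cause", "site", "month", "outcome")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and class a data frame of injury records
#'
#' A record is one reported serious-injury case: player age and years of
#' experience (from which the group code is derived), body system and
#' injury category, and optional cause-of-play, collision site, month and
#' outcome. All categorical fields are validated against the closed
#' vocabularies; unknown tokens are an error.
#'
#' @param df Data frame with columns
#'   `age, experience_years, body_system, injury, cause, site, month, outcome`.
#' @return The validated data frame, classed `injury_records`.
#' @seealso [load_records()], [crosstab()]
#' @export
injury_records <- function(df) {
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[record_columns]
  df$age <- as.integer(df$age)
  df$experience_years <- as.integer(df$experience_years)
  for (col in c("body_system", "injury", "cause", "site", "outcome")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  df$month <- suppressWarnings(as.integer(df$month))

  check_tokens <- function(col, valid, allow_na) {
    v <- df[[col]]
    bad <- if (allow_na) !is.na(v) & !v %in% valid else is.na(v) | !v %in% valid
    if (any(bad)) {
      stop(sprintf("parse error: row %d, column '%s': invalid token '%s'",
                   which(bad)[1L], col, as.character(df[[col]][which(bad)[1L]])))
    }
  }
  check_tokens("body_system", c("head", "spine"), allow_na = FALSE)
  inj_ok <- rep(FALSE, nrow(df))
  for (bs in unique(df$body_system)) {
    sel <- df$body_system == bs
    inj_ok[sel] <- !is.na(df$injury[sel]) &
      df$injury[sel] %in% injury_codes(bs)$category
  }
  if (!all(inj_ok)) {
    i <- which(!inj_ok)[1L]
    stop(sprintf(
      "parse error: row %d, column 'injury': invalid token '%s' for body system '%s'",
      i, as.character(df$injury[i]), df$body_system[i]))
  }
  check_tokens("cause", cause_codes()$token, allow_na = TRUE)
  check_tokens("site", site_codes()$token, allow_na = TRUE)
  check_tokens("outcome", outcome_levels(), allow_na = TRUE)
  if (any(!is.na(df$month) & (df$month < 1L | df$month > 12L))) {
    stop("parse error: column 'month': months must lie in 1..12 when known")
  }
  # derives the group and errors on out-of-scope age/experience
  invisible(assign_group_code(df$age, df$experience_years))
  class(df) <- c("injury_records", "data.frame")
  df
}

#' Read and write registry records as delimited text
#'
#' UTF-8 delimited text with a header row naming the schema columns
#' `age,experience_years,body_system,injury,cause,site,month,outcome`;
#' comma-separated by default, tab accepted. Empty cells are unknowns.
#' Row order is preserved and `write_records()` followed by
#' `load_records()` round-trips the data.
#'
#' @param path Path to the file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `load_records()`: an [injury_records()] data frame.
#' @export
load_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, na.strings = character())
  injury_records(df)
}

#' @rdname load_records
#' @param records An `injury_records` data frame.
#' @export
write_records <- function(records, path, sep = ",") {
  records <- injury_records(as.data.frame(records))
  out <- records
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
record_axis <- function(records, axis) {
  switch(axis,
    group = assign_group_code(records$age, records$experience_years),
    cause_site = cause_site_code(records$cause, records$site),
    age = ,
    experience_years = ,
    body_system = ,
    injury = ,
    cause = ,
    site = ,
    month = ,
    outcome = as.character(records[[axis]]),
    stop("unknown record axis: ", axis)
  )
}

# Combined cause-and-collision token as printed in registry tables:
# own/oppose tackles with a known head collision site collapse to
# THG / THB / OTHG; saving prints as "S"; all other causes print
# as their display token.
cause_site_code <- function(cause, site) {
  disp <- setNames(cause_codes()$display, cause_codes()$token)
  out <- unname(disp[cause])
  out[cause %in% "T" & site %in% "H-G"] <- "THG"
  out[cause %in% "T" & site %in% "H-B"] <- "THB"
  out[cause %in% "OT" & site %in% "H-G"] <- "OTHG"
  out
}

axis_levels <- function(records, axis, values) {
  switch(axis,
    group = c("16E1", "17E2", "18E3", "16EM", "17EM", "18EM"),
    injury = {
      systems <- unique(records$body_system)
      unique(unlist(lapply(systems, function(s) injury_codes(s)$category)))
    },
    cause = cause_codes()$token,
    site = site_codes()$token,
    month = as.character(1:12),
    outcome = outcome_levels(),
    sort(unique(values[!is.na(values)]))
  )
}

#' Labelled cross-tabulation of two categorical axes
#'
#' `contingency_table()` wraps a non-negative integer count matrix with
#' axis names and, optionally, *printed margins*: marginal totals carried
#' along as data (as when a table is transcribed from a publication)
#' rather than recomputed from the cells. Printed margins may legitimately
#' disagree with the cell sums when the source table itself is
#' inconsistent; [table_consistency()] reports any such cells.
#'
#' @param counts Non-negative integer matrix with row and column dimnames.
#' @param row_axis,col_axis Axis names (e.g. `"injury"`, `"group"`).
#' @param row_totals,col_totals,grand_total Optional printed marginal
#'   totals (named vectors / scalar).
#' @param total_cols Columns that partition the cases for row/grand
#'   totals. Published tables may print aggregate columns alongside their
#'   components (an age column next to its inexperienced sub-column), so a
#'   row's total is the sum over the aggregate columns only; `NULL`
#'   (default) means all columns partition the cases.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_axis = "row", col_axis = "col",
                              row_totals = NULL, col_totals = NULL,
                              grand_total = NULL, total_cols = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("`counts` must have row and column names")
  }
  if (any(!is.na(counts) & counts < 0)) stop("counts must be non-negative")
  if (!is.null(row_totals) && !setequal(names(row_totals), rownames(counts))) {
    stop("`row_totals` names must match the row labels")
  }
  if (!is.null(col_totals) && !setequal(names(col_totals), colnames(counts))) {
    stop("`col_totals` names must match the column labels")
  }
  if (!is.null(total_cols) && !all(total_cols %in% colnames(counts))) {
    stop("`total_cols` must name columns of the table")
  }
  structure(
    list(counts = counts, row_axis = row_axis, col_axis = col_axis,
         row_totals = row_totals[rownames(counts)],
         col_totals = col_totals[colnames(counts)],
         grand_total = grand_total, total_cols = total_cols),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s (%d x %d), n = %s\n",
              x$row_axis, x$col_axis, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts, na.rm = TRUE))))
  print(x$counts)
  invisible(x)
}

#' Cross-tabulate injury records over two categorical axes
#'
#' Cell (r, c) counts the records with row value r and column value c.
#' Records missing either axis value are dropped from that tabulation
#' only (they remain available for tabulations over other axes). The
#' derived axes `group` (age-by-experience code) and `cause_site`
#' (combined cause and collision token) are supported alongside the
#' stored columns.
#'
#' @param records An [injury_records()] data frame.
#' @param row_axis,col_axis Axis names: one of `group`, `injury`, `cause`,
#'   `site`, `cause_site`, `month`, `outcome`, `body_system`, `age`,
#'   `experience_years`.
#' @return A [contingency_table()].
#' @export
crosstab <- function(records, row_axis, col_axis) {
  if (nrow(records) == 0L) {
    m <- matrix(integer(0), 0L, 0L, dimnames = list(character(0), character(0)))
    return(contingency_table(m, row_axis, col_axis))
  }
  rv <- record_axis(records, row_axis)
  cv <- record_axis(records, col_axis)
  keep <- !is.na(rv) & !is.na(cv)
  rl <- axis_levels(records, row_axis, rv)
  cl <- axis_levels(records, col_axis, cv)
  tab <- table(factor(rv[keep], levels = rl), factor(cv[keep], levels = cl))
  m <- matrix(as.integer(tab), nrow = length(rl),
              dimnames = list(rl, cl))
  contingency_table(m, row_axis, col_axis)
}

block_sum <- function(tbl, rows, cols, margins) {
  cn <- colnames(tbl$counts); rn <- rownames(tbl$counts)
  if (!is.null(rows) && length(bad <- setdiff(rows, rn)))
    stop("unknown row label(s): ", paste(bad, collapse = ", "))
  if (!is.null(cols) && length(bad <- setdiff(cols, cn)))
    stop("unknown column label(s): ", paste(bad, collapse = ", "))
  if (margins == "printed") {
    if (is.null(rows) && is.null(cols)) {
      return(tbl$grand_total %||% sum(tbl$counts, na.rm = TRUE))
    }
    if (is.null(rows) && !is.null(tbl$col_totals)) {
      return(sum(tbl$col_totals[cols]))
    }
    if (is.null(cols) && !is.null(tbl$row_totals)) {
      return(sum(tbl$row_totals[rows]))
    }
  }
  sum(tbl$counts[rows %||% rn, cols %||% cn, drop = FALSE], na.rm = TRUE)
}

#' Count and proportion of a block of a contingency table
#'
#' Sums the selected block and reports it as a fraction of a denominator
#' block (the whole table by default). With `margins = "printed"`, whole
#' selected rows or columns are summed from the table's stored printed
#' marginal totals instead of its cells, reproducing a published table's
#' own arithmetic even where the printed cells and totals disagree.
#'
#' @param table A [contingency_table()].
#' @param rows,cols Labels of the selected block; `NULL` selects all.
#' @param denom_rows,denom_cols Labels of the denominator block; `NULL`
#'   (default) selects all, i.e. the grand total.
#' @param margins `"cells"` (sum the cells, default) or `"printed"` (use
#'   stored marginal totals for full-row/column selections).
#' @return A list with `count`, `total`, `fraction` (unrounded) and
#'   `percent` (half-up integer rounding, the convention of the source
#'   tables).
#' @export
proportion_summary <- function(table, rows = NULL, cols = NULL,
                               denom_rows = NULL, denom_cols = NULL,
                               margins = c("cells", "printed")) {
  margins <- match.arg(margins)
  stopifnot(inherits(table, "contingency_table"))
  count <- block_sum(table, rows, cols, margins)
  total <- block_sum(table, denom_rows, denom_cols, margins)
  if (is.na(total) || total == 0) {
    stop("undefined fraction: denominator block totals zero")
  }
  list(count = count, total = total, fraction = count / total,
       percent = percent_half_up(count / total))
}

percent_half_up <- function(fraction) as.integer(floor(fraction * 100 + 0.5))

#' Compare a table's printed margins with its cell sums
#'
#' @param table A [contingency_table()] with printed margins.
#' @return Data frame of mismatching margins (empty when consistent):
#'   one row per marginal label whose printed total differs from the sum
#'   of its cells.
#' @export
table_consistency <- function(table) {
  out <- data.frame(margin = character(0), label = character(0),
                    printed = numeric(0), cell_sum = numeric(0))
  total_cols <- table$total_cols %||% colnames(table$counts)
  if (!is.null(table$row_totals)) {
    cs <- rowSums(table$counts[, total_cols, drop = FALSE], na.rm = TRUE)
    bad <- which(!is.na(table$row_totals) & table$row_totals != cs)
    if (length(bad)) {
      out <- rbind(out, data.frame(margin = "row", label = names(cs)[bad],
                                   printed = unname(table$row_totals[bad]),
                                   cell_sum = unname(cs[bad])))
    }
  }
  if (!is.null(table$col_totals)) {
    cs <- colSums(table$counts, na.rm = TRUE)
    bad <- which(!is.na(table$col_totals) & table$col_totals != cs)
    if (length(bad)) {
      out <- rbind(out, data.frame(margin = "col", label = names(cs)[bad],
                                   printed = unname(table$col_totals[bad]),
                                   cell_sum = unname(cs[bad])))
    }
  }
  if (!is.null(table$grand_total)) {
    cs <- sum(table$counts[, total_cols, drop = FALSE], na.rm = TRUE)
    if (table$grand_total != cs) {
      out <- rbind(out, data.frame(margin = "grand", label = "Total",
                                   printed = table$grand_total,
                                   cell_sum = cs))
    }
  }
  rownames(out) <- NULL
  out
}
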