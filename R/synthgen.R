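#' Configuration for the synthetic registry generator
#'
#' Describes a synthetic serious-injury registry: how many records, the
#' marginal distribution over player groups, baseline category
#' distributions for injury, cause and month, and planted group-level
#' associations. An association multiplies the probability of the named
#' (group, category) cells by `association_strength` before renormalising
#' the group's row, concentrating specific injuries or causes in specific
#' groups the way the real registry concentrates, e.g., acute subdural
#' hematomas in first-year players. Strength 1 leaves the axes
#' independent.
#'
#' Defaults emulate the packaged head-injury registry: 48 records, group
#' marginals and injury/cause/month baselines taken from the packaged
#' tables, and the registry's dominant association (acute subdural
#' hematoma with the inexperienced 16/17-year groups) at strength 3.
#'
#' @param n_records Number of records.
#' @param group_probs Named probability vector over individual group codes.
#' @param injury_probs Named baseline probability vector over injury
#'   categories of `body_system`.
#' @param cause_probs Named baseline probability vector over cause tokens.
#' @param month_probs Named probability vector over months `1..12`.
#' @param body_system `"head"` or `"spine"`.
#' @param enriched_injury,enriched_cause Data frames with columns
#'   `group` and `category`: the cells boosted by `association_strength`.
#' @param association_strength Odds multiplier >= 1 for the enriched cells.
#' @param seed Integer seed; all generation is reproducible under it.
#' @return An object of class `synthetic_config`, including the derived
#'   row-stochastic `injury_probs_by_group` and `cause_probs_by_group`
#'   matrices.
#' @export
synthetic_config <- function(n_records = 48L,
                             group_probs = NULL,
                             injury_probs = NULL,
                             cause_probs = NULL,
                             month_probs = NULL,
                             body_system = c("head", "spine"),
                             enriched_injury = NULL,
                             enriched_cause = NULL,
                             association_strength = 3,
                             seed = 1L) {
  body_system <- match.arg(body_system)
  groups <- c("16E1", "17E2", "18E3", "16EM", "17EM", "18EM")
  if (is.null(group_probs)) {
    # head-injury group marginals of the packaged registry: 16/10/9/6/4/3
    group_probs <- setNames(c(16, 10, 9, 6, 4, 3) / 48, groups)
  }
  if (is.null(injury_probs)) {
    inj_tab <- fixture_table(if (body_system == "head")
      "table2_head_injuries" else "table2_spine_injuries")
    tot <- inj_tab$row_totals
    injury_probs <- tot / sum(tot)
  }
  if (is.null(cause_probs)) {
    # cause-of-play row totals of the packaged collision-site table
    cause_probs <- setNames(c(13, 27, 2, 4, 1, 1) / 48,
                            c("T", "OT", "R", "C", "SV", "O"))
  }
  if (is.null(month_probs)) {
    hi <- fixture_table("table1_months")$counts["HI", as.character(1:12)]
    month_probs <- setNames(hi / sum(hi), as.character(1:12))
  }
  if (is.null(enriched_injury) && association_strength > 1) {
    enriched_injury <- data.frame(group = c("16E1", "17E2"),
                                  category = c("ASH", "ASH"))
  }
  check_probs <- function(p, what) {
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("config error: `", what, "` must be a named probability vector ",
           "summing to 1")
    }
  }
  check_probs(group_probs, "group_probs")
  check_probs(injury_probs, "injury_probs")
  check_probs(cause_probs, "cause_probs")
  check_probs(month_probs, "month_probs")
  if (!all(names(group_probs) %in% groups)) {
    stop("config error: group_probs must name individual group codes")
  }
  if (association_strength < 1) {
    stop("config error: association_strength must be >= 1")
  }
  cfg <- structure(list(
    n_records = as.integer(n_records),
    group_probs = group_probs,
    injury_probs = injury_probs,
    cause_probs = cause_probs,
    month_probs = month_probs,
    body_system = body_system,
    enriched_injury = enriched_injury,
    enriched_cause = enriched_cause,
    association_strength = association_strength,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  cfg$injury_probs_by_group <- boosted_matrix(group_probs, injury_probs,
                                              enriched_injury,
                                              association_strength)
  cfg$cause_probs_by_group <- boosted_matrix(group_probs, cause_probs,
                                             enriched_cause,
                                             association_strength)
  cfg
}

# Row-stochastic (group x category) matrix: baseline probabilities with
# enriched cells multiplied by `strength`, rows renormalised.
boosted_matrix <- function(group_probs, base_probs, enriched, strength) {
  m <- matrix(rep(base_probs, each = length(group_probs)),
              nrow = length(group_probs),
              dimnames = list(names(group_probs), names(base_probs)))
  if (!is.null(enriched) && nrow(enriched) > 0L) {
    for (i in seq_len(nrow(enriched))) {
      gr <- as.character(enriched$group[i])
      cat <- as.character(enriched$category[i])
      if (!gr %in% rownames(m) || !cat %in% colnames(m)) {
        stop("config error: enriched cell (", gr, ", ", cat,
             ") outside the declared vocabularies")
      }
      m[gr, cat] <- m[gr, cat] * strength
    }
  }
  sweep(m, 1L, rowSums(m), "/")
}

group_to_age_exp <- function(group) {
  age <- as.integer(substr(group, 1L, 2L))
  exp <- ifelse(grepl("EM$", group), age - 15L + 1L, age - 15L)
  data.frame(age = age, experience_years = exp)
}

#' Generate a synthetic injury registry
#'
#' Two generation modes. `"multinomial"` samples each record
#' independently: group from `group_probs`, then injury and cause from the
#' group's row of the boosted matrices, month from `month_probs`.
#' `"allocate"` produces *exact* marginals by largest-remainder rounding
#' of the target counts (groups first, then categories within each
#' group), useful for building fixture-like registries deterministically;
#' associations apply in both modes.
#'
#' @param config A [synthetic_config()].
#' @param mode `"multinomial"` (default) or `"allocate"`.
#' @return An [injury_records()] data frame with `config$n_records` rows
#'   (zero-row registries are allowed).
#' @export
generate_registry <- function(config, mode = c("multinomial", "allocate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_records
  empty <- data.frame(age = integer(0), experience_years = integer(0),
                      body_system = character(0), injury = character(0),
                      cause = character(0), site = character(0),
                      month = integer(0), outcome = character(0))
  if (n == 0L) return(injury_records(empty))
  groups <- names(config$group_probs)
  if (mode == "multinomial") {
    rec <- with_local_seed(config$seed, {
      g <- sample(groups, n, replace = TRUE, prob = config$group_probs)
      draw_by_group <- function(probs_by_group) {
        out <- character(n)
        for (gr in groups) {
          idx <- which(g == gr)
          if (length(idx) == 0L) next
          out[idx] <- sample(colnames(probs_by_group), length(idx),
                             replace = TRUE, prob = probs_by_group[gr, ])
        }
        out
      }
      inj <- draw_by_group(config$injury_probs_by_group)
      cz <- draw_by_group(config$cause_probs_by_group)
      mo <- sample(as.integer(names(config$month_probs)), n, replace = TRUE,
                   prob = config$month_probs)
      list(g = g, inj = inj, cz = cz, mo = mo)
    })
  } else {
    n_g <- allocate_counts(n, config$group_probs)
    g <- rep(groups, n_g)
    inj <- unlist(lapply(seq_along(groups), function(i) {
      rep(colnames(config$injury_probs_by_group),
          allocate_counts(n_g[i], config$injury_probs_by_group[i, ]))
    }))
    cz <- unlist(lapply(seq_along(groups), function(i) {
      rep(colnames(config$cause_probs_by_group),
          allocate_counts(n_g[i], config$cause_probs_by_group[i, ]))
    }))
    mo <- rep(as.integer(names(config$month_probs)),
              allocate_counts(n, config$month_probs))
    rec <- list(g = g, inj = inj, cz = cz, mo = mo)
  }
  ae <- group_to_age_exp(rec$g)
  injury_records(data.frame(
    age = ae$age, experience_years = ae$experience_years,
    body_system = config$body_system, injury = rec$inj, cause = rec$cz,
    site = NA_character_, month = rec$mo, outcome = "unknown",
    stringsAsFactors = FALSE
  ))
}

# Largest-remainder (Hamilton) rounding of n * probs to integers summing
# to n; ties broken toward earlier categories.
allocate_counts <- function(n, probs) {
  target <- n * probs
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- target - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Random bipartite graph with planted blocks
#'
#' Left and right nodes are split into `n_blocks` aligned blocks;
#' cross-side pairs inside a block pair receive an edge with probability
#' `p_within`, pairs straddling blocks with probability `p_between`.
#' The planted partition is recorded so recovery by community detection
#' can be scored (e.g. by adjusted Rand index).
#'
#' @param n_left,n_right Nodes per side.
#' @param n_blocks Number of planted blocks (default 2).
#' @param p_within,p_between Edge probabilities, `0 <= p_between <=
#'   p_within <= 1`.
#' @param seed Integer seed.
#' @return List of class `planted_bipartite`: `graph` (a
#'   [bipartite_graph()]), `membership` (named planted block ids),
#'   `p_within`, `p_between`, `seed`.
#' @export
planted_partition_graph <- function(n_left, n_right, n_blocks = 2L,
                                    p_within = 0.9, p_between = 0.05,
                                    seed = 1L) {
  stopifnot(p_between >= 0, p_within <= 1, p_between <= p_within,
            n_blocks >= 1L, n_left >= n_blocks, n_right >= n_blocks)
  left <- sprintf("L%02d", seq_len(n_left))
  right <- sprintf("R%02d", seq_len(n_right))
  lb <- block_split(n_left, n_blocks)
  rb <- block_split(n_right, n_blocks)
  prob <- ifelse(outer(lb, rb, "=="), p_within, p_between)
  draws <- with_local_seed(seed,
                           matrix(runif(n_left * n_right), n_left, n_right))
  hit <- which(draws < prob, arr.ind = TRUE)
  edges <- data.frame(left = left[hit[, 1L]], right = right[hit[, 2L]],
                      weight = 1, stringsAsFactors = FALSE)
  graph <- bipartite_graph(left, right, edges)
  structure(list(
    graph = graph,
    membership = setNames(c(lb, rb), c(left, right)),
    p_within = p_within, p_between = p_between, seed = as.integer(seed)
  ), class = "planted_bipartite")
}

block_split <- function(n, k) sort(rep_len(seq_len(k), n))
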