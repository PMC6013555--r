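# Per-term DEG counts and percentages, per-disorder totals over the
# deduplicated pool union, DEG share, and number-vs-percentage rankings.

#' Count DEGs per GO term
#'
#' For each term, the number of called genes inside the term's gene set and
#' that count as a percentage of the term's pool size (two decimals,
#' half-up), e.g. 5 DEGs in a 54-gene term reports 9.26.
#'
#' @param deg_genes character vector of significant gene symbols for one
#'   condition.
#' @param term_sets named list: term id -> gene set (all non-empty).
#' @param region,age condition labels carried into the output.
#' @return data.frame: `term`, `region`, `age`, `n_deg`, `pool_size`,
#'   `percentage`.
#' @export
count_degs_per_term <- function(deg_genes, term_sets, region, age) {
  if (!length(term_sets)) stop("term_sets must be non-empty")
  sizes <- lengths(term_sets)
  if (any(sizes == 0L))
    stop("empty term set(s): ",
         paste(names(term_sets)[sizes == 0L], collapse = ", "))
  n_deg <- vapply(term_sets, function(s) length(intersect(deg_genes, s)),
                  integer(1))
  data.frame(term = names(term_sets), region = region, age = age,
             n_deg = unname(n_deg), pool_size = unname(sizes),
             percentage = round_half_up(100 * unname(n_deg) / unname(sizes), 2),
             stringsAsFactors = FALSE)
}

#' Per-disorder DEG totals over the pool union
#'
#' A gene lying in two of the disorder's terms counts once here (and twice
#' in the per-term counts). The DEG share is the disorder's unique DEG
#' count as a percentage of all DEGs in the experiment, reported to one
#' decimal (half-up) with an integer-rounded convenience column.
#'
#' @param deg_genes significant gene symbols for one condition.
#' @param pool a `disorder_pool`.
#' @param n_total_degs total number of DEGs in the experiment (positive; at
#'   least the pool's DEG count).
#' @param region,age condition labels.
#' @return one-row data.frame: `disorder`, `region`, `age`, `n_deg_unique`,
#'   `pool_size`, `percentage`, `share_of_all_degs`, `share_rounded`.
#' @export
disorder_totals <- function(deg_genes, pool, n_total_degs, region, age) {
  stopifnot(inherits(pool, "disorder_pool"))
  if (n_total_degs <= 0L) stop("n_total_degs must be positive")
  n_unique <- length(intersect(deg_genes, pool$union))
  if (n_total_degs < n_unique)
    stop("n_total_degs is smaller than the pool's own DEG count")
  data.frame(disorder = pool$disorder, region = region, age = age,
             n_deg_unique = n_unique, pool_size = length(pool$union),
             percentage = round_half_up(100 * n_unique / length(pool$union), 2),
             share_of_all_degs = round_half_up(100 * n_unique / n_total_degs, 1),
             share_rounded = round_half_up(100 * n_unique / n_total_degs, 0),
             stringsAsFactors = FALSE)
}

#' Rank disorders by DEG number or percentage
#'
#' Descending order by the chosen key; ties are broken by the other key
#' (also descending), then alphabetically by disorder label.
#'
#' @param totals data.frame of [disorder_totals()] rows for one condition
#'   (one row per disorder).
#' @param by ranking key: `"number"` (unique DEG count) or `"percentage"`.
#' @return list with `order` (disorder labels, best first), `winner`, and
#'   `by`.
#' @export
rank_disorders <- function(totals, by = c("number", "percentage")) {
  by <- match.arg(by)
  if (anyDuplicated(totals$disorder))
    stop("duplicate disorder entries: ",
         paste(unique(totals$disorder[duplicated(totals$disorder)]),
               collapse = ", "))
  key <- if (by == "number") totals$n_deg_unique else totals$percentage
  other <- if (by == "number") totals$percentage else totals$n_deg_unique
  ord <- order(-key, -other, totals$disorder)
  list(order = totals$disorder[ord], winner = totals$disorder[ord][1], by = by)
}

#' Tidy per-term and total statistics for every disorder and condition
#'
#' Convenience wrapper producing the long-format statistics table: one row
#' per (disorder, term-or-Total, region, age).
#'
#' @param deg_by_condition named list: `"<region>_<age>"` -> significant
#'   gene symbols.
#' @param pools list of `disorder_pool` objects.
#' @param n_total_degs named integer vector of experiment-wide DEG counts,
#'   same names as `deg_by_condition`.
#' @param conditions data.frame with `region`, `age` rows (default the
#'   cortex/hippocampus x 7/18 grid).
#' @return long-format data.frame with a `term` column where the disorder
#'   total rows carry `"Total"` and per-term rows the GO id.
#' @export
disorder_stat_table <- function(deg_by_condition, pools, n_total_degs,
                                conditions = condition_grid()) {
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- paste(conditions$region[i], conditions$age[i], sep = "_")
    degs <- deg_by_condition[[cond]]
    for (pool in pools) {
      # terms with no annotated genes have no defined percentage; they are
      # omitted from the per-term rows (the Total row still covers the pool)
      sets <- pool$term_sets[lengths(pool$term_sets) > 0L]
      per_term <- count_degs_per_term(degs, sets,
                                      conditions$region[i], conditions$age[i])
      per_term <- cbind(disorder = pool$disorder, per_term,
                        stringsAsFactors = FALSE)
      tot <- disorder_totals(degs, pool, n_total_degs[[cond]],
                             conditions$region[i], conditions$age[i])
      tot_row <- data.frame(disorder = pool$disorder, term = "Total",
                            region = tot$region, age = tot$age,
                            n_deg = tot$n_deg_unique,
                            pool_size = tot$pool_size,
                            percentage = tot$percentage,
                            stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- rbind(per_term, tot_row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grid-shaped ranking report
#'
#' The wide, publication-shaped view of [disorder_stat_table()]: one row
#' per (disorder, term), one `"pct (n/size)"` cell per condition.
#'
#' @param stat_table output of [disorder_stat_table()].
#' @return wide data.frame with one column pair per condition.
#' @export
stats_grid <- function(stat_table) {
  stat_table$cell <- sprintf("%.2f (%d/%d)", stat_table$percentage,
                             stat_table$n_deg, stat_table$pool_size)
  conds <- unique(stat_table[, c("region", "age")])
  base <- unique(stat_table[, c("disorder", "term")])
  for (i in seq_len(nrow(conds))) {
    sel <- stat_table$region == conds$region[i] & stat_table$age == conds$age[i]
    sub <- stat_table[sel, ]
    idx <- match(paste(base$disorder, base$term),
                 paste(sub$disorder, sub$term))
    base[[sprintf("%s_%sm_number", conds$region[i], conds$age[i])]] <-
      sub$n_deg[idx]
    base[[sprintf("%s_%sm_percentage", conds$region[i], conds$age[i])]] <-
      sub$cell[idx]
  }
  rownames(base) <- NULL
  base
}
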