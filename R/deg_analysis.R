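# Probe-level two-group differential expression, the joint
# p-value/fold-change significance criterion, probe-to-gene collapse and
# post hoc multiple-testing correction.

#' Differential-expression calling criteria
#'
#' A probe (or gene) is called significant when `p < alpha` and the
#' symmetric fold change `max(FC, 1/FC)` exceeds `fc_threshold`, both
#' strictly. The symmetric form makes down-regulation (FC < 1) eligible:
#' a fold change of 0.70 passes the default 1.3 bound since 1/0.70 > 1.3.
#'
#' @param alpha significance level in (0, 1); default 0.05.
#' @param fc_threshold fold-change bound > 1; default 1.3.
#' @param correction which p-values the `significant` flag uses: `"none"`
#'   (raw, the default), `"bonferroni"` or `"bh"`. Corrected columns are
#'   always reported alongside.
#' @param pooled use Student's pooled-variance t-test instead of Welch
#'   (sensitivity analysis flag).
#' @return a `deg_criteria` list.
#' @export
deg_criteria <- function(alpha = 0.05, fc_threshold = 1.3,
                         correction = c("none", "bonferroni", "bh"),
                         pooled = FALSE) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 1)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 correction = match.arg(correction), pooled = pooled),
            class = "deg_criteria")
}

#' Fold change between knockout and control groups
#'
#' Ratio of group means on the linear intensity scale (knockout over
#' control). `fold_change(a, b) * fold_change(b, a) == 1`.
#'
#' @param ko_values positive intensities, knockout group.
#' @param wt_values positive intensities, control group.
#' @return positive scalar fold change.
#' @export
fold_change <- function(ko_values, wt_values) {
  if (!length(ko_values) || !length(wt_values))
    stop("both groups must be non-empty")
  if (any(ko_values <= 0) || any(wt_values <= 0))
    stop("intensities must be positive")
  mean(ko_values) / mean(wt_values)
}

#' Two-group test behind the DEG caller
#'
#' Two-sided two-sample t-test (Welch by default) on the values as given;
#' the caller is responsible for any log transform (the pipeline tests
#' log2 intensities). Degenerate inputs follow the conventions: both groups
#' constant with equal means gives p = 1, both constant with different
#' means gives p = 0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return two-sided p-value in \[0, 1\].
#' @export
probe_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  stats::t.test(group_a, group_b, var.equal = pooled)$p.value
}

# Vectorised Welch/Student test over matrix rows: a and b are matrices with
# the same row set (probes) and >= 2 columns each. Returns per-row p-values.
# Same conventions as probe_test for zero-variance rows.
row_t_test <- function(a, b, pooled = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  # zero variance in both groups: p by the equal/unequal means convention
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  unname(p)
}

deg_significant <- function(p_value, fold_change, criteria) {
  sym_fc <- pmax(fold_change, 1 / fold_change)
  p_value < criteria$alpha & sym_fc > criteria$fc_threshold
}

#' Call differentially expressed probes for one condition
#'
#' Selects the knockout and control arrays of one (region, age) condition,
#' tests each probe on the log2 scale, computes the linear-scale fold
#' change, and applies the joint criterion (both inequalities strict; both
#' directions eligible).
#'
#' @param x an `expr_matrix` (from [generate_expression()] or
#'   [read_expression()]).
#' @param region,age condition labels present in the sample sheet.
#' @param criteria a [deg_criteria()].
#' @return data.frame with one row per probe: `probe`, `region`, `age`,
#'   `p_value`, `fold_change`, `direction` (`up` iff FC > 1), `significant`.
#' @export
call_degs <- function(x, region, age, criteria = deg_criteria()) {
  stopifnot(inherits(x, "expr_matrix"))
  s <- x$samples
  in_cond <- s$region == region & s$age_months == age
  if (!any(in_cond))
    stop(sprintf("condition (%s, %s months) absent from sample sheet",
                 region, age))
  control <- x$control %||% x$design$genotypes[1] %||% unique(s$genotype)[1]
  wt <- which(in_cond & s$genotype == control)
  ko <- which(in_cond & s$genotype != control)
  if (length(wt) < 2L || length(ko) < 2L)
    stop("each genotype needs >= 2 arrays in the condition")
  ko_mat <- x$intensities[, ko, drop = FALSE]
  wt_mat <- x$intensities[, wt, drop = FALSE]
  p <- row_t_test(log2(ko_mat), log2(wt_mat), pooled = criteria$pooled)
  fc <- rowMeans(ko_mat) / rowMeans(wt_mat)
  data.frame(probe = rownames(x$intensities), region = region, age = age,
             p_value = p, fold_change = unname(fc),
             direction = ifelse(fc > 1, "up", "down"),
             significant = deg_significant(p, fc, criteria),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse probe-level calls to gene level
#'
#' A gene is significant iff at least one of its probes is. The reported
#' p-value and fold change come from the gene's representative probe: the
#' minimum-p probe, ties broken by the lexicographically smallest probe id.
#'
#' @param probe_records probe-level records from [call_degs()].
#' @param probe_map data.frame `probe_id`, `gene` covering every probe in
#'   the records.
#' @return gene-level data.frame: `gene`, `region`, `age`,
#'   `representative_probe`, `p_value`, `fold_change`, `direction`,
#'   `significant`, sorted by gene symbol.
#' @export
collapse_probes <- function(probe_records, probe_map) {
  idx <- match(probe_records$probe, probe_map$probe_id)
  if (anyNA(idx))
    stop("probe(s) missing from probe map: ",
         paste(unique(probe_records$probe[is.na(idx)]), collapse = ", "))
  recs <- probe_records
  recs$gene <- probe_map$gene[idx]
  # representative probe first within gene: ascending p, then probe id
  recs <- recs[order(recs$gene, recs$p_value, recs$probe), , drop = FALSE]
  first <- !duplicated(recs$gene)
  out <- recs[first, c("gene", "region", "age", "probe", "p_value",
                       "fold_change", "direction", "significant")]
  names(out)[names(out) == "probe"] <- "representative_probe"
  out$significant <- as.logical(
    tapply(recs$significant, recs$gene, any)[out$gene])
  rownames(out) <- NULL
  out
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' p-values, computed with [stats::p.adjust()].
#'
#' @param p_values raw p-values in \[0, 1\] (may be empty).
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(p_values, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!length(p_values)) return(numeric())
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

#' Attach corrected p-value columns to DEG records
#'
#' Adds `p_bonferroni` and `p_bh` computed across all rows (the correction
#' scope is the full record set passed in — per condition across the
#' GO-filtered probe pool in the pipeline), and, when the criteria ask for
#' a corrected `significant` flag, re-applies the joint criterion on the
#' corrected p-values.
#'
#' @param records probe- or gene-level DEG records.
#' @param criteria a [deg_criteria()].
#' @return the records with `p_bonferroni` and `p_bh` columns.
#' @export
add_corrected_pvalues <- function(records, criteria = deg_criteria()) {
  records$p_bonferroni <- adjust_pvalues(records$p_value, "bonferroni")
  records$p_bh <- adjust_pvalues(records$p_value, "bh")
  if (criteria$correction != "none") {
    p_used <- if (criteria$correction == "bh") records$p_bh
              else records$p_bonferroni
    records$significant <- deg_significant(p_used, records$fold_change,
                                           criteria)
  }
  records
}
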