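# Cross-age intersection of DEG sets, direction classification
# (consistent / contra-regulated), common-gene extraction and region
# specificity.

#' Partition two gene sets into a Venn layout
#'
#' @param set_7m,set_18m character vectors of significant genes at the two
#'   ages.
#' @return list of three disjoint sets `only_7m`, `only_18m`, `common`
#'   whose union is the input union. Swapping the inputs swaps the "only"
#'   sets and fixes `common`.
#' @export
venn_partition <- function(set_7m, set_18m) {
  set_7m <- unique(set_7m); set_18m <- unique(set_18m)
  list(only_7m = sort(setdiff(set_7m, set_18m)),
       only_18m = sort(setdiff(set_18m, set_7m)),
       common = sort(intersect(set_7m, set_18m)))
}

#' Classify a gene's cross-age direction
#'
#' `consistent_up` when both fold changes exceed 1, `consistent_down` when
#' both are below 1, `contra` when the signs of (FC - 1) differ (up at one
#' age, down at the other), and `flat` when either fold change equals 1
#' exactly. The flat class is unreachable for genes passing the fold-change
#' criterion but keeps the classification total.
#'
#' @param fc_7m,fc_18m positive fold changes at the two ages (vectorised).
#' @return character vector of direction classes.
#' @export
classify_direction <- function(fc_7m, fc_18m) {
  if (any(fc_7m <= 0) || any(fc_18m <= 0))
    stop("fold changes must be positive")
  ifelse(fc_7m == 1 | fc_18m == 1, "flat",
         ifelse(fc_7m > 1 & fc_18m > 1, "consistent_up",
                ifelse(fc_7m < 1 & fc_18m < 1, "consistent_down", "contra")))
}

#' Find genes consistently called across both ages
#'
#' Restricts gene-level DEG records of both ages to one disorder pool,
#' builds the Venn partition of the significant sets, and classifies the
#' direction of every common gene. Commonality requires significance at
#' both ages regardless of direction, so a contra-regulated gene is still
#' common.
#'
#' @param records_7m,records_18m gene-level DEG records (from
#'   [collapse_probes()] or equivalent) for the same region at the two
#'   ages; must carry `gene`, `region`, `fold_change`, `significant`.
#' @param pool a `disorder_pool`; results are restricted to its union.
#' @param region region label; all records must match it.
#' @return data.frame sorted by gene symbol, one row per pool gene
#'   significant at either age: `gene`, `region`, `disorder`,
#'   `significant_7m`, `significant_18m`, `fc_7m`, `fc_18m`, `venn_class`,
#'   `direction_class` (NA unless common).
#' @export
find_common_genes <- function(records_7m, records_18m, pool, region) {
  stopifnot(inherits(pool, "disorder_pool"))
  if (!length(pool$union)) stop("disorder pool is empty")
  regions <- unique(c(records_7m$region, records_18m$region))
  if (length(regions) && !all(regions == region))
    stop(sprintf("records are not all from region '%s' (found: %s)",
                 region, paste(regions, collapse = ", ")))
  r7 <- records_7m[records_7m$gene %in% pool$union, , drop = FALSE]
  r18 <- records_18m[records_18m$gene %in% pool$union, , drop = FALSE]
  sig7 <- r7$gene[r7$significant]
  sig18 <- r18$gene[r18$significant]
  venn <- venn_partition(sig7, sig18)
  genes <- sort(unique(c(sig7, sig18)))
  if (!length(genes))
    return(data.frame(gene = character(), region = character(),
                      disorder = character(), significant_7m = logical(),
                      significant_18m = logical(), fc_7m = numeric(),
                      fc_18m = numeric(), venn_class = character(),
                      direction_class = character(),
                      stringsAsFactors = FALSE))
  fc7 <- r7$fold_change[match(genes, r7$gene)]
  fc18 <- r18$fold_change[match(genes, r18$gene)]
  venn_class <- ifelse(genes %in% venn$common, "common",
                       ifelse(genes %in% venn$only_7m, "only_7m", "only_18m"))
  direction <- rep(NA_character_, length(genes))
  is_common <- venn_class == "common"
  if (any(is_common))
    direction[is_common] <- classify_direction(fc7[is_common],
                                               fc18[is_common])
  data.frame(gene = genes, region = region, disorder = pool$disorder,
             significant_7m = genes %in% sig7,
             significant_18m = genes %in% sig18,
             fc_7m = fc7, fc_18m = fc18, venn_class = venn_class,
             direction_class = direction, stringsAsFactors = FALSE)
}

#' Flag region-specific common genes
#'
#' A common gene (significant at both ages) is region-specific when it is
#' common in exactly one of the two regions.
#'
#' @param results_cortex,results_hippocampus outputs of
#'   [find_common_genes()] for the two regions (same disorder).
#' @return data.frame per gene: `gene`, `common_cortex`,
#'   `common_hippocampus`, `region_specific`.
#' @export
region_specificity <- function(results_cortex, results_hippocampus) {
  common_c <- results_cortex$gene[results_cortex$venn_class == "common"]
  common_h <- results_hippocampus$gene[
    results_hippocampus$venn_class == "common"]
  genes <- sort(unique(c(common_c, common_h)))
  data.frame(gene = genes,
             common_cortex = genes %in% common_c,
             common_hippocampus = genes %in% common_h,
             region_specific = xor(genes %in% common_c, genes %in% common_h),
             stringsAsFactors = FALSE)
}

#' Venn-cell direction counts
#'
#' The count table behind an up/down/contra Venn display: for each Venn
#' cell, how many genes are up, down, or (in the overlap only)
#' contra-regulated. Age-exclusive genes are classed by their fold change
#' at the age where they are significant; only overlap genes receive the
#' cross-age contra/consistent classes.
#'
#' @param results output of [find_common_genes()].
#' @return data.frame: `region`, `disorder`, `venn_class`, `direction`,
#'   `n`; within each Venn cell the direction counts sum to the cell size.
#' @export
venn_direction_counts <- function(results) {
  if (!nrow(results))
    return(data.frame(region = character(), disorder = character(),
                      venn_class = character(), direction = character(),
                      n = integer(), stringsAsFactors = FALSE))
  dir <- ifelse(results$venn_class == "only_7m",
                ifelse(results$fc_7m > 1, "up", "down"),
         ifelse(results$venn_class == "only_18m",
                ifelse(results$fc_18m > 1, "up", "down"),
         ifelse(results$direction_class == "consistent_up", "up",
         ifelse(results$direction_class == "consistent_down", "down",
                results$direction_class))))
  agg <- stats::aggregate(list(n = seq_len(nrow(results))),
                          by = list(region = results$region,
                                    disorder = results$disorder,
                                    venn_class = results$venn_class,
                                    direction = dir),
                          FUN = length)
  agg[order(agg$region, agg$disorder, agg$venn_class, agg$direction), ,
      drop = FALSE]
}

#' Fold-change grid of consistently altered genes
#'
#' The publication-shaped view of cross-age results: one row per common
#' gene, the four (region x age) fold changes with a `*` marker on the
#' cells where the gene was called significant, plus its region-specificity
#' flag.
#'
#' @param results_by_region named list `cortex`, `hippocampus` of
#'   [find_common_genes()] outputs for one disorder.
#' @return data.frame grid (empty when no gene is common anywhere).
#' @export
common_gene_grid <- function(results_by_region) {
  rc <- results_by_region$cortex
  rh <- results_by_region$hippocampus
  spec <- region_specificity(rc, rh)
  if (!nrow(spec))
    return(data.frame(disorder = character(), gene = character(),
                      cortex_7m = character(), cortex_18m = character(),
                      hippocampus_7m = character(),
                      hippocampus_18m = character(),
                      region_specific = logical(), stringsAsFactors = FALSE))
  cell <- function(res, gene, which_age) {
    i <- match(gene, res$gene)
    if (is.na(i)) return("")
    fc <- if (which_age == "7") res$fc_7m[i] else res$fc_18m[i]
    sig <- if (which_age == "7") res$significant_7m[i] else
      res$significant_18m[i]
    if (is.na(fc)) "" else sprintf("%.3f%s", fc, if (isTRUE(sig)) "*" else "")
  }
  grid <- data.frame(
    disorder = rep(unique(c(rc$disorder, rh$disorder))[1], nrow(spec)),
    gene = spec$gene,
    cortex_7m = vapply(spec$gene, cell, "", res = rc, which_age = "7"),
    cortex_18m = vapply(spec$gene, cell, "", res = rc, which_age = "18"),
    hippocampus_7m = vapply(spec$gene, cell, "", res = rh, which_age = "7"),
    hippocampus_18m = vapply(spec$gene, cell, "", res = rh, which_age = "18"),
    region_specific = spec$region_specific,
    stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  grid
}
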