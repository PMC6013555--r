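# A compact worked example: gene-level calls for the ten
# neuropsychiatric-disorder genes that show consistent cross-age alteration
# in the presenilin-dKO screen, with their region-specific
# significance pattern. Used in documentation, tests and the acceptance
# report to exercise the cross-age machinery on a known answer.

demo_fc_table <- function() {
  # gene, cortex 7m FC, sig, cortex 18m FC, sig, hipp 7m FC, sig, hipp 18m
  # FC, sig
  rows <- list(
    list("Hist1h1c", 1.802, TRUE,  1.688, TRUE,  1.536, FALSE, 1.175, FALSE),
    list("Pcdhb16",  0.692, TRUE,  0.740, TRUE,  1.034, FALSE, 1.135, FALSE),
    list("Arc",      1.512, FALSE, 0.422, FALSE, 1.652, TRUE,  0.615, TRUE),
    list("Cnn3",     1.255, FALSE, 1.877, FALSE, 1.380, TRUE,  1.207, TRUE),
    list("Stx3",     1.062, FALSE, 0.869, FALSE, 1.582, TRUE,  1.376, TRUE),
    list("Arpc1b",   1.887, FALSE, 1.661, FALSE, 1.639, TRUE,  1.870, TRUE),
    list("Paxbp1",   1.356, TRUE,  0.767, TRUE,  1.337, FALSE, 1.020, FALSE),
    list("Sorbs1",   1.465, TRUE,  1.781, TRUE,  1.161, FALSE, 1.368, FALSE),
    list("Kdm2a",    2.237, TRUE,  2.511, TRUE,  2.229, FALSE, 1.755, FALSE))
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1]],
               cortex_7 = r[[2]], sig_cortex_7 = r[[3]],
               cortex_18 = r[[4]], sig_cortex_18 = r[[5]],
               hippocampus_7 = r[[6]], sig_hippocampus_7 = r[[7]],
               hippocampus_18 = r[[8]], sig_hippocampus_18 = r[[9]],
               stringsAsFactors = FALSE)))
}

#' Worked-example cross-age DEG records
#'
#' A small fixture of gene-level differential-expression calls for ten
#' disorder-pool genes (Hist1h1c, Pcdhb16, Arc, Cnn3, Stx3, Arpc1b, Paxbp1,
#' Sorbs1, Kdm2a) in cortex and hippocampus at 7 and 18 months, together
#' with minimal BIP/SCZ/MDD pools containing them. The significance pattern
#' is region-specific: e.g. Hist1h1c is consistently up in the cortex only,
#' Arc is contra-regulated (up at 7 months, down at 18) in the hippocampus,
#' and no MDD gene is consistently altered in the hippocampus.
#'
#' @return list with `records` (named list `"<region>_<age>"` of gene-level
#'   DEG record data.frames) and `pools` (named list of `disorder_pool`
#'   objects: SCZ, BIP, MDD).
#' @export
demo_common_gene_records <- function() {
  fc <- demo_fc_table()
  records <- list()
  for (region in c("cortex", "hippocampus")) {
    for (age in c("7", "18")) {
      records[[paste(region, age, sep = "_")]] <- data.frame(
        gene = fc$gene, region = region, age = age,
        fold_change = fc[[paste(region, age, sep = "_")]],
        significant = fc[[paste("sig", region, age, sep = "_")]],
        stringsAsFactors = FALSE)
    }
  }
  term_sets <- list(
    "GO:0014069" = c("Arc", "Cnn3"),            # postsynaptic density
    "GO:0045211" = c("Pcdhb16", "Arc"),         # postsynaptic membrane
    "GO:0043197" = c("Arc", "Cnn3"),            # dendritic spine
    "GO:0051568" = "Hist1h1c",                  # histone H3-K4 methylation
    "GO:0033267" = "Stx3",                      # axon part
    "GO:0090066" = "Arpc1b",                    # reg. of structure size
    "GO:0007129" = character(0),
    "GO:0070192" = character(0),
    "GO:0034330" = "Paxbp1",                    # cell junction organization
    "GO:0045216" = "Sorbs1",                    # cell-cell junction org.
    "GO:0043297" = character(0),
    "GO:0031056" = "Kdm2a",                     # reg. of histone modification
    "GO:0008601" = character(0))
  cfg <- disorder_config()
  pools <- lapply(split(cfg, cfg$disorder), function(sub)
    build_disorder_pool(term_sets, sub))
  list(records = records, pools = pools[c("SCZ", "BIP", "MDD")])
}
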