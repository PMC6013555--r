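# Named scenario bundles: a full set of pipeline inputs (expression, probe
# map, GAF, OBO, disorder config) plus ground-truth tables, generated with
# known planted effects so every downstream stage can be checked end to end.

# Table of configured per-term set sizes used by the paper_like scenario:
# the packaged disorder preset's 13 distinct terms with their snapshot pool
# sizes. Global redundancy 453 makes the realized all-disorder union 1207
# genes.
paper_like_term_sizes <- function() {
  c("GO:0051568" = 32L,  "GO:0007129" = 23L,  "GO:0090066" = 54L,
    "GO:0070192" = 362L, "GO:0014069" = 205L, "GO:0045211" = 207L,
    "GO:0043197" = 116L, "GO:0033267" = 192L, "GO:0008601" = 8L,
    "GO:0034330" = 137L, "GO:0043297" = 122L, "GO:0045216" = 67L,
    "GO:0031056" = 135L)
}
PAPER_LIKE_REDUNDANCY <- 453L

# Pick n genes belonging to the given disorder's pool and to no other
# disorder's pool (so planted per-disorder DEG counts stay clean).
exclusive_pool_genes <- function(pools, disorder) {
  own <- pools[[disorder]]$union
  others <- unlist(lapply(pools[setdiff(names(pools), disorder)],
                          function(p) p$union), use.names = FALSE)
  setdiff(own, others)
}

#' Generate a named scenario bundle
#'
#' Presets:
#' \describe{
#'   \item{`null`}{no planted effects; 5000 genes (>= 10,000 probes) and 10
#'     arrays per group, for type-I-error calibration of the DEG caller
#'     (the Welch approximation is only trustworthy with a few arrays per
#'     group, so calibration runs above the pooled design's n = 2).
#'     Ground-truth DEG table is empty.}
#'   \item{`paper_like`}{the packaged 13-term disorder configuration with
#'     snapshot pool sizes (1207-gene union); per condition, 16 SCZ, 6 BIP
#'     and 4 MDD pool-exclusive genes planted at log2 effect 1.5 (a strong
#'     ~2.8-fold hit, sized so the SCZ-first ordering survives the pooled
#'     design's low power and false-positive noise), so SCZ ranks first by
#'     DEG number in every condition; two cortex-common SCZ genes (one up,
#'     one down at both ages, log2 effect 1) and three hippocampus-common
#'     SCZ genes including one contra-regulated.}
#'   \item{`contra_demo`}{one gene planted at log2 effect +0.7 at 7 months
#'     and -0.7 at 18 months in the hippocampus, 10 arrays per group.}
#' }
#'
#' @param preset one of `"null"`, `"paper_like"`, `"contra_demo"`.
#' @param seed integer master seed; all stages derive their streams from it.
#' @param dir optional directory: when given, all inputs and ground-truth
#'   tables are written as plain text (TSV / GAF / OBO).
#' @param arrays_per_group override the preset's arrays per group (the
#'   pooled design's 2 for `paper_like`, 10 for `null`/`contra_demo`).
#' @return list: `expression` (an `expr_matrix`), `annotations` (gaf/obo
#'   lines + realized term sets), `disorder_config`, `effects`,
#'   `truth` (data.frame of planted DEGs with intended classes), `design`.
#' @export
generate_scenario <- function(preset = c("null", "paper_like", "contra_demo"),
                              seed = 1L, dir = NULL,
                              arrays_per_group = NULL) {
  preset <- match.arg(preset)
  cfg <- disorder_config()
  conditions <- condition_grid()

  if (preset == "null") {
    design <- simulation_design(arrays_per_group = arrays_per_group %||% 10L,
                                n_genes = 5000L, seed = seed)
    genes <- default_gene_names(design$n_genes)
    go_spec <- go_fixture_spec(paper_like_term_sizes(),
                               redundant_memberships = PAPER_LIKE_REDUNDANCY,
                               seed = derive_seed(seed, "go"))
    ann <- generate_annotations(go_spec, ontology_depth = 1L)
    effects <- planted_effects()
    truth <- empty_truth()
  } else if (preset == "paper_like") {
    design <- simulation_design(arrays_per_group = arrays_per_group %||% 2L,
                                n_genes = 1500L, seed = seed)
    genes <- default_gene_names(design$n_genes)
    go_spec <- go_fixture_spec(paper_like_term_sizes(),
                               redundant_memberships = PAPER_LIKE_REDUNDANCY,
                               seed = derive_seed(seed, "go"))
    ann <- generate_annotations(go_spec, ontology_depth = 1L)
    pools <- lapply(split(cfg, cfg$disorder), function(sub)
      build_disorder_pool(ann$term_sets, sub))
    picks <- with_seed(derive_seed(seed, "plant"), {
      n_plant <- c(SCZ = 16L, BIP = 6L, MDD = 4L)
      lapply(names(n_plant), function(d) {
        excl <- exclusive_pool_genes(pools, d)
        lapply(seq_len(nrow(conditions)), function(i)
          sample(excl, n_plant[[d]]))
      }) |> stats::setNames(names(n_plant))
    })
    effects <- list()
    truth_rows <- list()
    for (d in names(picks)) {
      for (i in seq_len(nrow(conditions))) {
        gset <- picks[[d]][[i]]
        eff <- planted_effects(gset, conditions$region[i], conditions$age[i],
                               rep(1.5, length(gset)))
        effects[[length(effects) + 1L]] <- eff
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(disorder = d, eff, expected_direction = "up",
                expected_class = NA_character_, stringsAsFactors = FALSE)
      }
    }
    # cross-age common SCZ genes: up/down pair in the cortex, three in the
    # hippocampus with one contra-regulated (the published direction motif)
    scz_excl <- exclusive_pool_genes(pools, "SCZ")
    planted_already <- unique(unlist(lapply(picks$SCZ, identity)))
    free <- setdiff(scz_excl, planted_already)
    common_genes <- with_seed(derive_seed(seed, "common"), sample(free, 5L))
    common_spec <- data.frame(
      gene = common_genes,
      region = c("cortex", "cortex", "hippocampus", "hippocampus",
                 "hippocampus"),
      e7 = c(1, -1, 1, 1, 1), e18 = c(1, -1, -1, 1, 1),
      class = c("consistent_up", "consistent_down", "contra",
                "consistent_up", "consistent_up"),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(common_spec))) {
      eff <- planted_effects(rep(common_spec$gene[i], 2L),
                             rep(common_spec$region[i], 2L), c("7", "18"),
                             c(common_spec$e7[i], common_spec$e18[i]))
      effects[[length(effects) + 1L]] <- eff
      truth_rows[[length(truth_rows) + 1L]] <-
        cbind(disorder = "SCZ", eff,
              expected_direction = ifelse(eff$log2_effect > 0, "up", "down"),
              expected_class = common_spec$class[i],
              stringsAsFactors = FALSE)
    }
    effects <- do.call(rbind, effects)
    truth <- do.call(rbind, truth_rows)
  } else { # contra_demo
    design <- simulation_design(arrays_per_group = arrays_per_group %||% 10L,
                                n_genes = 200L, seed = seed)
    genes <- default_gene_names(design$n_genes)
    gene <- genes[1]
    go_spec <- go_fixture_spec(c("GO:0014069" = 20L), seed =
                                 derive_seed(seed, "go"))
    ann <- generate_annotations(go_spec, ontology_depth = 0L)
    cfg <- cfg[cfg$term == "GO:0014069", , drop = FALSE]
    effects <- planted_effects(rep(gene, 2L), rep("hippocampus", 2L),
                               c("7", "18"), c(0.7, -0.7))
    truth <- cbind(disorder = "SCZ", effects,
                   expected_direction = c("up", "down"),
                   expected_class = "contra", stringsAsFactors = FALSE)
  }

  expr <- generate_expression(design, effects)
  bundle <- list(preset = preset, seed = seed, expression = expr,
                 annotations = ann, disorder_config = cfg,
                 effects = effects, truth = truth, design = design)
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

empty_truth <- function() {
  data.frame(disorder = character(), gene = character(), region = character(),
             age = character(), log2_effect = numeric(),
             expected_direction = character(), expected_class = character(),
             stringsAsFactors = FALSE)
}

#' Write a scenario bundle to disk
#'
#' Emits the pipeline input files (`expression.tsv`, `samples.tsv`,
#' `probe_map.tsv`, `annotations.gaf`, `ontology.obo`,
#' `disorder_config.tsv`) and the ground-truth table
#' (`ground_truth_degs.tsv`) as plain text.
#'
#' @param bundle output of [generate_scenario()].
#' @param dir target directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- bundle$expression
  mat <- data.frame(probe_id = rownames(expr$intensities),
                    expr$intensities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(mat, file.path(dir, "expression.tsv"))
  write_tsv(expr$samples, file.path(dir, "samples.tsv"))
  write_tsv(expr$probe_map, file.path(dir, "probe_map.tsv"))
  writeLines(bundle$annotations$gaf_lines, file.path(dir, "annotations.gaf"))
  writeLines(bundle$annotations$obo_lines, file.path(dir, "ontology.obo"))
  write_tsv(bundle$disorder_config, file.path(dir, "disorder_config.tsv"))
  write_tsv(bundle$truth, file.path(dir, "ground_truth_degs.tsv"))
  invisible(dir)
}
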