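# Expression / annotation generators: determinism, planted-effect
# semantics, probe-map properties and overlap accounting.

test_that("zero-noise null design gives identical columns and unit fold changes", {
  design <- simulation_design(n_genes = 20L, noise_sd_log2 = 0,
                              baseline_log2_sd = 1, seed = 11L)
  x <- generate_expression(design)
  expect_equal(nrow(x$intensities), nrow(x$probe_map))
  expect_equal(ncol(x$intensities), 2 * 2 * 2 * 2)
  # every probe constant across all arrays
  expect_true(all(apply(x$intensities, 1, function(r) diff(range(r)) == 0)))
  d <- call_degs(x, "cortex", "7")
  expect_true(all(d$fold_change == 1))
  expect_false(any(d$significant))
})

test_that("planted log2 effect of 1 yields an empirical KO/WT ratio near 2", {
  # law-of-large-numbers check: 50 arrays/group, sd 0.1
  design <- simulation_design(arrays_per_group = 50L, n_genes = 5L,
                              probes_per_gene = c(1L, 1L),
                              noise_sd_log2 = 0.1, seed = 5L)
  eff <- planted_effects("g00001", "cortex", "18", 1.0)
  x <- generate_expression(design, eff)
  s <- x$samples
  ko <- s$genotype == "KO" & s$region == "cortex" & s$age_months == "18"
  wt <- s$genotype == "WT" & s$region == "cortex" & s$age_months == "18"
  ratio <- mean(x$intensities["g00001_at1", ko]) /
    mean(x$intensities["g00001_at1", wt])
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
  # effect applied only to the matching condition's KO columns
  other <- s$genotype == "KO" & !(s$region == "cortex" & s$age_months == "18")
  ratio_other <- mean(x$intensities["g00001_at1", other]) /
    mean(x$intensities["g00001_at1", s$genotype == "WT" & !wt])
  expect_lt(abs(log2(ratio_other)), 0.2)
})

test_that("identical seeds reproduce byte-identical expression output", {
  design <- simulation_design(n_genes = 30L, seed = 99L)
  eff <- planted_effects(c("g00002", "g00002"), c("cortex", "cortex"),
                         c("7", "18"), c(0.7, -0.7))
  x1 <- generate_expression(design, eff)
  x2 <- generate_expression(design, eff)
  expect_identical(x1$intensities, x2$intensities)
  expect_identical(x1$probe_map, x2$probe_map)
  x3 <- generate_expression(simulation_design(n_genes = 30L, seed = 100L), eff)
  expect_false(identical(x1$intensities, x3$intensities))
})

test_that("effects referencing unknown genes, regions or ages are rejected by name", {
  design <- simulation_design(n_genes = 3L)
  expect_error(generate_expression(design,
                                   planted_effects("nope", "cortex", "7", 1)),
               "nope")
  expect_error(generate_expression(design,
                                   planted_effects("g00001", "thalamus", "7", 1)),
               "thalamus")
  expect_error(generate_expression(design,
                                   planted_effects("g00001", "cortex", "12", 1)),
               "12")
})

test_that("probe map covers every gene with unique probes", {
  expect_equal(nrow(generate_probe_map(character())), 0L)
  one_each <- generate_probe_map(c("a", "b", "c"), c(1L, 1L))
  expect_equal(nrow(one_each), 3L)
  expect_setequal(one_each$gene, c("a", "b", "c"))
  expect_false(anyDuplicated(one_each$probe_id) > 0)

  # re-draw oracle: the per-gene counts equal an independent draw from the
  # same seeded stream
  genes <- sprintf("gene%02d", 1:10)
  pm <- generate_probe_map(genes, c(1L, 5L), seed = 42L)
  counts <- table(factor(pm$gene, levels = genes))
  redraw <- npscreen:::with_seed(42L, sample(1:5, 10, replace = TRUE))
  expect_equal(as.integer(counts), redraw)
  expect_equal(nrow(pm), sum(redraw))
  expect_true(all(counts >= 1))
  expect_error(generate_probe_map(genes, c(0L, 2L)), "min")
})

test_that("GO fixture realizes configured sizes and exact overlap accounting", {
  ann <- generate_annotations(bip_fixture_spec())
  sizes <- lengths(ann$term_sets)
  expect_equal(sort(unname(sizes)), c(23L, 32L, 54L, 362L))
  union_size <- length(unique(unlist(ann$term_sets)))
  expect_equal(union_size, 448L)
  expect_equal(sum(sizes) - union_size, 23L)

  # disjoint case
  spec0 <- go_fixture_spec(c("GO:0000001" = 32L, "GO:0000002" = 23L,
                             "GO:0000003" = 54L, "GO:0000004" = 362L))
  ann0 <- generate_annotations(spec0)
  expect_equal(length(unique(unlist(ann0$term_sets))), 471L)

  # unsatisfiable overlap is rejected with the violated bound
  expect_error(go_fixture_spec(c("GO:0000001" = 5L, "GO:0000002" = 3L),
                               redundant_memberships = 4L),
               "unsatisfiable")
})

test_that("fixture identity sum(sizes) - |union| = redundancy holds for random specs", {
  set.seed(202)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    sizes <- sample(3:40, k)
    names(sizes) <- sprintf("GO:%07d", seq_len(k))
    bound <- sum(sizes) - max(sizes)
    red <- sample(0:bound, 1)
    ann <- generate_annotations(go_fixture_spec(sizes, red, seed = i))
    expect_equal(lengths(ann$term_sets)[names(sizes)], sizes)
    expect_equal(sum(lengths(ann$term_sets)) -
                   length(unique(unlist(ann$term_sets))), red)
  }
})

test_that("generated GAF/OBO round-trips through the annotation parser", {
  # depth-2 ontologies: a fraction of memberships sits on child terms, so
  # is_a expansion is required to recover the configured sets
  set.seed(303)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    sizes <- sample(5:30, k)
    names(sizes) <- sprintf("GO:%07d", sample(1e6, k))
    red <- sample(0:(sum(sizes) - max(sizes)), 1)
    ann <- generate_annotations(go_fixture_spec(sizes, red, seed = 100 + i),
                                ontology_depth = 2L, child_fraction = 0.5)
    graph <- parse_obo(ann$obo_lines, quiet = TRUE)
    recs <- filter_annotations(parse_gaf(ann$gaf_lines, quiet = TRUE))
    sets <- build_term_gene_sets(recs, graph, names(sizes))
    expect_equal(lapply(sets, sort), lapply(ann$term_sets, sort))
  }
})

test_that("expansion is genuinely needed at depth > 0", {
  sizes <- c("GO:0000010" = 30L, "GO:0000020" = 30L)
  ann <- generate_annotations(go_fixture_spec(sizes, seed = 9L),
                              ontology_depth = 2L, child_fraction = 0.6)
  recs <- filter_annotations(parse_gaf(ann$gaf_lines, quiet = TRUE))
  direct <- lapply(names(sizes),
                   function(t) unique(recs$gene[recs$term == t]))
  expect_true(any(lengths(direct) < sizes))
})

test_that("scenario presets carry the advertised ground truth", {
  null_b <- generate_scenario("null", seed = 4L)
  expect_equal(nrow(null_b$truth), 0L)
  expect_gte(nrow(null_b$expression$intensities), 10000L)

  contra <- generate_scenario("contra_demo", seed = 4L)
  expect_equal(unique(contra$truth$expected_class), "contra")
  expect_setequal(contra$truth$log2_effect, c(0.7, -0.7))

  expect_error(generate_scenario("bogus"), "arg")
})

test_that("paper_like ground truth ranks SCZ first by number in all conditions", {
  b <- generate_scenario("paper_like", seed = 2L)
  cfg <- b$disorder_config
  recs <- filter_annotations(parse_gaf(b$annotations$gaf_lines, quiet = TRUE))
  graph <- parse_obo(b$annotations$obo_lines, quiet = TRUE)
  sets <- build_term_gene_sets(recs, graph, unique(cfg$term))
  pools <- lapply(split(cfg, cfg$disorder), function(sub)
    build_disorder_pool(sets, sub))
  for (region in c("cortex", "hippocampus")) {
    for (age in c("7", "18")) {
      truth_genes <- unique(
        b$truth$gene[b$truth$region == region & b$truth$age == age])
      tot <- do.call(rbind, lapply(pools, function(p)
        disorder_totals(truth_genes, p, max(1L, length(truth_genes)),
                        region, age)))
      expect_equal(rank_disorders(tot, by = "number")$winner, "SCZ")
    }
  }
})

test_that("scenario bundles write a complete plain-text input set", {
  dir <- withr::local_tempdir()
  generate_scenario("contra_demo", seed = 1L, dir = dir)
  expect_setequal(dir(dir),
                  c("expression.tsv", "samples.tsv", "probe_map.tsv",
                    "annotations.gaf", "ontology.obo", "disorder_config.tsv",
                    "ground_truth_degs.tsv"))
  x <- read_expression(file.path(dir, "expression.tsv"),
                       file.path(dir, "samples.tsv"),
                       file.path(dir, "probe_map.tsv"))
  expect_s3_class(x, "expr_matrix")
  expect_equal(ncol(x$intensities), nrow(x$samples))
})
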