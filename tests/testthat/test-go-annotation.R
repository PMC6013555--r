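# GAF parsing, qualifier/taxon filtering, is_a expansion and disorder-pool
# accounting.

gaf_data_line <- function(gene, qualifier, term, taxon = "10090",
                          evidence = "IDA") {
  paste(c("MGI", paste0("MGI:", gene), gene, qualifier, term, "PMID:1",
          evidence, "", "P", "", "", "protein", paste0("taxon:", taxon),
          "20170919", "MGI", "", ""), collapse = "\t")
}

test_that("GAF parsing matches a hand parse and skips malformed lines", {
  expect_equal(nrow(parse_gaf("!gaf-version: 2.2")), 0L)

  lines <- c("!gaf-version: 2.2",
             gaf_data_line("Arc", "involved_in", "GO:0014069"),
             gaf_data_line("Cnn3", "NOT|involved_in", "GO:0043197",
                           taxon = "10090", evidence = "IEA"),
             gaf_data_line("Stx3", "part_of", "GO:0033267", taxon = "9606"))
  recs <- parse_gaf(lines)
  expect_equal(recs$gene, c("Arc", "Cnn3", "Stx3"))
  expect_equal(recs$term, c("GO:0014069", "GO:0043197", "GO:0033267"))
  expect_equal(recs$taxon, c("10090", "10090", "9606"))
  expect_equal(recs$evidence, c("IDA", "IEA", "IDA"))
  expect_equal(strsplit(recs$qualifiers[2], "|", fixed = TRUE)[[1]],
               c("NOT", "involved_in"))

  # short line and bad GO id are skipped with their line numbers, not fatal
  bad <- c(lines[1:2], "too\tfew\tcolumns",
           gaf_data_line("Kdm2a", "enables", "GO:bad"))
  expect_message(recs2 <- parse_gaf(bad), "3, 4")
  expect_equal(recs2$gene, "Arc")
})

test_that("GAF records survive a serialize/re-parse round trip", {
  lines <- c(gaf_data_line("Arc", "involved_in", "GO:0014069"),
             gaf_data_line("Cnn3", "NOT|involved_in", "GO:0043197"),
             gaf_data_line("Stx3", "part_of|enables", "GO:0033267"))
  recs <- parse_gaf(lines)
  expect_equal(parse_gaf(write_gaf(recs)), recs)
})

test_that("qualifier/taxon filter keeps exactly the valid records, idempotently", {
  lines <- c(gaf_data_line("a1", "involved_in", "GO:0000001", taxon = "9606"),
             gaf_data_line("a2", "enables", "GO:0000001", taxon = "9999"),
             gaf_data_line("a3", "NOT|involved_in", "GO:0000001"),
             gaf_data_line("a4", "involved_in", "GO:0000001"),
             gaf_data_line("a5", "colocalizes_with", "GO:0000002"),
             gaf_data_line("a6", "part_of", "GO:0000002"))
  recs <- parse_gaf(lines)
  kept <- filter_annotations(recs)
  expect_equal(kept$gene, c("a4", "a5", "a6"))
  expect_equal(filter_annotations(kept), kept)          # idempotent
  expect_lte(nrow(kept), nrow(recs))                    # never grows
  expect_equal(nrow(filter_annotations(recs[0, ])), 0L) # empty in, empty out

  # an empty qualifier cell is dropped; a disallowed qualifier is dropped
  other <- parse_gaf(c(gaf_data_line("b1", "", "GO:0000003"),
                       gaf_data_line("b2", "acts_upstream_of", "GO:0000003")))
  expect_equal(nrow(filter_annotations(other)), 0L)
  expect_error(filter_annotations(recs, allowed_qualifiers = character()),
               "non-empty")
})

test_that("is_a expansion returns the term plus all descendants", {
  chain <- ontology_graph(c("A", "B", "C"),
                          data.frame(child = c("A", "B"), parent = c("B", "C")))
  expect_setequal(expand_term(chain, "C"), c("A", "B", "C"))
  expect_equal(expand_term(chain, "A"), "A")  # leaf

  diamond <- ontology_graph(c("A", "B", "C", "D"),
                            data.frame(child = c("A", "A", "B", "C"),
                                       parent = c("B", "C", "D", "D")))
  got <- expand_term(diamond, "D")
  expect_setequal(got, c("A", "B", "C", "D"))
  expect_equal(length(got), 4L)               # no duplicates from both paths

  expect_error(expand_term(chain, "Z"), "Z")
  expect_error(ontology_graph(c("A", "B"),
                              data.frame(child = c("A", "B"),
                                         parent = c("B", "A"))),
               "cycle")
})

test_that("expansion agrees with brute-force reachability on random DAGs", {
  set.seed(77)
  for (i in 1:10) {
    dag <- random_dag(200, p_edge = 0.02)
    graph <- ontology_graph(dag$terms, dag$edges)
    for (term in sample(dag$terms, 5)) {
      expect_equal(sort(expand_term(graph, term)),
                   oracle_descendants(dag$edges, term))
    }
  }
})

test_that("term gene sets honour expansion and collapse duplicate annotations", {
  graph <- ontology_graph(c("GO:0000001", "GO:0000002"),
                          data.frame(child = "GO:0000001",
                                     parent = "GO:0000002"))
  recs <- parse_gaf(c(
    gaf_data_line("childgene", "involved_in", "GO:0000001"),
    gaf_data_line("dup", "involved_in", "GO:0000002", evidence = "IDA"),
    gaf_data_line("dup", "involved_in", "GO:0000002", evidence = "IEA")))
  sets <- build_term_gene_sets(recs, graph, c("GO:0000001", "GO:0000002"))
  expect_equal(sets[["GO:0000001"]], "childgene")
  # child-term annotation propagates to the parent; duplicates count once
  expect_equal(sets[["GO:0000002"]], c("childgene", "dup"))
  expect_equal(build_term_gene_sets(recs[0, ], graph, "GO:0000002"),
               list("GO:0000002" = character(0)))
  expect_error(build_term_gene_sets(recs, graph, "GO:9999999"), "GO:9999999")
})

test_that("part_of relationships are parsed but not traversed", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001",
           "relationship: part_of GO:0000002 ! whole", "",
           "[Term]", "id: GO:0000002", "")
  expect_message(graph <- parse_obo(obo), "part_of")
  expect_equal(expand_term(graph, "GO:0000002"), "GO:0000002")
})

test_that("disorder pools reproduce the published overlap accounting", {
  # BIP shape: sizes 32/23/54/362 with 23 redundant memberships -> union 448
  bip <- generate_annotations(bip_fixture_spec())
  cfg_bip <- data.frame(disorder = "BIP", term = names(bip$term_sets),
                        name = names(bip$term_sets))
  pool_bip <- build_disorder_pool(bip$term_sets, cfg_bip)
  expect_equal(length(pool_bip$union), 448L)
  expect_equal(pool_bip$redundant_memberships, 23L)

  # SCZ shape: sizes 205/207/116/32/192 with 196 redundancies -> union 556
  scz <- generate_annotations(go_fixture_spec(
    c("GO:0014069" = 205L, "GO:0045211" = 207L, "GO:0043197" = 116L,
      "GO:0051568" = 32L, "GO:0033267" = 192L),
    redundant_memberships = 196L, seed = 2L))
  cfg_scz <- data.frame(disorder = "SCZ", term = names(scz$term_sets),
                        name = names(scz$term_sets))
  pool_scz <- build_disorder_pool(scz$term_sets, cfg_scz)
  expect_equal(length(pool_scz$union), 556L)

  # MDD shape: sizes 8/137/122/67/135 with 134 redundancies -> union 335
  mdd <- generate_annotations(go_fixture_spec(
    c("GO:0008601" = 8L, "GO:0034330" = 137L, "GO:0043297" = 122L,
      "GO:0045216" = 67L, "GO:0031056" = 135L),
    redundant_memberships = 134L, seed = 3L))
  cfg_mdd <- data.frame(disorder = "MDD", term = names(mdd$term_sets),
                        name = names(mdd$term_sets))
  expect_equal(length(build_disorder_pool(mdd$term_sets, cfg_mdd)$union), 335L)

  # mutually disjoint sets: union is the plain sum
  disj <- list(t1 = c("a", "b"), t2 = c("c"), t3 = c("d", "e", "f"))
  cfg_d <- data.frame(disorder = "X", term = names(disj), name = names(disj))
  pool_d <- build_disorder_pool(disj, cfg_d)
  expect_equal(length(pool_d$union), 6L)
  expect_equal(pool_d$redundant_memberships, 0L)

  expect_error(build_disorder_pool(disj, data.frame(disorder = "X",
                                                    term = "missing",
                                                    name = "missing")),
               "missing")
})

test_that("redundancy identity holds for arbitrary random term sets", {
  set.seed(88)
  universe <- sprintf("gene%03d", 1:60)
  for (i in 1:25) {
    sets <- lapply(seq_len(sample(2:5, 1)),
                   function(j) sample(universe, sample(1:30, 1)))
    names(sets) <- sprintf("GO:%07d", seq_along(sets))
    cfg <- data.frame(disorder = "X", term = names(sets), name = names(sets))
    pool <- build_disorder_pool(sets, cfg)
    expect_equal(pool$redundant_memberships,
                 sum(lengths(sets)) - length(unique(unlist(sets))))
    expect_setequal(pool$union, unique(unlist(sets)))
  }
})

test_that("the packaged disorder preset has 14 slots over 13 distinct terms", {
  cfg <- disorder_config()
  expect_equal(nrow(cfg), 14L)
  expect_equal(length(unique(cfg$term)), 13L)
  expect_equal(sum(cfg$disorder == "BIP"), 4L)
  expect_equal(sum(cfg$disorder == "SCZ"), 5L)
  expect_equal(sum(cfg$disorder == "MDD"), 5L)
  # the H3-K4 methylation term is shared between BIP and SCZ
  expect_setequal(cfg$disorder[cfg$term == "GO:0051568"], c("BIP", "SCZ"))

  # both numbers surface in the pool report
  demo <- demo_common_gene_records()
  report <- pool_report(demo$pools, cfg)
  expect_equal(attr(report, "term_slots"), 14L)
  expect_equal(attr(report, "distinct_terms"), 13L)
})
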