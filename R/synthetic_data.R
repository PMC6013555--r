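# Synthetic expression / annotation generators with known ground truth.
#
# The generators emulate the shape of an Affymetrix-style probe-level
# experiment: a 2-genotype x 2-region x 2-age design with a small number of
# arrays per group, several probes per gene, log-normal intensities, and GO
# annotation fixtures with configurable per-term sizes and overlaps.

#' Describe a simulated expression experiment
#'
#' The default design mirrors the pooled mouse study the package targets:
#' WT vs forebrain PSEN double-knockout, cortex and hippocampus, 7 and 18
#' months of age, two arrays per (genotype, region, age) group.
#'
#' @param genotypes character vector of genotype labels; the second label is
#'   treated as the knockout (effect-carrying) genotype.
#' @param regions character vector of brain-region labels.
#' @param ages character vector of age labels (months).
#' @param arrays_per_group number of arrays per (genotype, region, age)
#'   group; must be at least 2 so a two-group test is defined.
#' @param n_genes number of genes in the simulated universe.
#' @param probes_per_gene integer length-2 vector `c(min, max)`: each gene
#'   receives a uniform draw of probes in this range.
#' @param baseline_log2_mean mean of per-probe baseline log2 intensity.
#' @param baseline_log2_sd between-probe spread of baseline log2 intensity.
#' @param noise_sd_log2 within-group Gaussian noise SD on the log2 scale.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `sim_design` (a validated list).
#' @export
simulation_design <- function(genotypes = c("WT", "KO"),
                              regions = c("cortex", "hippocampus"),
                              ages = c("7", "18"),
                              arrays_per_group = 2L,
                              n_genes = 100L,
                              probes_per_gene = c(1L, 4L),
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 1.5,
                              noise_sd_log2 = 0.15,
                              seed = 1L) {
  if (length(genotypes) != 2L)
    stop("exactly two genotypes (control, knockout) are supported")
  if (arrays_per_group < 2L)
    stop("arrays_per_group must be >= 2: a two-group test needs ",
         "at least two values per group")
  if (n_genes < 0L) stop("n_genes must be non-negative")
  if (length(probes_per_gene) != 2L || probes_per_gene[1] < 1L)
    stop("probes_per_gene must be c(min, max) with min >= 1")
  if (probes_per_gene[2] < probes_per_gene[1])
    stop("probes_per_gene max must be >= min")
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be non-negative")
  structure(
    list(genotypes = as.character(genotypes),
         regions = as.character(regions),
         ages = as.character(ages),
         arrays_per_group = as.integer(arrays_per_group),
         n_genes = as.integer(n_genes),
         probes_per_gene = as.integer(probes_per_gene),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         noise_sd_log2 = noise_sd_log2,
         seed = as.integer(seed)),
    class = "sim_design")
}

#' Planted differential-expression effects
#'
#' @param gene gene identifiers.
#' @param region region label per effect.
#' @param age age label per effect.
#' @param log2_effect log2 expression shift (knockout minus control). A gene
#'   may carry effects of opposite sign at different ages, which is how
#'   contra-regulation is planted.
#' @return data.frame with one row per planted effect.
#' @export
planted_effects <- function(gene = character(), region = character(),
                            age = character(), log2_effect = numeric()) {
  data.frame(gene = as.character(gene), region = as.character(region),
             age = as.character(age), log2_effect = as.numeric(log2_effect),
             stringsAsFactors = FALSE)
}

default_gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a probe-to-gene map
#'
#' Each gene receives a uniform random number of probes in
#' `probes_per_gene = c(min, max)`; probe identifiers are unique and encode
#' their gene of origin (`<gene>_at1`, `<gene>_at2`, ...).
#'
#' @param genes character vector of gene identifiers (may be empty).
#' @param probes_per_gene integer `c(min, max)` with min >= 1.
#' @param seed integer seed.
#' @return data.frame with columns `probe_id`, `gene`.
#' @export
generate_probe_map <- function(genes, probes_per_gene = c(1L, 4L), seed = 1L) {
  if (probes_per_gene[1] < 1L) stop("minimum probes per gene must be >= 1")
  if (length(genes) == 0L)
    return(data.frame(probe_id = character(), gene = character(),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  n_probes <- with_seed(seed, {
    if (probes_per_gene[1] == probes_per_gene[2]) {
      rep(probes_per_gene[1], length(genes))
    } else {
      sample(seq(probes_per_gene[1], probes_per_gene[2]),
             length(genes), replace = TRUE)
    }
  })
  data.frame(
    probe_id = unlist(mapply(function(g, k) sprintf("%s_at%d", g, seq_len(k)),
                             genes, n_probes, SIMPLIFY = FALSE),
                      use.names = FALSE),
    gene = rep(genes, n_probes),
    stringsAsFactors = FALSE)
}

#' Generate a probe-level expression matrix with planted effects
#'
#' Intensities are drawn on the log2 scale as
#' `baseline(probe) + effect(gene, region, age)` (knockout arrays of the
#' matching region and age only) `+ N(0, noise_sd_log2)`, then exponentiated
#' to linear intensities. Identical seeds reproduce identical matrices.
#'
#' @param design a `sim_design`.
#' @param effects data.frame from [planted_effects()] (may be empty).
#' @param probe_map optional probe map; generated from the design when NULL.
#' @return an `expr_matrix` object: list with `intensities` (probes x
#'   arrays matrix, linear scale), `samples` (array sheet with `array_id`,
#'   `genotype`, `region`, `age_months`), and `probe_map`.
#' @export
generate_expression <- function(design, effects = planted_effects(),
                                probe_map = NULL) {
  stopifnot(inherits(design, "sim_design"))
  genes <- default_gene_names(design$n_genes)
  if (is.null(probe_map)) {
    probe_map <- generate_probe_map(genes, design$probes_per_gene,
                                    seed = derive_seed(design$seed, "probe_map"))
  } else {
    genes <- unique(probe_map$gene)
  }
  if (nrow(effects)) {
    bad_gene <- setdiff(effects$gene, genes)
    if (length(bad_gene))
      stop("planted effect references unknown gene(s): ",
           paste(bad_gene, collapse = ", "))
    bad_region <- setdiff(effects$region, design$regions)
    if (length(bad_region))
      stop("planted effect references unknown region(s): ",
           paste(bad_region, collapse = ", "))
    bad_age <- setdiff(effects$age, design$ages)
    if (length(bad_age))
      stop("planted effect references unknown age(s): ",
           paste(bad_age, collapse = ", "))
  }

  groups <- expand.grid(replicate = seq_len(design$arrays_per_group),
                        genotype = design$genotypes, age = design$ages,
                        region = design$regions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    array_id = sprintf("%s_%s_%sm_%d", groups$genotype, groups$region,
                       groups$age, groups$replicate),
    genotype = groups$genotype, region = groups$region,
    age_months = groups$age, stringsAsFactors = FALSE)

  n_probe <- nrow(probe_map)
  n_array <- nrow(samples)
  ko <- design$genotypes[2]

  log2mat <- with_seed(derive_seed(design$seed, "intensities"), {
    baseline <- stats::rnorm(n_probe, design$baseline_log2_mean,
                             design$baseline_log2_sd)
    m <- matrix(baseline, n_probe, n_array)
    if (nrow(effects)) {
      for (i in seq_len(nrow(effects))) {
        rows <- probe_map$gene == effects$gene[i]
        cols <- samples$genotype == ko &
          samples$region == effects$region[i] &
          samples$age_months == effects$age[i]
        m[rows, cols] <- m[rows, cols] + effects$log2_effect[i]
      }
    }
    if (design$noise_sd_log2 > 0)
      m <- m + matrix(stats::rnorm(n_probe * n_array, 0, design$noise_sd_log2),
                      n_probe, n_array)
    m
  })
  intensities <- 2^log2mat
  dimnames(intensities) <- list(probe_map$probe_id, samples$array_id)
  structure(list(intensities = intensities, samples = samples,
                 probe_map = probe_map, design = design, effects = effects),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d arrays (%d genes)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$probe_map$gene))))
  invisible(x)
}

#' Specification for a GO annotation fixture
#'
#' @param term_sizes named integer vector: GO term id -> configured gene-set
#'   size (after qualifier/taxon filtering and is_a expansion).
#' @param redundant_memberships number of gene-in-term memberships beyond
#'   each gene's first, i.e. `sum(term_sizes) - length(union)`. Must not
#'   exceed `sum(term_sizes) - max(term_sizes)`.
#' @param taxon NCBI taxon id written into the GAF (default mouse, 10090).
#' @param qualifier annotation qualifier written into the GAF.
#' @param gene_prefix prefix for invented gene symbols.
#' @param seed integer seed.
#' @return a `go_fixture_spec` list.
#' @export
go_fixture_spec <- function(term_sizes, redundant_memberships = 0L,
                            taxon = "10090", qualifier = "involved_in",
                            gene_prefix = "g", seed = 1L) {
  if (is.null(names(term_sizes)) || any(!nzchar(names(term_sizes))))
    stop("term_sizes must be a named vector of GO ids")
  if (any(term_sizes < 1L)) stop("every term size must be positive")
  bound <- sum(term_sizes) - max(term_sizes)
  if (redundant_memberships > bound)
    stop(sprintf(paste0("unsatisfiable overlap: redundant_memberships (%d) ",
                        "exceeds sum(term_sizes) - max(term_sizes) = %d"),
                 redundant_memberships, bound))
  if (redundant_memberships < 0L)
    stop("redundant_memberships must be non-negative")
  structure(list(term_sizes = term_sizes,
                 redundant_memberships = as.integer(redundant_memberships),
                 taxon = as.character(taxon), qualifier = qualifier,
                 gene_prefix = gene_prefix, seed = as.integer(seed)),
            class = "go_fixture_spec")
}

# Realize per-term gene sets honouring the configured sizes and the exact
# number of redundant (duplicate) memberships. Terms are filled largest
# first; later terms take up to the remaining redundancy budget from genes
# already in earlier terms, then fresh genes.
realize_term_sets <- function(spec) {
  sizes <- sort(spec$term_sizes, decreasing = TRUE)
  union_size <- sum(sizes) - spec$redundant_memberships
  genes <- sprintf("%s%05d", spec$gene_prefix, seq_len(union_size))
  sets <- vector("list", length(sizes))
  names(sets) <- names(sizes)
  used <- character()
  fresh_at <- 1L
  budget <- spec$redundant_memberships
  for (i in seq_along(sizes)) {
    take_old <- min(budget, length(used), sizes[i])
    reused <- if (take_old > 0) used[seq_len(take_old)] else character()
    n_fresh <- sizes[i] - take_old
    fresh <- if (n_fresh > 0) genes[seq(fresh_at, length.out = n_fresh)]
             else character()
    fresh_at <- fresh_at + n_fresh
    budget <- budget - take_old
    sets[[i]] <- c(reused, fresh)
    used <- unique(c(used, sets[[i]]))
  }
  stopifnot(budget == 0L, fresh_at - 1L == union_size)
  # restore the caller's term order
  sets[names(spec$term_sizes)]
}

# Fabricate child-term ids that cannot collide with real GO ids used in
# fixtures (the GO:8xxxxxx block).
child_term_id <- function(counter) sprintf("GO:8%06d", counter)

gaf_line <- function(gene, qualifier, term, taxon, evidence = "IEA") {
  paste(c("SYNDB", gene, gene, qualifier, term, "SYNDB_REF:0000001",
          evidence, "", "P", "", "", "protein", paste0("taxon:", taxon),
          "20170919", "SYNDB", "", ""), collapse = "\t")
}

#' Generate matched GAF and OBO fixtures
#'
#' Emits a GAF 2.2 annotation table and an OBO 1.2 ontology such that
#' parsing the GAF, filtering on the spec's taxon and qualifier, and
#' expanding each configured term through its is_a descendants recovers
#' exactly the configured per-term gene sets. With `ontology_depth > 0` a
#' fraction of memberships is attached to generated child terms, so the
#' expansion step is genuinely required.
#'
#' @param spec a [go_fixture_spec()].
#' @param ontology_depth length of the is_a child chain under each term.
#' @param child_fraction fraction of memberships annotated to a child term
#'   instead of the configured term (only when `ontology_depth > 0`).
#' @param dir optional directory; when given, `annotations.gaf` and
#'   `ontology.obo` are written there.
#' @return list with `gaf_lines`, `obo_lines`, `term_sets` (the realized
#'   ground-truth sets), and `gaf_path`/`obo_path` when `dir` is given.
#' @export
generate_annotations <- function(spec, ontology_depth = 0L,
                                 child_fraction = 0.3, dir = NULL) {
  stopifnot(inherits(spec, "go_fixture_spec"))
  term_sets <- with_seed(derive_seed(spec$seed, "term_sets"),
                         realize_term_sets(spec))
  terms <- names(term_sets)

  # ontology: each configured term gets a chain of ontology_depth children
  obo <- c("format-version: 1.2", "date: 01:01:2020 00:00", "")
  children <- list()  # term -> character vector of its chain, leaf last
  counter <- 0L
  for (t in terms) {
    obo <- c(obo, "[Term]", sprintf("id: %s", t),
             sprintf("name: synthetic term %s", t), "")
    chain <- character()
    parent <- t
    if (ontology_depth > 0L) {
      for (d in seq_len(ontology_depth)) {
        counter <- counter + 1L
        id <- child_term_id(counter)
        obo <- c(obo, "[Term]", sprintf("id: %s", id),
                 sprintf("name: synthetic child %d of %s", d, t),
                 sprintf("is_a: %s ! parent", parent), "")
        chain <- c(chain, id)
        parent <- id
      }
    }
    children[[t]] <- chain
  }

  gaf <- c("!gaf-version: 2.2",
           "! synthetic annotation fixture (npscreen generator)")
  gaf_body <- with_seed(derive_seed(spec$seed, "gaf"), {
    lines <- character()
    for (t in terms) {
      for (g in term_sets[[t]]) {
        target <- t
        chain <- children[[t]]
        if (length(chain) && stats::runif(1) < child_fraction)
          target <- chain[sample.int(length(chain), 1L)]
        lines <- c(lines, gaf_line(g, spec$qualifier, target, spec$taxon))
      }
    }
    lines
  })
  gaf <- c(gaf, gaf_body)

  out <- list(gaf_lines = gaf, obo_lines = obo, term_sets = term_sets)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$gaf_path <- file.path(dir, "annotations.gaf")
    out$obo_path <- file.path(dir, "ontology.obo")
    writeLines(gaf, out$gaf_path)
    writeLines(obo, out$obo_path)
  }
  out
}
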