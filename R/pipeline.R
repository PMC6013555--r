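# Pipeline orchestration: read or simulate inputs, build pools, call DEGs
# per condition, compute disorder statistics and cross-age classes, write
# all reports plus a machine-readable run manifest.

#' Read a probe-level expression matrix and its sample sheet
#'
#' The matrix TSV has the probe id in the first column and one column per
#' array; the sample sheet TSV has columns `array_id`, `genotype`,
#' `region`, `age_months`.
#'
#' @param expression_path path to the matrix TSV.
#' @param samples_path path to the sample sheet TSV.
#' @param probe_map_path path to the two-column probe map TSV
#'   (`probe_id`, `gene`).
#' @param control label of the control genotype; defaults to `"WT"` when
#'   present in the sheet, otherwise the first genotype encountered.
#' @return an `expr_matrix` object.
#' @export
read_expression <- function(expression_path, samples_path, probe_map_path,
                            control = NULL) {
  mat_df <- read_tsv(expression_path)
  samples <- read_tsv(samples_path)
  probe_map <- read_tsv(probe_map_path)
  stopifnot(all(c("array_id", "genotype", "region", "age_months")
                %in% names(samples)))
  names(probe_map)[1:2] <- c("probe_id", "gene")
  samples$age_months <- as.character(samples$age_months)
  intensities <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(intensities) <- mat_df[[1]]
  missing <- setdiff(samples$array_id, colnames(intensities))
  if (length(missing))
    stop("sample sheet array(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  intensities <- intensities[, samples$array_id, drop = FALSE]
  control <- control %||%
    (if ("WT" %in% samples$genotype) "WT" else samples$genotype[1])
  structure(list(intensities = intensities, samples = samples,
                 probe_map = probe_map, control = control),
            class = "expr_matrix")
}

#' Pipeline configuration
#'
#' Exactly one of `preset` and the input paths must be given.
#'
#' @param preset scenario preset name (`"null"`, `"paper_like"`,
#'   `"contra_demo"`), or NULL when paths are supplied.
#' @param expression,samples,probe_map,gaf,obo input file paths (all
#'   required when `preset` is NULL).
#' @param disorder_config_path path to a disorder config TSV, or NULL for
#'   the packaged preset.
#' @param criteria a [deg_criteria()].
#' @param seed integer master seed.
#' @param out output directory.
#' @param overwrite allow writing into a non-empty existing directory.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(preset = NULL, expression = NULL, samples = NULL,
                            probe_map = NULL, gaf = NULL, obo = NULL,
                            disorder_config_path = NULL,
                            criteria = deg_criteria(), seed = 1L,
                            out = NULL, overwrite = FALSE) {
  paths <- list(expression = expression, samples = samples,
                probe_map = probe_map, gaf = gaf, obo = obo)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (is.null(preset) && !all(have_paths))
    stop("either a preset or all five input paths must be given")
  if (!is.null(preset) && any(have_paths))
    stop("give a preset or input paths, not both")
  stopifnot(inherits(criteria, "deg_criteria"))
  structure(list(preset = preset, paths = paths,
                 disorder_config_path = disorder_config_path,
                 criteria = criteria, seed = as.integer(seed), out = out,
                 overwrite = isTRUE(overwrite)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `criteria` may be a
#' mapping with `alpha`, `fc_threshold`, `correction`, `pooled`.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  crit <- do.call(deg_criteria, y$criteria %||% list())
  args <- list(preset = y$preset, expression = y$expression,
               samples = y$samples, probe_map = y$probe_map, gaf = y$gaf,
               obo = y$obo, disorder_config_path = y$disorder_config,
               criteria = crit, seed = y$seed %||% 1L, out = y$out,
               overwrite = y$overwrite %||% FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(pipeline_config, args)
}

#' Validate pipeline input files
#'
#' Non-mutating checks: sample-sheet completeness (every array has
#' genotype, region and age), probe-map coverage of every matrix row, and
#' GAF/OBO parseability. Problems become report rows, never errors.
#'
#' @param paths named list with `expression`, `samples`, `probe_map`,
#'   `gaf`, `obo` file paths.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(paths) {
  checks <- list()
  note <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)

  for (p in names(paths)) {
    ok <- !is.null(paths[[p]]) && file.exists(paths[[p]])
    note(paste0(p, "_exists"), ok, if (ok) "" else paste0(paths[[p]], " missing"))
  }
  if (!all(vapply(checks, function(x) x$pass, logical(1))))
    return(do.call(rbind, checks))

  samples <- tryCatch(read_tsv(paths$samples), error = function(e) NULL)
  if (is.null(samples)) {
    note("sample_sheet_parses", FALSE, "unreadable sample sheet")
  } else {
    note("sample_sheet_parses", TRUE)
    needed <- c("array_id", "genotype", "region", "age_months")
    missing_col <- setdiff(needed, names(samples))
    note("sample_sheet_columns", !length(missing_col),
         paste(missing_col, collapse = ", "))
    if (!length(missing_col)) {
      incomplete <- samples$array_id[
        !stats::complete.cases(samples[needed]) |
          rowSums(samples[needed] == "" | is.na(samples[needed])) > 0]
      note("sample_sheet_complete", !length(incomplete),
           if (length(incomplete))
             paste("missing values for array(s):",
                   paste(incomplete, collapse = ", ")) else "")
    }
  }

  mat <- tryCatch(read_tsv(paths$expression), error = function(e) NULL)
  probe_map <- tryCatch(read_tsv(paths$probe_map), error = function(e) NULL)
  note("expression_parses", !is.null(mat))
  note("probe_map_parses", !is.null(probe_map))
  if (!is.null(mat) && !is.null(probe_map)) {
    unmapped <- setdiff(mat[[1]], probe_map[[1]])
    note("probe_map_covers_matrix", !length(unmapped),
         if (length(unmapped))
           paste("unmapped probe(s):",
                 paste(utils::head(unmapped, 5), collapse = ", "),
                 if (length(unmapped) > 5) "..." else "") else "")
  }
  if (!is.null(mat) && !is.null(samples) && "array_id" %in% names(samples)) {
    absent <- setdiff(samples$array_id, names(mat)[-1])
    note("matrix_covers_sample_sheet", !length(absent),
         paste(absent, collapse = ", "))
  }

  gaf <- tryCatch(parse_gaf(paths$gaf, quiet = TRUE),
                  error = function(e) NULL)
  note("gaf_parses", !is.null(gaf) && nrow(gaf) > 0,
       if (is.null(gaf)) "unreadable" else if (!nrow(gaf)) "no records" else "")
  obo <- tryCatch(parse_obo(paths$obo, quiet = TRUE),
                  error = function(e) NULL)
  note("obo_parses", !is.null(obo) && length(obo$terms) > 0,
       if (is.null(obo)) "unreadable" else "")
  do.call(rbind, checks)
}

#' Run the full screening pipeline
#'
#' Stages: load or simulate inputs; parse and filter annotations; build
#' per-term gene sets and disorder pools; per (region, age) condition call
#' probe-level DEGs, collapse to genes, and correct p-values across the
#' GO-pool probes; compute per-term/per-disorder statistics and rankings;
#' classify cross-age behaviour per disorder and region. Writes all reports
#' as TSV plus `manifest.json`; identical config and seed give identical
#' outputs. Any stage failure aborts with a stage-named error and removes
#' partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; reports under `config$out`
#'   when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out
  created <- FALSE
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) && !config$overwrite)
      stop("output directory not empty (use overwrite): ", out_dir)
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      created <- TRUE
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        if (created) unlink(out_dir, recursive = TRUE)
        else unlink(dir(out_dir, full.names = TRUE), recursive = TRUE)
      }
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage: inputs ---------------------------------------------------------
  inputs <- run_stage("inputs", {
    if (!is.null(config$preset)) {
      bundle <- generate_scenario(config$preset, seed = config$seed)
      list(expr = bundle$expression,
           gaf = parse_gaf(bundle$annotations$gaf_lines, quiet = TRUE),
           graph = parse_obo(bundle$annotations$obo_lines, quiet = TRUE),
           cfg = bundle$disorder_config, truth = bundle$truth)
    } else {
      p <- config$paths
      list(expr = read_expression(p$expression, p$samples, p$probe_map),
           gaf = parse_gaf(p$gaf),
           graph = parse_obo(p$obo),
           cfg = disorder_config(config$disorder_config_path),
           truth = NULL)
    }
  })

  # -- stage: pools ----------------------------------------------------------
  pools_out <- run_stage("pools", {
    filtered <- filter_annotations(inputs$gaf)
    term_sets <- build_term_gene_sets(filtered, inputs$graph,
                                      unique(inputs$cfg$term))
    pools <- lapply(split(inputs$cfg, inputs$cfg$disorder), function(sub)
      build_disorder_pool(term_sets, sub))
    # keep config order (BIP, SCZ, MDD under the packaged preset)
    pools <- pools[unique(inputs$cfg$disorder)]
    list(filtered = filtered, term_sets = term_sets, pools = pools,
         report = pool_report(pools, inputs$cfg))
  })

  all_pool_genes <- sort(unique(unlist(lapply(pools_out$pools,
                                              function(p) p$union))))
  conditions <- condition_grid(
    regions = unique(inputs$expr$samples$region),
    ages = unique(inputs$expr$samples$age_months))

  # -- stage: deg ------------------------------------------------------------
  deg_out <- run_stage("deg", {
    probe_map <- inputs$expr$probe_map
    pool_probes <- probe_map$probe_id[probe_map$gene %in% all_pool_genes]
    gene_records <- list()
    pool_records <- list()
    for (i in seq_len(nrow(conditions))) {
      region <- conditions$region[i]; age <- conditions$age[i]
      probe_recs <- call_degs(inputs$expr, region, age, config$criteria)
      genes <- collapse_probes(probe_recs, probe_map)
      # correction scope: the GO-filtered probe pool within this condition
      pool_recs <- probe_recs[probe_recs$probe %in% pool_probes, ,
                              drop = FALSE]
      pool_genes <- collapse_probes(pool_recs, probe_map)
      pool_genes <- add_corrected_pvalues(pool_genes, config$criteria)
      key <- paste(region, age, sep = "_")
      gene_records[[key]] <- genes
      pool_records[[key]] <- pool_genes
    }
    list(gene_records = gene_records, pool_records = pool_records,
         n_pool_probes = length(pool_probes))
  })

  # -- stage: stats ----------------------------------------------------------
  stats_out <- run_stage("stats", {
    deg_by_condition <- lapply(deg_out$pool_records,
                               function(r) r$gene[r$significant])
    n_total <- vapply(deg_out$gene_records,
                      function(r) sum(r$significant), integer(1))
    n_total <- pmax(n_total, 1L)  # degenerate all-null runs keep shares at 0
    stat_table <- disorder_stat_table(deg_by_condition, pools_out$pools,
                                      n_total, conditions)
    totals <- list(); rankings <- list()
    for (i in seq_len(nrow(conditions))) {
      key <- paste(conditions$region[i], conditions$age[i], sep = "_")
      tot <- do.call(rbind, lapply(pools_out$pools, function(p)
        disorder_totals(deg_by_condition[[key]], p, n_total[[key]],
                        conditions$region[i], conditions$age[i])))
      rownames(tot) <- NULL
      totals[[key]] <- tot
      rk <- rank_disorders(tot, by = "number")
      rkp <- rank_disorders(tot, by = "percentage")
      rankings[[key]] <- data.frame(
        region = conditions$region[i], age = conditions$age[i],
        by = c("number", "percentage"),
        order = c(paste(rk$order, collapse = " > "),
                  paste(rkp$order, collapse = " > ")),
        winner = c(rk$winner, rkp$winner), stringsAsFactors = FALSE)
    }
    list(stat_table = stat_table, grid = stats_grid(stat_table),
         totals = do.call(rbind, totals),
         rankings = do.call(rbind, rankings), n_total_degs = n_total)
  })

  # -- stage: crossage -------------------------------------------------------
  crossage_out <- run_stage("crossage", {
    regions <- unique(conditions$region)
    ages <- unique(conditions$age)
    results <- list(); grids <- list(); counts <- list()
    for (d in names(pools_out$pools)) {
      per_region <- list()
      for (region in regions) {
        res <- find_common_genes(
          deg_out$pool_records[[paste(region, ages[1], sep = "_")]],
          deg_out$pool_records[[paste(region, ages[2], sep = "_")]],
          pools_out$pools[[d]], region)
        per_region[[region]] <- res
        counts[[paste(d, region)]] <- venn_direction_counts(res)
      }
      results[[d]] <- per_region
      if (length(regions) == 2L)
        grids[[d]] <- common_gene_grid(per_region)
    }
    list(results = results, grids = do.call(rbind, grids),
         counts = do.call(rbind, counts))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("npscreen")),
    preset = config$preset %||% "user_data",
    seed = config$seed,
    criteria = unclass(config$criteria),
    counts = list(
      probes_in = nrow(inputs$expr$intensities),
      probes_after_go_filter = deg_out$n_pool_probes,
      pool_genes = length(all_pool_genes),
      genes_after_collapse = nrow(deg_out$pool_records[[1]]),
      degs_per_condition = lapply(deg_out$pool_records,
                                  function(r) sum(r$significant)),
      total_degs_per_condition = as.list(stats_out$n_total_degs),
      planted_degs = if (!is.null(inputs$truth)) nrow(inputs$truth) else NA),
    term_slots = attr(pools_out$report, "term_slots"),
    distinct_terms = attr(pools_out$report, "distinct_terms"),
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(manifest = manifest, pool_report = pools_out$report,
                 pools = pools_out$pools, deg = deg_out$pool_records,
                 stat_table = stats_out$stat_table,
                 stats_grid = stats_out$grid, totals = stats_out$totals,
                 rankings = stats_out$rankings,
                 crossage = crossage_out$results,
                 common_gene_grid = crossage_out$grids,
                 venn_counts = crossage_out$counts,
                 truth = inputs$truth)

  if (!is.null(out_dir)) run_stage("write", {
    write_tsv(pools_out$report, file.path(out_dir, "pool_report.tsv"))
    for (key in names(deg_out$pool_records))
      write_tsv(deg_out$pool_records[[key]],
                file.path(out_dir, sprintf("deg_%sm.tsv", key)))
    write_tsv(stats_out$stat_table, file.path(out_dir, "term_stats.tsv"))
    write_tsv(stats_out$grid, file.path(out_dir, "stats_grid.tsv"))
    write_tsv(stats_out$totals, file.path(out_dir, "disorder_totals.tsv"))
    write_tsv(stats_out$rankings, file.path(out_dir, "rankings.tsv"))
    if (!is.null(crossage_out$counts) && nrow(crossage_out$counts))
      write_tsv(crossage_out$counts, file.path(out_dir, "venn_counts.tsv"))
    if (!is.null(crossage_out$grids) && NROW(crossage_out$grids))
      write_tsv(crossage_out$grids, file.path(out_dir, "common_genes.tsv"))
    if (!is.null(inputs$truth))
      write_tsv(inputs$truth, file.path(out_dir, "ground_truth_degs.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(result)
}
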