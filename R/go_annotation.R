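# GO annotation handling: GAF 2.2 parsing, qualifier/taxon filtering,
# is_a descendant expansion over an OBO-derived term graph, and construction
# of per-disorder gene pools.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"

# Qualifiers retained when screening annotations (GAF 2.2 vocabulary).
#' @export
DEFAULT_QUALIFIERS <- c("part_of", "involved_in", "enables",
                        "contributes_to", "colocalizes_with")

#' Parse a GAF 2.2 annotation stream
#'
#' Reads tab-separated GAF text. Lines starting with `!` are comments.
#' Column mapping follows GAF 2.2: gene symbol from column 3, qualifiers
#' from column 4 (split on `|`), GO id from column 5, evidence from column
#' 7, taxon from column 13 (`taxon:NNNN`, first id if interacting taxa are
#' listed). Malformed lines (fewer than 13 columns or a non-GO id) are
#' reported with their line number and skipped; they are never fatal.
#'
#' @param source path to a GAF file, or a character vector of lines.
#' @param quiet suppress the malformed-line report.
#' @return data.frame of annotation records with columns `gene`, `term`,
#'   `qualifiers` (`|`-joined), `taxon`, `evidence`.
#' @export
parse_gaf <- function(source, quiet = FALSE) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  empty <- data.frame(gene = character(), term = character(),
                      qualifiers = character(), taxon = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  line_no <- which(keep)
  if (!length(line_no)) return(empty)
  fields <- strsplit(lines[line_no], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  ok <- n_col >= 13L
  go_ok <- rep(FALSE, length(fields))
  go_ok[ok] <- grepl(GO_ID_PATTERN, vapply(fields[ok], `[`, "", 5L))
  bad <- which(!(ok & go_ok))
  if (length(bad) && !quiet)
    message("parse_gaf: skipped ", length(bad), " malformed line(s): ",
            paste(line_no[bad], collapse = ", "))
  fields <- fields[ok & go_ok]
  if (!length(fields)) return(empty)
  taxa <- vapply(fields, `[`, "", 13L)
  taxa <- sub("^taxon:", "", vapply(strsplit(taxa, "|", fixed = TRUE),
                                    `[`, "", 1L))
  data.frame(gene = vapply(fields, `[`, "", 3L),
             term = vapply(fields, `[`, "", 5L),
             qualifiers = vapply(fields, `[`, "", 4L),
             taxon = taxa,
             evidence = vapply(fields, `[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Serialize annotation records back to GAF 2.2 lines
#'
#' Inverse of [parse_gaf()] up to the columns the records carry; the
#' round trip parse -> serialize -> parse is the identity on records.
#'
#' @param records annotation records from [parse_gaf()].
#' @return character vector of GAF lines (with header comment).
#' @export
write_gaf <- function(records) {
  c("!gaf-version: 2.2",
    vapply(seq_len(nrow(records)), function(i)
      gaf_line(records$gene[i], records$qualifiers[i], records$term[i],
               records$taxon[i], records$evidence[i]), character(1)))
}

split_qualifiers <- function(q) strsplit(q, "|", fixed = TRUE)

#' Filter annotation records by taxon and qualifier
#'
#' A record is kept when its taxon matches, it carries no `NOT` qualifier,
#' and at least one of its qualifiers is in the allowed set. Records with an
#' empty qualifier cell are dropped. Input order is preserved; the filter is
#' idempotent.
#'
#' @param records annotation records.
#' @param taxon taxon id to keep (default mouse, `"10090"`).
#' @param allowed_qualifiers allowed qualifier labels (non-empty).
#' @return the surviving records.
#' @export
filter_annotations <- function(records, taxon = "10090",
                               allowed_qualifiers = DEFAULT_QUALIFIERS) {
  if (!length(allowed_qualifiers))
    stop("allowed_qualifiers must be non-empty")
  if (!nrow(records)) return(records)
  quals <- split_qualifiers(records$qualifiers)
  keep <- records$taxon == taxon &
    !vapply(quals, function(q) "NOT" %in% q, logical(1)) &
    vapply(quals, function(q) any(q %in% allowed_qualifiers), logical(1))
  records[keep, , drop = FALSE]
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, keeping `id:` and `is_a:` tags. `relationship:
#' part_of` lines are parsed but deliberately not traversed (descendant
#' expansion follows is_a only); a notice is emitted when any are present.
#' Other tags are ignored.
#'
#' @param source path to an OBO file, or a character vector of lines.
#' @param quiet suppress the part_of notice.
#' @return an `ontology_graph`: list with `terms` (character) and `edges`
#'   (data.frame `child`, `parent` of is_a pairs).
#' @export
parse_obo <- function(source, quiet = FALSE) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  terms <- character()
  child <- parent <- character()
  cur <- NA_character_
  in_term <- FALSE
  n_part_of <- 0L
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (startsWith(ln, "is_a:") && !is.na(cur)) {
      child <- c(child, cur)
      parent <- c(parent, trimws(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      n_part_of <- n_part_of + 1L
    }
  }
  if (n_part_of > 0L && !quiet)
    message("parse_obo: ", n_part_of,
            " part_of relationship(s) parsed but not traversed ",
            "(descendant expansion follows is_a edges only)")
  ontology_graph(terms = unique(c(terms, child, parent)),
                 edges = data.frame(child = child, parent = parent,
                                    stringsAsFactors = FALSE))
}

#' Construct an ontology term graph
#'
#' @param terms character vector of term ids.
#' @param edges data.frame with columns `child`, `parent` (is_a pairs);
#'   every endpoint must appear in `terms` and the graph must be acyclic.
#' @return an `ontology_graph` list.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  missing <- setdiff(c(edges$child, edges$parent), terms)
  if (length(missing))
    stop("edge endpoint(s) not in term set: ", paste(missing, collapse = ", "))
  g <- structure(list(terms = as.character(terms),
                      edges = data.frame(child = as.character(edges$child),
                                         parent = as.character(edges$parent),
                                         stringsAsFactors = FALSE)),
                 class = "ontology_graph")
  if (has_cycle(g)) stop("is_a graph contains a cycle")
  g
}

# Kahn-style cycle check on the is_a digraph.
has_cycle <- function(graph) {
  edges <- graph$edges
  if (!nrow(edges)) return(FALSE)
  nodes <- graph$terms
  indeg <- table(factor(edges$parent, levels = nodes))
  active <- rep(TRUE, nrow(edges))
  queue <- nodes[indeg == 0]
  removed <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    removed <- removed + 1L
    out <- which(active & edges$child == n)
    for (e in out) {
      active[e] <- FALSE
      p <- edges$parent[e]
      if (!any(active & edges$parent == p)) queue <- c(queue, p)
    }
  }
  removed < length(nodes)
}

#' Expand a term to itself plus all is_a descendants
#'
#' Returns the term together with every term whose transitive is_a closure
#' reaches it, i.e. all descendants. Annotations made to any member of this
#' set count toward the term's gene set.
#'
#' @param graph an `ontology_graph`.
#' @param term a term id present in the graph.
#' @return character vector of term ids (no duplicates; includes `term`).
#' @export
expand_term <- function(graph, term) {
  if (!term %in% graph$terms) stop("unknown ontology term: ", term)
  out <- term
  frontier <- term
  while (length(frontier)) {
    kids <- graph$edges$child[graph$edges$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  unique(out)
}

#' Build per-term gene sets from filtered annotations
#'
#' Gene `g` belongs to term `t`'s set iff some record annotates `g` to any
#' member of `expand_term(graph, t)`. Duplicate annotations (e.g. different
#' evidence codes) collapse to a single membership.
#'
#' @param records filtered annotation records.
#' @param graph an `ontology_graph`.
#' @param terms term ids to build sets for; all must be in the graph.
#' @return named list: term id -> sorted character vector of gene symbols.
#' @export
build_term_gene_sets <- function(records, graph, terms) {
  missing <- setdiff(terms, graph$terms)
  if (length(missing))
    stop("term(s) absent from ontology graph: ",
         paste(missing, collapse = ", "))
  sets <- lapply(terms, function(t) {
    members <- expand_term(graph, t)
    sort(unique(records$gene[records$term %in% members]))
  })
  names(sets) <- terms
  sets
}

#' The packaged disorder-to-GO-term configuration
#'
#' Loads the preset mapping of BIP, SCZ and MDD to the GO terms enriched
#' with their susceptibility alleles in the Psychiatric Genomics Consortium
#' pathway analysis: 4 terms for BIP, 5 for SCZ, 5 for MDD. Histone H3-K4
#' methylation (GO:0051568) is assigned to both BIP and SCZ, so the 14
#' term slots cover 13 distinct terms.
#'
#' @param path optional path to a custom three-column TSV (`disorder`,
#'   `term`, `name`); default loads the packaged preset.
#' @return data.frame with columns `disorder`, `term`, `name`.
#' @export
disorder_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "disorder_terms.tsv",
                                package = "npscreen", mustWork = TRUE)
  cfg <- read_tsv(path)
  stopifnot(all(c("disorder", "term", "name") %in% names(cfg)))
  bad <- cfg$term[!grepl(GO_ID_PATTERN, cfg$term)]
  if (length(bad))
    stop("malformed GO id(s) in disorder config: ", paste(bad, collapse = ", "))
  cfg
}

#' Assemble one disorder's gene pool
#'
#' The pool is the deduplicated union of the gene sets of the disorder's
#' configured terms; `redundant_memberships` counts memberships beyond each
#' gene's first (`sum of set sizes - union size`), the parenthesized overlap
#' accounting used in pool-size reports.
#'
#' @param term_sets named list of gene sets (term id -> genes).
#' @param config disorder config rows for a single disorder.
#' @return a `disorder_pool`: list with `disorder`, `term_sets` (this
#'   disorder's terms only), `union`, `redundant_memberships`.
#' @export
build_disorder_pool <- function(term_sets, config) {
  disorder <- unique(config$disorder)
  stopifnot(length(disorder) == 1L)
  missing <- setdiff(config$term, names(term_sets))
  if (length(missing))
    stop("term(s) missing from term_sets: ", paste(missing, collapse = ", "))
  sets <- term_sets[config$term]
  pool_union <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(disorder = disorder, term_sets = sets, union = pool_union,
                 redundant_memberships =
                   sum(lengths(sets)) - length(pool_union)),
            class = "disorder_pool")
}

#' @export
print.disorder_pool <- function(x, ...) {
  cat(sprintf("disorder_pool %s: %d terms, union %d genes (%d redundant memberships)\n",
              x$disorder, length(x$term_sets), length(x$union),
              x$redundant_memberships))
  invisible(x)
}

#' Summarize disorder pools (pool-size report)
#'
#' One row per (disorder, term) with the term's set size, plus a `Total` row
#' per disorder giving the union size and the redundant-membership count.
#' The report also surfaces the slot vs distinct-term accounting (14 slots /
#' 13 distinct terms under the packaged preset).
#'
#' @param pools list of `disorder_pool` objects.
#' @param config the disorder config used to build them.
#' @return data.frame pool report.
#' @export
pool_report <- function(pools, config) {
  rows <- lapply(pools, function(p) {
    terms <- names(p$term_sets)
    nm <- config$name[match(terms, config$term)]
    rbind(
      data.frame(disorder = p$disorder, term = terms, name = nm,
                 n_genes = lengths(p$term_sets, use.names = FALSE),
                 redundant_memberships = NA_integer_,
                 stringsAsFactors = FALSE),
      data.frame(disorder = p$disorder, term = "Total", name = "Total",
                 n_genes = length(p$union),
                 redundant_memberships = p$redundant_memberships,
                 stringsAsFactors = FALSE))
  })
  report <- do.call(rbind, rows)
  attr(report, "term_slots") <- nrow(config)
  attr(report, "distinct_terms") <- length(unique(config$term))
  report
}
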