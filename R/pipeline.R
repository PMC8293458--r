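#' Pipeline run configuration
#'
#' Collects the inputs, output location and tunable parameters of the
#' full analysis. Defaults reproduce the standard settings of the
#' analysis the package implements: minimum keyword frequency 5,
#' keyword cap 1000, top-10 and top-20 tables, doubled co-occurrence
#' weights and mention-count bipartite weights, Louvain seed 0 at
#' resolution 1.
#'
#' @param annotation_file PubTator annotation file path.
#' @param citation_file MEDLINE citation file path (or a vector of
#'   paths, merged with PMID deduplication).
#' @param subheading_dir Directory of plain-text PMID list files (one
#'   per subheading), or `NULL` to skip the intersection analysis.
#' @param out_dir Output directory for all artifacts.
#' @param min_keyword_freq Minimum keyword frequency (default 5).
#' @param keyword_top_n Keyword cap (default 1000).
#' @param table_top_n Rows in the top-gene table (default 10).
#' @param keyword_table_top_n Rows in the keyword frequency CSV
#'   (default 20).
#' @param doubled_weights Doubled co-occurrence convention (default
#'   `TRUE`).
#' @param mention_count_weights Mention-count bipartite weights
#'   (default `TRUE`).
#' @param community_seed,community_resolution Louvain parameters.
#' @param neighborhood_nodes Optional node ids for a key-node
#'   neighborhood subgraph (e.g. top genes plus a disease hub).
#' @return A `run_config` list.
#' @export
run_config <- function(annotation_file, citation_file = NULL,
                       subheading_dir = NULL, out_dir = "litcooc_out",
                       min_keyword_freq = 5, keyword_top_n = 1000,
                       table_top_n = 10, keyword_table_top_n = 20,
                       doubled_weights = TRUE, mention_count_weights = TRUE,
                       community_seed = 0, community_resolution = 1,
                       neighborhood_nodes = NULL) {
  structure(list(
    annotation_file = annotation_file, citation_file = citation_file,
    subheading_dir = subheading_dir, out_dir = out_dir,
    min_keyword_freq = min_keyword_freq, keyword_top_n = keyword_top_n,
    table_top_n = table_top_n, keyword_table_top_n = keyword_table_top_n,
    doubled_weights = doubled_weights,
    mention_count_weights = mention_count_weights,
    community_seed = community_seed,
    community_resolution = community_resolution,
    neighborhood_nodes = neighborhood_nodes
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full literature-mining pipeline
#'
#' Executes every stage on the configured inputs and writes the
#' artifacts into the output directory: per-class bioconcept
#' statistics, year/journal/keyword frequency tables, the exclusive
#' intersection profile (CSV + plot), the document-bioconcept
#' bipartite and bioconcept co-occurrence graphs (GraphML + summary),
#' the gene-gene subgraph with its top-gene table, and optionally a
#' key-node neighborhood subgraph. Returns a report tibble listing
#' each artifact with its row/node/edge counts.
#'
#' @param config A [run_config()].
#' @return Tibble report (`artifact`, `path`, `rows`, `nodes`,
#'   `edges`), plus attribute `warnings` with parse bookkeeping.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$annotation_file)) {
    stop("pipeline stage 'parse_annotations' failed: input not found: ",
         config$annotation_file, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  note <- function(artifact, path, rows = NA, nodes = NA, edges = NA) {
    report[[length(report) + 1L]] <<- tibble(
      artifact = artifact, path = path,
      rows = as.integer(rows), nodes = as.integer(nodes),
      edges = as.integer(edges))
  }
  out <- function(f) file.path(config$out_dir, f)
  bookkeeping <- list()

  docs <- stage("parse_annotations", parse_pubtator(config$annotation_file))
  stats_tbl <- stage("concept_stats", concept_stats(docs))
  write.csv(stats_tbl, out("bioconcept_stats.csv"), row.names = FALSE)
  note("bioconcept_stats", out("bioconcept_stats.csv"), rows = nrow(stats_tbl))

  if (!is.null(config$citation_file)) {
    cites <- stage("parse_citations",
                   merge_citation_files(as.list(config$citation_file)))
    bookkeeping$citation_skipped <- attr(cites, "skipped")
    bookkeeping$citation_duplicates <- attr(cites, "duplicates")
    yrs <- year_counts(cites)
    write.csv(yrs, out("year_counts.csv"), row.names = FALSE)
    note("year_counts", out("year_counts.csv"), rows = nrow(yrs))
    jnl <- journal_counts(cites)
    write.csv(jnl, out("journal_counts.csv"), row.names = FALSE)
    note("journal_counts", out("journal_counts.csv"), rows = nrow(jnl))
    kw <- keyword_frequencies(cites, config$min_keyword_freq,
                              config$keyword_top_n)
    write.csv(head(kw, config$keyword_table_top_n),
              out("keyword_frequencies.csv"), row.names = FALSE)
    note("keyword_frequencies", out("keyword_frequencies.csv"),
         rows = min(nrow(kw), config$keyword_table_top_n))
    kg <- keyword_cooccurrence(cites, config$min_keyword_freq,
                               config$keyword_top_n)
    export_graph(kg, out("keyword_cooccurrence.graphml"), "graphml")
    note("keyword_cooccurrence", out("keyword_cooccurrence.graphml"),
         nodes = igraph::vcount(kg), edges = igraph::ecount(kg))
  }

  if (!is.null(config$subheading_dir)) {
    paths <- list.files(config$subheading_dir, full.names = TRUE)
    sets <- stage("subheading_lists", read_pmid_lists(paths))
    m <- stage("membership_matrix", build_membership_matrix(sets))
    ints <- exclusive_intersections(m)
    ints_out <- ints[, c("combination", "degree", "count")]
    write.csv(ints_out, out("exclusive_intersections.csv"), row.names = FALSE)
    note("exclusive_intersections", out("exclusive_intersections.csv"),
         rows = nrow(ints_out))
    pairs <- inclusive_pair_counts(m)
    write.csv(pairs, out("inclusive_pair_counts.csv"), row.names = FALSE)
    note("inclusive_pair_counts", out("inclusive_pair_counts.csv"),
         rows = nrow(pairs))
    writeLines(nonparticipating_sets(m), out("nonparticipating_sets.txt"))
    p <- plot_intersections(m)
    ggplot2::ggsave(out("intersections_upset.png"), p,
                    width = 9, height = 6, dpi = 120)
    note("intersections_plot", out("intersections_upset.png"))
  }

  bip <- stage("bipartite_graph",
               build_bipartite(docs, config$mention_count_weights))
  export_graph(bip, out("pmid_bioconcept.graphml"), "graphml")
  note("pmid_bioconcept_graph", out("pmid_bioconcept.graphml"),
       nodes = igraph::vcount(bip), edges = igraph::ecount(bip))

  coo <- stage("cooccurrence_graph",
               build_cooccurrence(docs, config$doubled_weights))
  export_graph(coo, out("bioconcept_cooccurrence.graphml"), "graphml")
  note("bioconcept_cooccurrence_graph", out("bioconcept_cooccurrence.graphml"),
       nodes = igraph::vcount(coo), edges = igraph::ecount(coo))

  gene <- stage("gene_subgraph", class_subgraph(coo, "Gene"))
  export_graph(gene, out("gene_gene.graphml"), "graphml")
  note("gene_gene_graph", out("gene_gene.graphml"),
       nodes = igraph::vcount(gene), edges = igraph::ecount(gene))

  summaries <- dplyr::bind_rows(lapply(
    list(pmid_bioconcept = bip, bioconcept_cooccurrence = coo,
         gene_gene = gene),
    function(g) {
      if (igraph::vcount(g) == 0L) return(NULL)
      graph_summary(g, config$community_seed, config$community_resolution)
    }), .id = "graph")
  write.csv(summaries, out("graph_summaries.csv"), row.names = FALSE)
  note("graph_summaries", out("graph_summaries.csv"), rows = nrow(summaries))

  if (igraph::vcount(gene) > 0L) {
    top <- degree_table(gene, config$table_top_n)
    write.csv(top, out("top_genes.csv"), row.names = FALSE)
    note("top_genes", out("top_genes.csv"), rows = nrow(top))
  }

  if (!is.null(config$neighborhood_nodes)) {
    nb <- stage("neighborhood_subgraph",
                suppressWarnings(
                  neighborhood_subgraph(coo, config$neighborhood_nodes)))
    export_graph(nb, out("neighborhood.graphml"), "graphml")
    note("neighborhood_graph", out("neighborhood.graphml"),
         nodes = igraph::vcount(nb), edges = igraph::ecount(nb))
    bookkeeping$neighborhood_missing <- attr(nb, "missing")
  }

  rep_tbl <- dplyr::bind_rows(report)
  attr(rep_tbl, "warnings") <- bookkeeping
  rep_tbl
}
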