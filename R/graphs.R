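#' Per-document bioconcept mention counts
#'
#' The shared kernel of both graph builders: tallies, for one
#' document, how many times each ID-bearing bioconcept is mentioned.
#' ID-less mentions are excluded — without an identifier, identity
#' across documents is undefined, so such mentions can never become
#' graph nodes.
#'
#' @param doc An [annotated_document].
#' @return Named integer vector: canonical key -> mention count.
#' @export
document_concepts <- function(doc) {
  ann <- doc$annotations
  keys <- ann$canonical[!is.na(ann$canonical)]
  if (length(keys) == 0L) return(setNames(integer(), character()))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

# canonical key -> class lookup across a corpus
corpus_key_classes <- function(docs) {
  ann <- corpus_annotations(docs)
  ann <- ann[!is.na(ann$canonical), c("canonical", "class")]
  ann <- ann[!duplicated(ann$canonical), ]
  setNames(ann$class, ann$canonical)
}

# sparse binary docs x keys incidence and mention-count matrices
corpus_incidence <- function(docs) {
  per_doc <- lapply(docs, document_concepts)
  nz <- lengths(per_doc) > 0L
  per_doc <- per_doc[nz]
  pmids <- vapply(docs[nz], function(d) d$pmid, character(1))
  keys <- sort(unique(unlist(lapply(per_doc, names), use.names = FALSE)))
  if (length(keys) == 0L) {
    return(list(pmids = character(), keys = character(),
                counts = Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(), dims = c(0L, 0L))))
  }
  i <- rep.int(seq_along(per_doc), lengths(per_doc))
  j <- match(unlist(lapply(per_doc, names), use.names = FALSE), keys)
  x <- unlist(per_doc, use.names = FALSE)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                                 dims = c(length(per_doc), length(keys)),
                                 dimnames = list(pmids, keys))
  list(pmids = pmids, keys = keys, counts = counts)
}

#' Document-bioconcept bipartite graph
#'
#' Builds the two-mode graph linking articles to the bioconcepts
#' annotated in them. Nodes are PMIDs with at least one ID-bearing
#' annotation plus their concept keys; the edge between a PMID and a
#' concept is weighted by the mention count (default) or 1 when
#' `mention_counts = FALSE`. Documents contributing no ID-bearing
#' annotation yield no node. With mention-count weights the average
#' weighted degree exceeds the average degree whenever concepts are
#' mentioned repeatedly, as observed in real annotated corpora.
#'
#' @param docs List of [annotated_document] objects.
#' @param mention_counts Weight edges by the number of mentions
#'   (default `TRUE`); `FALSE` gives binary 0/1 weights.
#' @return An `igraph` graph; vertices carry `kind` ("pmid" or
#'   "bioconcept") and `concept_class` (`NA` for PMID nodes), edges
#'   carry integer `weight`.
#' @export
build_bipartite <- function(docs, mention_counts = TRUE) {
  inc <- corpus_incidence(docs)
  cls <- corpus_key_classes(docs)
  sm <- methods::as(inc$counts, "TsparseMatrix")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(inc$pmids) + length(inc$keys),
    name = c(inc$pmids, inc$keys),
    kind = c(rep("pmid", length(inc$pmids)), rep("bioconcept", length(inc$keys))),
    concept_class = c(rep(NA_character_, length(inc$pmids)),
                      unname(cls[inc$keys]))
  )
  if (length(sm@i)) {
    ends <- rbind(inc$pmids[sm@i + 1L], inc$keys[sm@j + 1L])
    w <- if (mention_counts) as.integer(sm@x) else rep(1L, length(sm@x))
    g <- igraph::add_edges(g, ends, weight = w)
  }
  g
}

#' Bioconcept-bioconcept co-occurrence graph
#'
#' Builds the one-mode co-occurrence network over all ID-bearing
#' bioconcept keys. For each document, every unordered pair of
#' distinct concepts present contributes +2 to that pair's edge weight
#' (equivalently, both directed edges are created and parallel edges
#' merged by summing), so edge weight = 2 x the number of documents
#' containing both concepts. A pair sharing 32 articles therefore has
#' weight 64, a pair sharing one article weight 2, and every node has
#' even weighted degree with minimum 2. Within-document mention
#' multiplicity does not inflate the weight: a document mentioning A
#' three times and B twice still contributes +2 to the A-B edge.
#'
#' @param docs List of [annotated_document] objects.
#' @param doubled Use the doubled per-document contribution (default
#'   `TRUE`, the convention all summaries assume); `FALSE` gives plain
#'   shared-document counts.
#' @return An `igraph` graph; vertices carry `kind = "bioconcept"` and
#'   `concept_class`, edges carry integer `weight`.
#' @export
build_cooccurrence <- function(docs, doubled = TRUE) {
  inc <- corpus_incidence(docs)
  cls <- corpus_key_classes(docs)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(inc$keys), name = inc$keys,
                            kind = "bioconcept",
                            concept_class = unname(cls[inc$keys]))
  if (length(inc$keys) >= 2L) {
    b <- inc$counts
    b@x[] <- 1
    shared <- Matrix::crossprod(b)  # keys x keys shared-document counts
    shared <- Matrix::triu(shared, k = 1L)
    sm <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
    keep <- sm@x > 0
    if (any(keep)) {
      ends <- rbind(inc$keys[sm@i[keep] + 1L], inc$keys[sm@j[keep] + 1L])
      w <- as.integer(sm@x[keep]) * (if (doubled) 2L else 1L)
      g <- igraph::add_edges(g, ends, weight = w)
    }
  }
  g
}

#' Class-induced subgraph
#'
#' Restricts a bioconcept graph to the nodes of one class (e.g. the
#' gene-gene network extracted from the full co-occurrence network),
#' preserving edge weights.
#'
#' @param graph Bioconcept `igraph` graph with a `concept_class`
#'   vertex attribute.
#' @param concept_class One of [bioconcept_classes].
#' @return Induced `igraph` subgraph.
#' @export
class_subgraph <- function(graph, concept_class) {
  if (!concept_class %in% bioconcept_classes) {
    stop("unknown bioconcept class: ", concept_class, call. = FALSE)
  }
  cls <- igraph::V(graph)$concept_class
  keep <- which(!is.na(cls) & cls == concept_class)
  igraph::induced_subgraph(graph, keep)
}

#' Neighborhood subgraph on selected nodes
#'
#' Induced subgraph on exactly the listed node identifiers — e.g. the
#' top genes plus a key disease node, to inspect their mutual
#' associations. Identifiers absent from the graph are reported in
#' `attr(result, "missing")` (and via a warning), not fatal.
#'
#' @param graph An `igraph` graph with named vertices.
#' @param node_ids Character vector of node names.
#' @return Induced `igraph` subgraph with attribute `missing`.
#' @export
neighborhood_subgraph <- function(graph, node_ids) {
  present <- node_ids[node_ids %in% igraph::V(graph)$name]
  missing <- setdiff(node_ids, present)
  if (length(missing)) {
    warning(length(missing), " node id(s) not in graph: ",
            paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- igraph::induced_subgraph(graph, present)
  attr(sub, "missing") <- missing
  sub
}

#' Summary metrics of a weighted graph
#'
#' Computes the standard network-level descriptors: node and edge
#' counts, average degree (2E/N), average weighted degree (mean
#' strength), weighted modularity of the community partition found by
#' Louvain multilevel optimisation at the given resolution, and the
#' mean unweighted local clustering coefficient over all nodes (nodes
#' of degree < 2 count as 0).
#'
#' @param graph Non-empty `igraph` graph with edge `weight`.
#' @param seed Integer seed for the (stochastic) community optimiser;
#'   default 0.
#' @param resolution Louvain resolution parameter; default 1.
#' @return Tibble with one row: `node_count`, `edge_count`,
#'   `avg_degree`, `avg_weighted_degree`, `modularity`, `n_communities`,
#'   `avg_clustering_coefficient`.
#' @export
graph_summary <- function(graph, seed = 0, resolution = 1) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph: no summary defined", call. = FALSE)
  e <- igraph::ecount(graph)
  w <- if (e > 0L && "weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else rep(1, e)
  cc_local <- igraph::transitivity(graph, type = "local", isolates = "zero")
  if (e > 0L) {
    comm <- with_local_seed(seed, {
      igraph::cluster_louvain(graph, weights = w, resolution = resolution)
    })
    mod <- igraph::modularity(graph, igraph::membership(comm), weights = w,
                              resolution = resolution)
    ncomm <- length(unique(igraph::membership(comm)))
  } else {
    mod <- 0
    ncomm <- n
  }
  tibble(
    node_count = n,
    edge_count = e,
    avg_degree = 2 * e / n,
    avg_weighted_degree = sum(w) * 2 / n,
    modularity = mod,
    n_communities = ncomm,
    avg_clustering_coefficient = mean(cc_local)
  )
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Top nodes by weighted degree
#'
#' Ranks nodes by weighted degree (strength) descending — ties broken
#' by degree descending, then node id ascending — and reports, for
#' each, its most strongly linked partner: the neighbour on the
#' maximum-weight incident edge (ties by partner id ascending) and
#' that edge's weight.
#'
#' @param graph An `igraph` graph with edge `weight`.
#' @param top_n Number of rows (default 10).
#' @param class_filter Optional bioconcept class; restrict rows to
#'   nodes of that class (degrees are still computed on the graph as
#'   given).
#' @return Tibble: `concept_id`, `display_name`, `weighted_degree`,
#'   `degree`, `top_partner`, `top_partner_weight`.
#' @export
degree_table <- function(graph, top_n = 10, class_filter = NULL) {
  stopifnot(top_n >= 1)
  nm <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  wdeg <- igraph::strength(graph, weights = igraph::E(graph)$weight)
  display <- igraph::vertex_attr(graph, "display_name")
  if (is.null(display)) display <- nm
  keep <- seq_along(nm)
  if (!is.null(class_filter)) {
    if (!class_filter %in% bioconcept_classes) {
      stop("unknown bioconcept class: ", class_filter, call. = FALSE)
    }
    cls <- igraph::V(graph)$concept_class
    keep <- which(!is.na(cls) & cls == class_filter)
  }
  ord <- keep[order(-wdeg[keep], -deg[keep], nm[keep])]
  ord <- head(ord, top_n)
  el <- igraph::as_data_frame(graph, what = "edges")
  partner_of <- function(v) {
    inc <- el[el$from == v | el$to == v, , drop = FALSE]
    if (nrow(inc) == 0L) return(list(p = NA_character_, w = NA_integer_))
    other <- ifelse(inc$from == v, inc$to, inc$from)
    best <- order(-inc$weight, other)[1L]
    list(p = other[best], w = as.integer(inc$weight[best]))
  }
  partners <- lapply(nm[ord], partner_of)
  tibble(
    concept_id = nm[ord],
    display_name = display[ord],
    weighted_degree = as.integer(round(wdeg[ord])),
    degree = as.integer(deg[ord]),
    top_partner = vapply(partners, `[[`, character(1), "p"),
    top_partner_weight = vapply(partners, `[[`, integer(1), "w")
  )
}

#' Export a weighted graph
#'
#' Writes a graph as GraphML (single file, node `kind`/`concept_class`
#' attributes and edge `weight` preserved) or as a CSV edge list
#' (`source`, `target`, `weight`) plus a node table CSV (`name`,
#' `kind`, `concept_class`). [import_graph()] reproduces the graph
#' from either format. Node order is sorted by id so exports are
#' deterministic.
#'
#' @param graph An `igraph` graph with named vertices.
#' @param path Output path; for `edge-csv` the node table is written
#'   beside it with suffix `_nodes.csv`.
#' @param format `"graphml"` or `"edge-csv"`.
#' @return Invisibly, the path(s) written.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  graph <- igraph::permute(graph, match(igraph::V(graph)$name,
                                        sort(igraph::V(graph)$name)))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("source", "target")
  if (!"weight" %in% names(el)) el$weight <- integer(nrow(el))
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  if (!"name" %in% names(nodes)) nodes$name <- character(nrow(nodes))
  if (!"kind" %in% names(nodes)) nodes$kind <- rep(NA_character_, nrow(nodes))
  if (!"concept_class" %in% names(nodes)) {
    nodes$concept_class <- rep(NA_character_, nrow(nodes))
  }
  node_path <- sub("\\.csv$", "", path)
  node_path <- paste0(node_path, "_nodes.csv")
  write.csv(el, path, row.names = FALSE)
  write.csv(nodes[, c("name", "kind", "concept_class")], node_path,
            row.names = FALSE)
  invisible(c(path, node_path))
}

#' Import a weighted graph written by [export_graph()]
#'
#' @param path Path given to [export_graph()].
#' @param format `"graphml"` or `"edge-csv"`.
#' @return An `igraph` graph.
#' @export
import_graph <- function(path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::vertex_attr(g, "id")) &&
        is.null(igraph::vertex_attr(g, "name"))) {
      igraph::V(g)$name <- igraph::vertex_attr(g, "id")
    }
    if ("id" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "id")
    }
    if (igraph::ecount(g)) igraph::E(g)$weight <- as.integer(igraph::E(g)$weight)
    return(normalize_na_class(g))
  }
  el <- read.csv(path, colClasses = "character")
  node_path <- paste0(sub("\\.csv$", "", path), "_nodes.csv")
  nodes <- read.csv(node_path, colClasses = "character")
  g <- igraph::graph_from_data_frame(
    el[, c("source", "target")], directed = FALSE, vertices = nodes
  )
  if (nrow(el)) igraph::E(g)$weight <- as.integer(el$weight)
  normalize_na_class(g)
}

# GraphML/CSV serialise NA attribute values as the string "NA" or ""
normalize_na_class <- function(g) {
  for (a in c("kind", "concept_class")) {
    v <- igraph::vertex_attr(g, a)
    if (!is.null(v)) {
      v[!is.na(v) & (v == "NA" | v == "")] <- NA_character_
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  g
}
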