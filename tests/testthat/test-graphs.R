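test_that("document_concepts counts ID-bearing mentions only", {
  docs <- tiny_docs()
  expect_equal(document_concepts(docs[[1]]), c(Gene_7157 = 2L))
  expect_equal(document_concepts(docs[[2]]),
               c(Gene_207 = 1L, Gene_7157 = 1L))
  empty <- annotated_document("9", "No annotations here")
  expect_length(document_concepts(empty), 0)
  expect_length(document_concepts(fixture_43()), 43)
})

test_that("bipartite graph links documents to concepts by mention count", {
  docs <- tiny_docs()
  g <- build_bipartite(docs)
  w <- bipartite_edge_weights(g)
  expect_equal(w[["101||Gene_7157"]], 2L)   # mentioned twice in doc 101
  expect_equal(w[["102||Gene_7157"]], 1L)
  expect_equal(w[["102||Gene_207"]], 1L)
  # concept degree = number of containing documents
  expect_equal(unname(igraph::degree(g, "Gene_7157")), 2)
  # pmid weighted degree = total ID-bearing mention count of the document
  expect_equal(unname(igraph::strength(g, "101")), 2)
  expect_equal(unname(igraph::strength(g, "102")), 2)
  # ID-less chemical contributes no node
  expect_false(any(igraph::V(g)$concept_class %in% "Chemical"))
  # binary-weight variant
  gb <- build_bipartite(docs, mention_counts = FALSE)
  expect_equal(bipartite_edge_weights(gb)[["101||Gene_7157"]], 1L)
})

test_that("co-occurrence weights are twice the shared-document count", {
  # two genes sharing exactly one document -> weight 2
  one <- tiny_docs()[2]
  g1 <- build_cooccurrence(one)
  expect_equal(graph_edge_weights(g1)[["Gene_207||Gene_7157"]], 2L)
  # multiplicity does not inflate: doc with 3xA, 2xB still contributes +2
  multi <- annotated_document("7", "T", paste(rep("m", 5), collapse = " "),
    data.frame(start = 2 + 2 * (0:4), end = 3 + 2 * (0:4), mention = "m",
               class = "Gene", id = c("1", "1", "1", "2", "2")))
  gm <- build_cooccurrence(list(multi))
  expect_equal(graph_edge_weights(gm)[["Gene_1||Gene_2"]], 2L)
  # undoubled convention available behind a flag
  expect_equal(graph_edge_weights(
    build_cooccurrence(list(multi), doubled = FALSE))[["Gene_1||Gene_2"]], 1L)
})

test_that("co-occurrence and bipartite builders match brute-force oracles", {
  for (s in 1:3) {
    corp <- generate_corpus(corpus_spec(n_docs = 150, seed = s))
    docs <- corp$documents
    g <- build_cooccurrence(docs)
    got <- graph_edge_weights(g)
    want <- oracle_pair_counts(docs)
    expect_equal(length(got), length(want))
    for (k in names(want)) expect_equal(got[[k]], 2L * want[[k]])
    expect_true(all(unlist(got) %% 2 == 0) && all(unlist(got) >= 2))

    bw <- bipartite_edge_weights(build_bipartite(docs))
    bo <- oracle_bipartite_counts(docs)
    expect_equal(length(bw), length(bo))
    for (k in names(bo)) expect_equal(bw[[k]], bo[[k]])

    # concept bipartite degree = containing-document count from the oracle
    keys <- unique(sub("^.*\\|\\|", "", names(bo)))
    ndocs_per_key <- table(sub("^.*\\|\\|", "", names(bo)))
    bg <- build_bipartite(docs)
    expect_equal(unname(igraph::degree(bg, keys)),
                 as.integer(ndocs_per_key[keys]))
  }
})

test_that("class subgraph induces exactly the class's nodes, weights kept", {
  docs <- list(annotated_document("1", "T", "a b c",
    data.frame(start = c(2, 4, 6), end = c(3, 5, 7),
               mention = c("a", "b", "c"),
               class = c("Gene", "Gene", "Disease"),
               id = c("1", "2", "D1"))))
  g <- build_cooccurrence(docs)
  gg <- class_subgraph(g, "Gene")
  expect_setequal(igraph::V(gg)$name, c("Gene_1", "Gene_2"))
  expect_equal(igraph::ecount(gg), 1)
  expect_equal(igraph::E(gg)$weight, 2L)
  expect_equal(igraph::vcount(class_subgraph(g, "Species")), 0)
  expect_error(class_subgraph(g, "NotAClass"), "unknown bioconcept class")

  corp <- generate_corpus(corpus_spec(n_docs = 100, seed = 5))
  full <- build_cooccurrence(corp$documents)
  gene <- class_subgraph(full, "Gene")
  expect_true(all(igraph::V(gene)$concept_class == "Gene"))
  # restriction of the oracle to gene pairs
  want <- oracle_pair_counts(corp$documents)
  gene_pairs <- Filter(length, want[grepl("^Gene_.*\\|\\|Gene_", names(want))])
  got <- graph_edge_weights(gene)
  expect_equal(length(got), length(gene_pairs))
  for (k in names(gene_pairs)) expect_equal(got[[k]], 2L * gene_pairs[[k]])
})

test_that("neighborhood subgraph keeps listed nodes and reports missing ids", {
  # star: hub connected to 10 others, mirroring a key-disease neighborhood
  docs <- lapply(1:10, function(i) {
    annotated_document(as.character(i), "T", "hub spoke",
      data.frame(start = c(2, 6), end = c(5, 11),
                 mention = c("hub", "spoke"),
                 class = c("Disease", "Gene"),
                 id = c("HUB", as.character(i))))
  })
  g <- build_cooccurrence(docs)
  ids <- c("Disease_HUB", paste0("Gene_", 1:10))
  nb <- neighborhood_subgraph(g, ids)
  expect_equal(unname(igraph::degree(nb, "Disease_HUB")), 10)
  expect_warning(nb2 <- neighborhood_subgraph(g, c(ids, "Gene_nope")),
                 "not in graph")
  expect_equal(attr(nb2, "missing"), "Gene_nope")
  single <- suppressWarnings(neighborhood_subgraph(g, "Gene_1"))
  expect_equal(igraph::ecount(single), 0)
  # induced edges have parent weights
  ew <- graph_edge_weights(nb)
  pw <- graph_edge_weights(g)
  for (k in names(ew)) expect_equal(ew[[k]], pw[[k]])
})

test_that("graph summary reproduces closed-form metrics", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c"); igraph::E(tri)$weight <- 1L
  s <- graph_summary(tri)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$avg_clustering_coefficient, 1)

  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(3),
                                        igraph::make_full_graph(3))
  igraph::V(two_cliques)$name <- letters[1:6]
  igraph::E(two_cliques)$weight <- 1L
  s2 <- graph_summary(two_cliques, seed = 0)
  expect_equal(s2$modularity, 0.5)
  expect_equal(s2$n_communities, 2L)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]; igraph::E(star)$weight <- 1L
  expect_equal(graph_summary(star)$avg_clustering_coefficient, 0)

  expect_error(graph_summary(igraph::make_empty_graph(0, directed = FALSE)),
               "empty graph")
})

test_that("avg degree identity 2E/N holds on generated graphs", {
  corp <- generate_corpus(corpus_spec(n_docs = 80, seed = 9))
  g <- build_cooccurrence(corp$documents)
  s <- graph_summary(g)
  expect_equal(s$avg_degree, 2 * s$edge_count / s$node_count)
  expect_gte(s$modularity, -0.5)
  expect_lte(s$modularity, 1)
  # doubled convention: weighted degrees even, minimum 2 on non-isolated nodes
  st <- igraph::strength(g)
  st <- st[igraph::degree(g) > 0]
  expect_true(all(st %% 2 == 0) && all(st >= 2))
})

test_that("degree_table ranks by weighted degree with stated tie-breaks", {
  # path a-b-c with weights 5 and 3
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(5L, 3L)),
    directed = FALSE)
  tab <- degree_table(g, top_n = 3)
  expect_equal(tab$concept_id[1], "b")
  expect_equal(tab$weighted_degree[1], 8L)
  expect_equal(tab$degree[1], 2L)
  expect_equal(tab$top_partner[1], "a")
  expect_equal(tab$top_partner_weight[1], 5L)
  expect_true(all(tab$top_partner_weight <= tab$weighted_degree))

  single <- igraph::graph_from_data_frame(
    data.frame(from = "x", to = "y", weight = 4L), directed = FALSE)
  st <- degree_table(single, top_n = 2)
  expect_equal(st$weighted_degree, c(4L, 4L))
  expect_equal(st$concept_id, c("x", "y"))  # id-ascending tie-break
  expect_equal(st$top_partner, c("y", "x"))

  # deterministic total order on a generated graph
  corp <- generate_corpus(corpus_spec(n_docs = 60, seed = 13))
  gg <- class_subgraph(build_cooccurrence(corp$documents), "Gene")
  t1 <- degree_table(gg, top_n = 20)
  t2 <- degree_table(gg, top_n = 20)
  expect_identical(t1, t2)
  key <- order(-t1$weighted_degree, -t1$degree, t1$concept_id)
  expect_equal(key, seq_len(nrow(t1)))
})

test_that("degree_table class filter restricts rows, not the graph", {
  docs <- list(annotated_document("1", "T", "a b",
    data.frame(start = c(2, 4), end = c(3, 5), mention = c("a", "b"),
               class = c("Gene", "Disease"), id = c("1", "D"))))
  g <- build_cooccurrence(docs)
  tab <- degree_table(g, top_n = 5, class_filter = "Gene")
  expect_equal(tab$concept_id, "Gene_1")
  expect_equal(tab$top_partner, "Disease_D")
})

test_that("graph export/import round-trips in both formats", {
  same_graph <- function(a, b) {
    norm <- function(g) {
      e <- igraph::as_data_frame(g, "edges")
      e <- data.frame(s = pmin(e$from, e$to), t = pmax(e$from, e$to),
                      w = e$weight)
      e <- e[order(e$s, e$t), ]; rownames(e) <- NULL; e
    }
    vn <- function(g) {
      v <- igraph::as_data_frame(g, "vertices")[, c("name", "kind",
                                                    "concept_class")]
      v <- v[order(v$name), ]; rownames(v) <- NULL; v
    }
    isTRUE(all.equal(norm(a), norm(b))) && isTRUE(all.equal(vn(a), vn(b)))
  }
  corp <- generate_corpus(corpus_spec(n_docs = 40, seed = 17))
  for (g in list(build_cooccurrence(corp$documents),
                 build_bipartite(corp$documents))) {
    gm <- withr::local_tempfile(fileext = ".graphml")
    export_graph(g, gm, "graphml")
    expect_true(same_graph(g, import_graph(gm, "graphml")))
    ec <- withr::local_tempfile(fileext = ".csv")
    export_graph(g, ec, "edge-csv")
    expect_true(same_graph(g, import_graph(ec, "edge-csv")))
    # edge-csv row count = edge count (minus header)
    expect_equal(length(readLines(ec)) - 1L, igraph::ecount(g))
  }
  # empty graph exports header-only files
  e <- igraph::make_empty_graph(0, directed = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  export_graph(e, p, "edge-csv")
  expect_equal(length(readLines(p)), 1L)
  expect_error(export_graph(e, p, "nonsense"))
})
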