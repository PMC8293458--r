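# Brute-force oracles, independent of the graph builders: plain double
# loops over documents and pattern enumeration over membership rows.

# shared-document count for every concept pair (undoubled)
oracle_pair_counts <- function(docs) {
  key_sets <- lapply(docs, function(d) {
    unique(d$annotations$canonical[!is.na(d$annotations$canonical)])
  })
  counts <- list()
  for (ks in key_sets) {
    if (length(ks) < 2L) next
    ks <- sort(ks)
    for (i in seq_len(length(ks) - 1L)) {
      for (j in seq((i + 1L), length(ks))) {
        k <- paste(ks[i], ks[j], sep = "||")
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mention count per (pmid, key), brute force over annotation rows
oracle_bipartite_counts <- function(docs) {
  counts <- list()
  for (d in docs) {
    ann <- d$annotations
    for (i in seq_len(nrow(ann))) {
      if (is.na(ann$canonical[i])) next
      k <- paste(d$pmid, ann$canonical[i], sep = "||")
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  counts
}

# edge weights of an igraph graph as a named list "a||b" -> weight (a < b)
graph_edge_weights <- function(g) {
  el <- igraph::as_data_frame(g, "edges")
  out <- list()
  for (i in seq_len(nrow(el))) {
    a <- min(el$from[i], el$to[i]); b <- max(el$from[i], el$to[i])
    out[[paste(a, b, sep = "||")]] <- el$weight[i]
  }
  out
}

# edge weights of a bipartite graph keyed "pmid||concept" using node kinds
bipartite_edge_weights <- function(g) {
  el <- igraph::as_data_frame(g, "edges")
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  out <- list()
  for (i in seq_len(nrow(el))) {
    p <- if (kind[[el$from[i]]] == "pmid") el$from[i] else el$to[i]
    k <- if (kind[[el$from[i]]] == "pmid") el$to[i] else el$from[i]
    out[[paste(p, k, sep = "||")]] <- el$weight[i]
  }
  out
}

# exclusive pattern tally by explicit enumeration over all 2^k combinations
oracle_exclusive <- function(m) {
  sets <- colnames(m)
  k <- length(sets)
  out <- list()
  for (mask in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    match_rows <- apply(m > 0, 1L, function(r) all(r == inset))
    cnt <- sum(match_rows)
    if (cnt > 0L) {
      out[[paste(sets[inset], collapse = "&")]] <- cnt
    }
  }
  out
}

# a tiny two-document fixture used in several unit tests
tiny_docs <- function() {
  d1 <- annotated_document("101", "Title one", "p53 p53 and a chemical",
    data.frame(start = c(10, 14, 24), end = c(13, 17, 32),
               mention = c("p53", "p53", "chemical"),
               class = c("Gene", "Gene", "Chemical"),
               id = c("7157", "7157", NA)))
  d2 <- annotated_document("102", "Title two", "p53 meets AKT1",
    data.frame(start = c(10, 20), end = c(13, 24),
               mention = c("p53", "AKT1"),
               class = c("Gene", "Gene"),
               id = c("7157", "207")))
  list(d1, d2)
}
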