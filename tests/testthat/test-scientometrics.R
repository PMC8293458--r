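fake_records <- function(years = integer(), journals = character(),
                         mesh = list()) {
  n <- max(length(years), length(journals), length(mesh))
  tibble::tibble(
    pmid = as.character(seq_len(n)),
    year = if (length(years)) years else rep(NA_integer_, n),
    journal_full = if (length(journals)) journals else rep("J", n),
    journal_abbrev = "J",
    mesh = if (length(mesh)) mesh else rep(list(character()), n)
  )
}

test_that("year and journal counts tally records with deterministic order", {
  r <- fake_records(years = c(2014L, 2014L, 2015L, NA))
  yc <- year_counts(r)
  expect_equal(yc$item, c("2014", "2015"))
  expect_equal(yc$frequency, c(2L, 1L))
  expect_equal(attr(yc, "unknown_year"), 1L)
  expect_equal(sum(yc$pct), 100)

  r2 <- fake_records(journals = c("A", "A", "A", "B"))
  jc <- journal_counts(r2)
  expect_equal(jc$item[1], "A")
  expect_equal(jc$frequency, c(3L, 1L))

  empty <- year_counts(fake_records())
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "unknown_year"), 0L)
})

test_that("generated year and journal tallies match the generator ledger", {
  corp <- generate_corpus(corpus_spec(n_docs = 120, seed = 11))
  yc <- year_counts(corp$citations)
  led <- corp$ledger$year_counts
  expect_equal(setNames(yc$frequency, yc$item)[names(led)],
               setNames(as.integer(led), names(led)))
  jc <- journal_counts(corp$citations)
  led_j <- corp$ledger$journal_counts
  expect_equal(jc$item[1], names(led_j)[which.max(led_j)])
})

test_that("keyword frequencies apply the inclusive min-frequency cut", {
  mesh <- c(rep(list(c("alpha", "beta")), 5), rep(list("beta"), 1),
            rep(list("gamma"), 4))
  r <- fake_records(mesh = mesh)
  kw <- keyword_frequencies(r, min_freq = 5)
  expect_setequal(kw$item, c("alpha", "beta"))  # gamma at 4 excluded
  expect_equal(kw$frequency[kw$item == "alpha"], 5L)
  expect_equal(kw$frequency[kw$item == "beta"], 6L)
  # per-record dedup: repeated heading in one record counts once
  r2 <- fake_records(mesh = list(c("x", "x"), "x"))
  expect_equal(keyword_frequencies(r2, min_freq = 1)$frequency, 2L)
  # pct over the post-filter table
  r3 <- fake_records(mesh = c(rep(list("a"), 30), rep(list("b"), 10)))
  kw3 <- keyword_frequencies(r3, min_freq = 1)
  expect_equal(kw3$pct, c(75, 25))
  # top_n truncation recomputes pct over the truncated table
  kw4 <- keyword_frequencies(r3, min_freq = 1, top_n = 1)
  expect_equal(kw4$item, "a")
  expect_equal(kw4$pct, 100)
})

test_that("keyword co-occurrence weights count shared records once", {
  r <- fake_records(mesh = list(c("a", "b"), c("a", "b"), c("a", "c")))
  g <- keyword_cooccurrence(r, min_freq = 1, top_n = 10)
  w <- graph_edge_weights(g)
  expect_equal(w[["a||b"]], 2)
  expect_equal(w[["a||c"]], 1)
  expect_null(w[["b||c"]])   # never share a record
  expect_false(igraph::any_loop(g))

  # brute-force oracle on a random synthetic corpus
  corp <- generate_corpus(corpus_spec(n_docs = 50, seed = 3))
  g2 <- keyword_cooccurrence(corp$citations, min_freq = 1, top_n = 1000)
  mesh <- lapply(corp$citations$mesh, unique)
  for (pair in sample(names(graph_edge_weights(g2)), 25)) {
    ab <- strsplit(pair, "||", fixed = TRUE)[[1]]
    brute <- sum(vapply(mesh, function(h) all(ab %in% h), logical(1)))
    expect_equal(graph_edge_weights(g2)[[pair]], brute)
  }
  # frequency of a heading bounds the weight of incident edges
  freq <- keyword_frequencies(corp$citations, min_freq = 1, top_n = 1000)
  fmap <- setNames(freq$frequency, freq$item)
  el <- igraph::as_data_frame(g2, "edges")
  expect_true(all(el$weight <= pmin(fmap[el$from], fmap[el$to])))
})

test_that("keyword graph respects the top_n node cap", {
  r <- fake_records(mesh = rep(list(c("a", "b", "c", "d")), 3))
  g <- keyword_cooccurrence(r, min_freq = 1, top_n = 2)
  expect_lte(igraph::vcount(g), 2)
})
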