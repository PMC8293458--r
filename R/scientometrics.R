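frequency_table <- function(items) {
  if (length(items) == 0L) {
    return(tibble(item = character(), frequency = integer(), pct = numeric()))
  }
  tab <- table(items)
  out <- tibble(item = names(tab), frequency = as.integer(tab))
  finish_frequency_table(out)
}

# sort by frequency desc, ties lexicographic by item; pct over the table's own sum
finish_frequency_table <- function(out) {
  out <- out[order(-out$frequency, out$item), , drop = FALSE]
  out$pct <- if (nrow(out)) 100 * out$frequency / sum(out$frequency) else numeric()
  out
}

#' Publication counts per year
#'
#' Tallies citation records by publication year, the year-wise trend
#' view of a corpus. Records without a parseable year are excluded from
#' the table and counted in `attr(result, "unknown_year")`.
#'
#' @param records Citation tibble from [parse_medline()].
#' @return Frequency table tibble (`item`, `frequency`, `pct`), sorted
#'   by frequency descending with lexicographic tie-break.
#' @export
year_counts <- function(records) {
  known <- !is.na(records$year)
  out <- frequency_table(as.character(records$year[known]))
  attr(out, "unknown_year") <- sum(!known)
  out
}

#' Publication counts per journal
#'
#' As [year_counts()], keyed by the full journal title.
#'
#' @inheritParams year_counts
#' @return Frequency table tibble.
#' @export
journal_counts <- function(records) {
  j <- records$journal_full
  known <- !is.na(j) & nzchar(j)
  out <- frequency_table(j[known])
  attr(out, "unknown_journal") <- sum(!known)
  out
}

#' MeSH keyword frequencies
#'
#' Counts, for each MeSH heading, the number of records containing it
#' (headings are deduplicated within a record, so qualifier variants of
#' one heading count once per record). Headings below `min_freq` are
#' excluded; the table is then truncated to the `top_n` most frequent
#' headings and percentages computed over that final table — matching
#' the convention of reporting percentages over the retained keyword
#' list only.
#'
#' @param records Citation tibble with a `mesh` list-column.
#' @param min_freq Minimum record count for a heading to be retained
#'   (inclusive); default 5.
#' @param top_n Keep only the `top_n` most frequent headings after
#'   filtering; default 1000.
#' @return Frequency table tibble (`item`, `frequency`, `pct`).
#' @export
keyword_frequencies <- function(records, min_freq = 5, top_n = 1000) {
  stopifnot(min_freq >= 1, top_n >= 1)
  headings <- unlist(lapply(records$mesh, unique), use.names = FALSE)
  out <- frequency_table(headings)
  out <- out[out$frequency >= min_freq, , drop = FALSE]
  out <- head(out, top_n)
  finish_frequency_table(out)
}

#' MeSH keyword co-occurrence network
#'
#' Builds an undirected weighted graph over the headings retained by
#' the [keyword_frequencies()] filter (minimum frequency, then top-n
#' truncation). The weight of edge (a, b) is the number of records
#' containing both headings; pairs never sharing a record have no
#' edge. Each shared record counts once — the standard co-occurrence
#' link-strength convention (distinct from the doubled convention of
#' the bioconcept graphs, see [build_cooccurrence()]).
#'
#' @inheritParams keyword_frequencies
#' @return An `igraph` graph; vertices carry `kind = "keyword"` and
#'   `frequency`, edges carry `weight`.
#' @export
keyword_cooccurrence <- function(records, min_freq = 5, top_n = 1000) {
  freq <- keyword_frequencies(records, min_freq = min_freq, top_n = top_n)
  keep <- freq$item
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(keep), name = keep, kind = "keyword",
                            frequency = freq$frequency)
  if (length(keep) >= 2L && nrow(records)) {
    sets <- lapply(records$mesh, function(h) sort(intersect(unique(h), keep)))
    sets <- Filter(function(s) length(s) >= 2L, sets)
    if (length(sets)) {
      pairs <- dplyr::bind_rows(lapply(sets, function(s) {
        cmb <- utils::combn(s, 2L)
        tibble(from = cmb[1L, ], to = cmb[2L, ])
      }))
      w <- dplyr::count(pairs, .data$from, .data$to, name = "weight")
      g <- igraph::add_edges(g, rbind(w$from, w$to), weight = w$weight)
    }
  }
  g
}
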