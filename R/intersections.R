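#' Build a PMID-by-set membership matrix
#'
#' Turns named element lists (e.g. the PMID list downloaded for each
#' MeSH subheading) into a binary membership matrix: rows are the
#' deduplicated union of all elements, columns the named sets,
#' `cell(e, s) = 1` iff element `e` belongs to set `s`. Every element
#' of the union belongs to at least one set by construction.
#'
#' @param named_sets Named list of character vectors (set name ->
#'   element identifiers). Duplicate elements within one list count
#'   once.
#' @return Integer matrix of class `membership_matrix`, with element
#'   identifiers as rownames and set names as colnames.
#' @export
build_membership_matrix <- function(named_sets) {
  stopifnot(length(named_sets) >= 1L)
  nm <- names(named_sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("named_sets must have unique non-empty names", call. = FALSE)
  }
  sets <- lapply(named_sets, function(x) unique(as.character(x)))
  elements <- unique(unlist(sets, use.names = FALSE))
  if (length(elements) == 0L) {
    stop("empty union: no elements to intersect", call. = FALSE)
  }
  m <- vapply(sets, function(s) as.integer(elements %in% s),
              integer(length(elements)))
  m <- matrix(m, nrow = length(elements), dimnames = list(elements, nm))
  structure(m, class = c("membership_matrix", class(m)))
}

check_membership <- function(matrix) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (any(rowSums(matrix) == 0L)) {
    stop("membership matrix has elements belonging to no set", call. = FALSE)
  }
  invisible(matrix)
}

#' Exclusive (distinct-mode) set intersections
#'
#' For every membership pattern that actually occurs, reports the set
#' combination and the number of elements whose membership equals
#' exactly that combination — the "distinct" mode of UpSet-style
#' analysis, where an element is counted for one and only one
#' combination. Counts therefore partition the union: they sum to the
#' number of unique elements.
#'
#' Rows are sorted by count descending; ties are broken by smaller
#' combination size first, then lexicographically by the combination
#' label.
#'
#' @param matrix A [build_membership_matrix()] result.
#' @return Tibble with columns `combination` ("&"-joined set names, in
#'   column order), `degree` (number of sets in the combination),
#'   `count`, and a `sets` list-column of the set names.
#' @export
exclusive_intersections <- function(matrix) {
  check_membership(matrix)
  pat <- apply(matrix > 0, 1L, function(r) paste(colnames(matrix)[r], collapse = "&"))
  tab <- table(pat)
  sets <- strsplit(names(tab), "&", fixed = TRUE)
  out <- tibble(
    combination = names(tab),
    degree = lengths(sets),
    count = as.integer(tab),
    sets = sets
  )
  out[order(-out$count, out$degree, out$combination), , drop = FALSE]
}

#' Pairwise inclusive intersection sizes
#'
#' The classical pairwise view: for each pair of sets, the number of
#' elements belonging to both, regardless of any other memberships
#' (so an element in three sets contributes to all three of its
#' pairs). Reported alongside the exclusive profile because narrative
#' statements about "the intersection of A and B" usually mean this
#' inclusive figure.
#'
#' @inheritParams exclusive_intersections
#' @return Tibble (`set1`, `set2`, `count`), count descending, zero
#'   pairs omitted.
#' @export
inclusive_pair_counts <- function(matrix) {
  check_membership(matrix)
  cp <- crossprod(matrix > 0)
  idx <- which(upper.tri(cp) & cp > 0, arr.ind = TRUE)
  out <- tibble(
    set1 = colnames(matrix)[idx[, 1L]],
    set2 = colnames(matrix)[idx[, 2L]],
    count = as.integer(cp[idx])
  )
  out[order(-out$count, out$set1, out$set2), , drop = FALSE]
}

#' Sets not participating in any intersection
#'
#' A set participates in the intersection structure when at least one
#' of its elements also belongs to another set. This returns the sets
#' for which no such element exists — equivalently, sets appearing in
#' no exclusive intersection of size two or more. With a single-set
#' matrix the answer is that set (no partner exists).
#'
#' @inheritParams exclusive_intersections
#' @return Character vector of set names, in column order.
#' @export
nonparticipating_sets <- function(matrix) {
  check_membership(matrix)
  shared <- rowSums(matrix > 0) >= 2L
  part <- colSums(matrix[shared, , drop = FALSE] > 0) > 0L
  colnames(matrix)[!part]
}

#' UpSet-style intersection plot
#'
#' Draws the exclusive intersection profile as a bar chart of counts
#' over a dot matrix of set combinations, bars ordered by count
#' descending (ties by smaller degree, then name).
#'
#' @inheritParams exclusive_intersections
#' @param n_max Plot at most this many combinations (default 40).
#' @return A patchwork/ggplot object.
#' @export
plot_intersections <- function(matrix, n_max = 40) {
  ints <- head(exclusive_intersections(matrix), n_max)
  ints$rank <- seq_len(nrow(ints))
  set_names <- colnames(matrix)
  dots <- dplyr::bind_rows(lapply(seq_len(nrow(ints)), function(i) {
    tibble(rank = ints$rank[i], set = set_names,
           member = set_names %in% ints$sets[[i]])
  }))
  dots$set <- factor(dots$set, levels = rev(set_names))
  p_bar <- ggplot2::ggplot(ints, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_col(fill = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 2.6) +
    ggplot2::labs(x = NULL, y = "Exclusive intersection size") +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
  p_dots <- ggplot2::ggplot(dots, ggplot2::aes(x = .data$rank, y = .data$set)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$member), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey85"),
                                 guide = "none") +
    ggplot2::labs(x = "Intersection", y = NULL) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p_bar, p_dots, ncol = 1, heights = c(2, 1))
}

#' Read plain-text PMID list files as named sets
#'
#' Each file holds one PMID per line; the set name is the file name
#' without extension. Blank lines are ignored.
#'
#' @param paths Character vector of file paths.
#' @return Named list of character vectors, suitable for
#'   [build_membership_matrix()].
#' @export
read_pmid_lists <- function(paths) {
  sets <- lapply(paths, function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x[nzchar(x)]
  })
  names(sets) <- sub("\\.[^.]*$", "", basename(paths))
  sets
}
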