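#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats setNames
#' @importFrom utils head write.csv read.csv
NULL

#' Bioconcept classes recognised by the annotation pipeline
#'
#' The ten entity classes produced by PubTator-style named-entity
#' annotation of PubMed titles and abstracts: cell lines, chemicals,
#' diseases, DNA and protein mutations, genes, genus and species names,
#' SNPs, and strains.
#'
#' @format Character vector of length 10.
#' @export
bioconcept_classes <- c(
  "CellLine", "Chemical", "Disease", "DNAMutation", "Gene",
  "Genus", "ProteinMutation", "SNP", "Species", "Strain"
)

#' Canonical bioconcept identity
#'
#' A bioconcept is identified by its class and a database identifier
#' (e.g. an NCBI Gene ID or a MeSH descriptor). The canonical label is
#' `"<class>_<id>"`, the form used as node name in all graphs — e.g.
#' `Species_9606` for human, `Disease_MESH:D009369` for cancer. The id
#' may itself contain separators (`MESH:D009369`); only the first `_`
#' separates class from id. An annotation without an identifier ("no
#' ID") has no canonical label and can never become a graph node,
#' because its identity across documents is undefined.
#'
#' @param concept_class One of [bioconcept_classes].
#' @param concept_id Identifier string, or `NA`/`""` for an ID-less
#'   mention.
#' @return A list of class `bioconcept_key` with elements
#'   `concept_class`, `concept_id` (`NA_character_` when absent) and
#'   `canonical` (`NA_character_` when absent).
#' @examples
#' concept_key("Species", "9606")$canonical   # "Species_9606"
#' concept_key("Gene", NA)$canonical          # NA: ID-less mention
#' @export
concept_key <- function(concept_class, concept_id = NA_character_) {
  if (length(concept_class) != 1L || !concept_class %in% bioconcept_classes) {
    stop("invalid bioconcept class: ", paste(concept_class, collapse = ", "),
         " (must be one of: ", paste(bioconcept_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  id <- as.character(concept_id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) id <- NA_character_
  structure(
    list(
      concept_class = concept_class,
      concept_id = id,
      canonical = if (is.na(id)) NA_character_ else paste0(concept_class, "_", id)
    ),
    class = "bioconcept_key"
  )
}

#' @export
print.bioconcept_key <- function(x, ...) {
  lab <- if (is.na(x$canonical)) paste0(x$concept_class, " (no ID)") else x$canonical
  cat("<bioconcept_key> ", lab, "\n", sep = "")
  invisible(x)
}

canonical_label <- function(concept_class, concept_id) {
  ifelse(is.na(concept_id) | !nzchar(concept_id),
         NA_character_,
         paste0(concept_class, "_", concept_id))
}

empty_annotation_tbl <- function() {
  tibble(
    pmid = character(), start = integer(), end = integer(),
    mention = character(), class = character(), id = character(),
    canonical = character()
  )
}

#' Construct an annotated document
#'
#' Bundles a PMID, its title/abstract text and a table of entity
#' annotations into an `annotated_document`. Annotations are stored as
#' a tibble with columns `pmid`, `start`, `end` (0-based, half-open
#' character offsets into title + separator + abstract), `mention`,
#' `class`, `id` (`NA` when the mention carries no identifier) and the
#' derived `canonical` label.
#'
#' @param pmid Document identifier (non-empty string).
#' @param title Title text.
#' @param abstract Abstract text; may be empty (title-only records are
#'   legal in PubMed).
#' @param annotations A data frame with columns `start`, `end`,
#'   `mention`, `class` and optionally `id`; row order is preserved.
#' @return An `annotated_document` object.
#' @export
annotated_document <- function(pmid, title, abstract = "", annotations = NULL) {
  pmid <- as.character(pmid)
  stopifnot(length(pmid) == 1L, nzchar(pmid))
  if (is.null(annotations) || nrow(annotations) == 0L) {
    ann <- empty_annotation_tbl()
  } else {
    annotations <- as_tibble(annotations)
    if (!"id" %in% names(annotations)) annotations$id <- NA_character_
    ann <- tibble(
      pmid = pmid,
      start = as.integer(annotations$start),
      end = as.integer(annotations$end),
      mention = as.character(annotations$mention),
      class = as.character(annotations$class),
      id = {
        id <- as.character(annotations$id)
        id[!is.na(id) & !nzchar(id)] <- NA_character_
        id
      }
    )
    ann$canonical <- canonical_label(ann$class, ann$id)
  }
  doc <- structure(
    list(pmid = pmid, title = as.character(title),
         abstract = as.character(abstract), annotations = ann),
    class = "annotated_document"
  )
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  ann <- doc$annotations
  if (nrow(ann) == 0L) return(invisible(doc))
  if (!all(ann$pmid == doc$pmid)) {
    stop("annotation pmid differs from document pmid ", doc$pmid, call. = FALSE)
  }
  bad <- !ann$class %in% bioconcept_classes
  if (any(bad)) {
    stop("unknown bioconcept class: ", paste(unique(ann$class[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ann$start) | is.na(ann$end) | ann$start < 0L | ann$start >= ann$end)) {
    stop("invalid annotation span in document ", doc$pmid,
         " (need 0 <= start < end)", call. = FALSE)
  }
  if (any(!nzchar(ann$mention))) {
    stop("empty annotation mention in document ", doc$pmid, call. = FALSE)
  }
  # combined text = title + 1-char separator + abstract
  len <- nchar(doc$title) + (if (nzchar(doc$abstract)) 1L + nchar(doc$abstract) else 0L)
  if (any(ann$end > len)) {
    stop("annotation span exceeds combined title+abstract length in document ",
         doc$pmid, call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat("<annotated_document> PMID ", x$pmid, ": ", nrow(x$annotations),
      " annotation(s)\n", sep = "")
  cat("  title: ", substr(x$title, 1, 60),
      if (nchar(x$title) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Parse a PubTator-format annotation export
#'
#' Reads the plain-text PubTator exchange format: blank-line-separated
#' records, each with a `<pmid>|t|<title>` line, an optional
#' `<pmid>|a|<abstract>` line, then zero or more tab-separated
#' annotation lines `<pmid> <start> <end> <mention> <class> <id>` (the
#' id field may be empty or absent, yielding an ID-less mention).
#' Offsets are preserved verbatim; document and annotation order are
#' preserved. CRLF line endings are tolerated.
#'
#' @param text Either a single string containing the whole stream, a
#'   character vector of lines, or a path to a file.
#' @return List of [annotated_document] objects.
#' @seealso [write_pubtator()] for the inverse; the two round-trip.
#' @export
parse_pubtator <- function(text) {
  lines <- as_lines(text)
  docs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec("^([^|]+)\\|t\\|(.*)$", lines[i]))[[1]]
    if (length(m) == 0L) {
      stop("line ", i, ": expected '<pmid>|t|<title>' record header, got: ",
           substr(lines[i], 1, 60), call. = FALSE)
    }
    pmid <- m[2]; title <- m[3]; abstract <- ""
    i <- i + 1L
    if (i <= n && grepl("^[^|]+\\|a\\|", lines[i])) {
      ma <- regmatches(lines[i], regexec("^([^|]+)\\|a\\|(.*)$", lines[i]))[[1]]
      if (ma[2] != pmid) {
        stop("line ", i, ": abstract pmid ", ma[2],
             " does not match record pmid ", pmid, call. = FALSE)
      }
      abstract <- ma[3]
      i <- i + 1L
    }
    ann_rows <- list()
    while (i <= n && nzchar(lines[i])) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 5L || length(f) > 6L) {
        stop("line ", i, ": annotation line must have 5 or 6 tab-separated fields, got ",
             length(f), call. = FALSE)
      }
      if (f[1] != pmid) {
        stop("line ", i, ": annotation pmid ", f[1],
             " does not match record pmid ", pmid, call. = FALSE)
      }
      if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3])) {
        stop("line ", i, ": non-integer annotation offsets", call. = FALSE)
      }
      if (!f[5] %in% bioconcept_classes) {
        stop("line ", i, ": unknown bioconcept class '", f[5], "'", call. = FALSE)
      }
      ann_rows[[length(ann_rows) + 1L]] <- list(
        start = as.integer(f[2]), end = as.integer(f[3]),
        mention = f[4], class = f[5],
        id = if (length(f) == 6L && nzchar(f[6])) f[6] else NA_character_
      )
      i <- i + 1L
    }
    ann <- if (length(ann_rows)) {
      tibble(
        start = vapply(ann_rows, `[[`, integer(1), "start"),
        end = vapply(ann_rows, `[[`, integer(1), "end"),
        mention = vapply(ann_rows, `[[`, character(1), "mention"),
        class = vapply(ann_rows, `[[`, character(1), "class"),
        id = vapply(ann_rows, `[[`, character(1), "id")
      )
    } else NULL
    docs[[length(docs) + 1L]] <- annotated_document(pmid, title, abstract, ann)
  }
  docs
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  sub("\r$", "", lines)
}

#' Serialise documents to PubTator format
#'
#' Writes a list of [annotated_document] objects back to the PubTator
#' exchange format, records separated by exactly one blank line, LF
#' line endings. `parse_pubtator(write_pubtator(docs))` reproduces
#' `docs` field-for-field.
#'
#' @param docs List of `annotated_document` objects.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The serialised text (invisibly when `path` is given).
#' @export
write_pubtator <- function(docs, path = NULL) {
  blocks <- vapply(docs, function(d) {
    validate_document(d)
    out <- paste0(d$pmid, "|t|", d$title)
    if (nzchar(d$abstract)) out <- c(out, paste0(d$pmid, "|a|", d$abstract))
    if (nrow(d$annotations)) {
      a <- d$annotations
      out <- c(out, paste(a$pmid, a$start, a$end, a$mention, a$class,
                          ifelse(is.na(a$id), "", a$id), sep = "\t"))
    }
    paste(out, collapse = "\n")
  }, character(1))
  text <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(text, con, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' Per-class bioconcept statistics
#'
#' Tallies annotations across a corpus into the standard per-class
#' summary: `total` (all mentions of the class), `unique` (distinct
#' canonical class+ID keys) and `no_id` (mentions lacking an
#' identifier). All ten classes are always reported; classes absent
#' from the corpus report zeros.
#'
#' @param docs List of [annotated_document] objects.
#' @return Tibble with columns `class`, `total`, `unique`, `no_id`,
#'   one row per class in the canonical class order.
#' @export
concept_stats <- function(docs) {
  ann <- corpus_annotations(docs)
  out <- tibble(class = bioconcept_classes, total = 0L, unique = 0L, no_id = 0L)
  if (nrow(ann)) {
    tot <- table(factor(ann$class, levels = bioconcept_classes))
    noid <- table(factor(ann$class[is.na(ann$id)], levels = bioconcept_classes))
    uni <- ann[!is.na(ann$canonical), c("class", "canonical")]
    uni <- uni[!duplicated(uni$canonical), ]
    uq <- table(factor(uni$class, levels = bioconcept_classes))
    out$total <- as.integer(tot)
    out$no_id <- as.integer(noid)
    out$unique <- as.integer(uq)
  }
  out
}

corpus_annotations <- function(docs) {
  if (length(docs) == 0L) return(empty_annotation_tbl())
  dplyr::bind_rows(lapply(docs, function(d) d$annotations))
}
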