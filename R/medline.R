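#' Parse a PubMed MEDLINE text export
#'
#' Reads the MEDLINE tag-value format (4-character tag, dash, value;
#' continuation lines indented; records separated by blank lines) and
#' extracts the fields the downstream analyses use: PMID, publication
#' year (first 4-digit token of the `DP` value), full journal title
#' (`JT`), journal abbreviation (`TA`) and MeSH headings (`MH`).
#'
#' MeSH headings are normalised: the leading major-topic `*` is
#' stripped, qualifiers after `/` are discarded, per-term `*` markers
#' removed, the heading lowercased, and duplicates within a record
#' dropped (first occurrence kept). Records lacking a PMID are skipped
#' with a warning; the number skipped is available as
#' `attr(result, "skipped")`.
#'
#' @param text A single string, character vector of lines, or file path.
#' @return Tibble with columns `pmid`, `year` (integer, `NA` when the
#'   date is unparseable), `journal_full`, `journal_abbrev` and `mesh`
#'   (list-column of normalised heading vectors), plus attribute
#'   `skipped`.
#' @export
parse_medline <- function(text) {
  lines <- as_lines(text)
  # fold continuation lines (indented) into the previous tag line
  rec_break <- !nzchar(trimws(lines))
  recs <- split(lines[!rec_break], cumsum(rec_break)[!rec_break])
  recs <- Filter(length, recs)

  skipped <- 0L
  rows <- lapply(recs, function(rl) {
    cont <- grepl("^\\s+\\S", rl)
    grp <- cumsum(!cont)
    fields <- vapply(split(rl, grp), function(x) {
      paste(trimws(x), collapse = " ")
    }, character(1))
    m <- regmatches(fields, regexec("^([A-Z0-9]{1,4})\\s*- (.*)$", fields))
    tags <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, character(1))
    vals <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, character(1))
    pmid <- vals[which(tags == "PMID")[1]]
    if (is.na(pmid) || !nzchar(pmid)) return(NULL)
    dp <- vals[which(tags == "DP")[1]]
    year <- NA_integer_
    if (!is.na(dp)) {
      ym <- regmatches(dp, regexpr("\\b[0-9]{4}\\b", dp))
      if (length(ym)) year <- as.integer(ym)
    }
    jt <- vals[which(tags == "JT")[1]]
    ta <- vals[which(tags == "TA")[1]]
    mh <- normalize_mesh(vals[tags == "MH" & !is.na(tags)])
    list(pmid = pmid, year = year,
         journal_full = if (is.na(jt)) "" else jt,
         journal_abbrev = if (is.na(ta)) "" else ta,
         mesh = mh)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  rows <- unname(Filter(Negate(is.null), rows))
  out <- tibble(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    year = vapply(rows, `[[`, integer(1), "year"),
    journal_full = vapply(rows, `[[`, character(1), "journal_full"),
    journal_abbrev = vapply(rows, `[[`, character(1), "journal_abbrev"),
    mesh = unname(lapply(rows, `[[`, "mesh"))
  )
  if (skipped > 0L) {
    warning(skipped, " MEDLINE record(s) lacking a PMID were skipped",
            call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Normalise MeSH heading strings
#'
#' Applies the heading normalisation used throughout the keyword
#' analyses: strip the leading major-topic `*`, drop qualifiers after
#' `/`, strip any remaining `*`, lowercase, trim, and deduplicate
#' preserving first occurrence. Idempotent.
#'
#' @param x Character vector of raw `MH` values.
#' @return Character vector of normalised headings.
#' @export
normalize_mesh <- function(x) {
  if (length(x) == 0L) return(character())
  h <- sub("^\\*", "", unname(x))
  h <- sub("/.*$", "", h)
  h <- gsub("*", "", h, fixed = TRUE)
  h <- tolower(trimws(h))
  h <- h[nzchar(h)]
  h[!duplicated(h)]
}

#' Merge citation files, deduplicating by PMID
#'
#' Batch downloads from PubMed arrive as several MEDLINE files; this
#' concatenates them into one citation table, keeping the first
#' occurrence of each PMID. The number of duplicate records dropped is
#' available as `attr(result, "duplicates")`. Merging is idempotent.
#'
#' @param streams List of MEDLINE inputs (strings, line vectors or file
#'   paths), or a list of already-parsed citation tibbles.
#' @return Deduplicated citation tibble as from [parse_medline()].
#' @export
merge_citation_files <- function(streams) {
  parts <- lapply(streams, function(s) {
    if (is.data.frame(s)) s else parse_medline(s)
  })
  all <- dplyr::bind_rows(parts)
  dup <- duplicated(all$pmid)
  out <- all[!dup, , drop = FALSE]
  attr(out, "duplicates") <- sum(dup)
  attr(out, "skipped") <- sum(vapply(parts, function(p) {
    s <- attr(p, "skipped"); if (is.null(s)) 0L else s
  }, numeric(1)))
  out
}
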