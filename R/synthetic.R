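#' Specification for a synthetic annotated corpus
#'
#' Describes the statistical structure of a simulated literature
#' corpus: how many documents, how concept mentions are distributed
#' over the ten bioconcept classes, how popular individual concepts
#' are within a class (Zipf rank-frequency), how often a concept is
#' mentioned repeatedly within one document, which classes produce
#' identifier-less mentions and at what rate, the publication-year and
#' journal mix, MeSH keyword vocabulary, subheading membership
#' probabilities, and optional planted co-occurrence pairs with an
#' exact shared-document count.
#'
#' Defaults mirror the large annotated proteome-literature corpora the
#' pipeline is designed for, at desk scale: class mix proportional to
#' the observed per-class annotation totals (Species most frequent,
#' Strain rarest), identifier-less mentions only for CellLine,
#' Chemical and Disease at their observed rates (~11%, ~14.9%, ~4.6%),
#' publication years 1992-2021 with a rising trend, a dominant
#' specialist journal, and about 11 annotations per document.
#'
#' @param n_docs Number of documents (default 500).
#' @param vocab_sizes Named integer vector: per-class concept
#'   vocabulary size (all 10 classes).
#' @param class_weights Named numeric vector: relative probability
#'   that an annotation belongs to each class.
#' @param zipf_exponent Zipf exponent s > 0 for within-class concept
#'   popularity, P(rank r) proportional to r^-s (default 1).
#' @param ann_mean,ann_size Negative-binomial mean and size for the
#'   number of annotations per document (default mean 11, size 5).
#' @param mention_multiplicity Probability that a drawn concept is
#'   mentioned a second time in the same document (default 0.15).
#' @param no_id_rate Named numeric vector: per-class probability that
#'   a mention lacks an identifier; nonzero only for CellLine,
#'   Chemical, Disease by default.
#' @param years,year_weights Publication years and sampling weights
#'   (default 1992-2021, linearly rising).
#' @param journals,journal_weights Journal titles and weights; the
#'   first journal dominates by default.
#' @param subheadings Character vector of subheading set names.
#' @param subheading_probs Per-document membership probability for
#'   each subheading (memberships overlap; documents may fall under
#'   none).
#' @param mesh_vocab_size,mesh_per_doc MeSH keyword vocabulary size
#'   and mean headings per record (Zipf-weighted draws).
#' @param planted_pairs List of `list(key1, key2, n_docs)` entries;
#'   each pair of canonical keys is made to co-occur in exactly
#'   `n_docs` documents (both keys are removed from all other
#'   documents).
#' @param seed Integer seed; identical spec + seed gives a
#'   byte-identical corpus.
#' @return A `corpus_spec` object (validated list).
#' @export
corpus_spec <- function(n_docs = 500,
                        vocab_sizes = c(CellLine = 8, Chemical = 60,
                                        Disease = 45, DNAMutation = 6,
                                        Gene = 150, Genus = 4,
                                        ProteinMutation = 10, SNP = 5,
                                        Species = 50, Strain = 2),
                        class_weights = c(CellLine = 0.001, Chemical = 0.25,
                                          Disease = 0.237, DNAMutation = 0.0004,
                                          Gene = 0.203, Genus = 0.0001,
                                          ProteinMutation = 0.0012, SNP = 0.0001,
                                          Species = 0.305, Strain = 0.0001),
                        zipf_exponent = 1,
                        ann_mean = 11, ann_size = 5,
                        mention_multiplicity = 0.15,
                        no_id_rate = c(CellLine = 0.11, Chemical = 0.149,
                                       Disease = 0.046),
                        years = 1992:2021,
                        year_weights = seq_along(years),
                        journals = c("Proteomics", "J Proteome Res",
                                     "Mol Cell Proteomics", "J Proteomics",
                                     "PLoS One", "Sci Rep"),
                        journal_weights = c(5, 3, 2, 2, 1, 1),
                        subheadings = c("physiology", "metabolism", "genetics",
                                        "analysis", "chemistry", "immunology",
                                        "drug effects", "pharmacokinetics"),
                        subheading_probs = c(0.45, 0.40, 0.25, 0.20, 0.15,
                                             0.08, 0.05, 0.002),
                        mesh_vocab_size = 80, mesh_per_doc = 8,
                        planted_pairs = list(),
                        seed = 1L) {
  full_rate <- setNames(numeric(length(bioconcept_classes)), bioconcept_classes)
  full_rate[names(no_id_rate)] <- no_id_rate
  spec <- structure(
    list(
      n_docs = as.integer(n_docs),
      vocab_sizes = vocab_sizes[bioconcept_classes],
      class_weights = class_weights[bioconcept_classes],
      zipf_exponent = zipf_exponent,
      ann_mean = ann_mean, ann_size = ann_size,
      mention_multiplicity = mention_multiplicity,
      no_id_rate = full_rate,
      years = years, year_weights = year_weights,
      journals = journals, journal_weights = journal_weights,
      subheadings = subheadings, subheading_probs = subheading_probs,
      mesh_vocab_size = as.integer(mesh_vocab_size),
      mesh_per_doc = mesh_per_doc,
      planted_pairs = planted_pairs,
      seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
  validate_corpus_spec(spec)
}

validate_corpus_spec <- function(spec) {
  stopifnot(spec$n_docs >= 0L, spec$zipf_exponent > 0,
            all(!is.na(spec$vocab_sizes)), all(spec$vocab_sizes >= 1),
            all(!is.na(spec$class_weights)), all(spec$class_weights >= 0),
            sum(spec$class_weights) > 0,
            spec$mention_multiplicity >= 0, spec$mention_multiplicity <= 1,
            all(spec$no_id_rate >= 0), all(spec$no_id_rate <= 1),
            length(spec$year_weights) == length(spec$years),
            length(spec$journal_weights) == length(spec$journals),
            length(spec$subheading_probs) == length(spec$subheadings))
  for (pp in spec$planted_pairs) {
    stopifnot(length(pp) == 3L)
    if (pp[[3]] > spec$n_docs) {
      stop("infeasible spec: planted pair needs ", pp[[3]],
           " shared documents but corpus has only ", spec$n_docs, call. = FALSE)
    }
  }
  spec
}

zipf_weights <- function(n, s) {
  w <- (seq_len(n))^(-s)
  w / sum(w)
}

synthetic_key <- function(class, rank) {
  prefix <- c(CellLine = "CVCL:", Chemical = "MESH:C", Disease = "MESH:D",
              DNAMutation = "c.", Gene = "", Genus = "TXG", ProteinMutation = "p.",
              SNP = "rs", Species = "TX", Strain = "ST")
  id <- paste0(prefix[class], 1000L + rank)
  list(class = unname(class), id = unname(id),
       canonical = paste0(class, "_", id))
}

split_canonical <- function(key) {
  cls <- sub("_.*$", "", key)
  if (!cls %in% bioconcept_classes) {
    stop("planted key '", key, "' has no valid class prefix", call. = FALSE)
  }
  list(class = cls, id = sub("^[^_]+_", "", key))
}

#' Generate a synthetic annotated literature corpus
#'
#' Draws a full simulated corpus from a [corpus_spec()]: PubTator-style
#' annotated documents (with mention text spliced into placeholder
#' abstracts at recorded offsets, so the records are well-formed for
#' parser round trips), MEDLINE-style citation records (year, journal,
#' MeSH headings), per-subheading PMID membership lists, and a ground
#' truth ledger recording what was actually drawn: per-class
#' total/unique/no-ID tallies, year and journal tallies, planted-pair
#' shared-document counts, and the subheading membership lists.
#'
#' Planted pairs are enforced exactly: both keys are first removed
#' from all background documents, then injected together into a
#' random sample of exactly `n_docs` documents.
#'
#' A single random stream is used, seeded once from `spec$seed`; the
#' caller's RNG state is left untouched. Identical spec + seed yields
#' a byte-identical corpus.
#'
#' @param spec A [corpus_spec()].
#' @return List with elements `documents` (list of
#'   [annotated_document]), `citations` (tibble as from
#'   [parse_medline()]), `subheading_lists` (named list of PMID
#'   vectors) and `ledger` (ground-truth bookkeeping).
#' @export
generate_corpus <- function(spec) {
  validate_corpus_spec(spec)
  with_local_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n <- spec$n_docs
  if (n == 0L) {
    return(list(documents = list(),
                citations = parse_medline(character()),
                subheading_lists = setNames(
                  rep(list(character()), length(spec$subheadings)),
                  spec$subheadings),
                ledger = list(concept_stats = concept_stats(list()),
                              year_counts = integer(), journal_counts = integer(),
                              planted = list(), membership = list(),
                              mesh_record_counts = integer())))
  }
  pmids <- sprintf("SYN%06d", seq_len(n))

  # --- per-document concept draws ---
  cw <- spec$class_weights / sum(spec$class_weights)
  doc_keys <- vector("list", n)     # list of data.frames: class,id,canonical,noid
  for (d in seq_len(n)) {
    k <- stats::rnbinom(1, mu = spec$ann_mean, size = spec$ann_size)
    if (k == 0L) { doc_keys[[d]] <- NULL; next }
    classes <- sample(bioconcept_classes, k, replace = TRUE, prob = cw)
    ranks <- vapply(classes, function(cl) {
      v <- spec$vocab_sizes[[cl]]
      sample.int(v, 1L, prob = zipf_weights(v, spec$zipf_exponent))
    }, integer(1))
    noid <- stats::runif(k) < spec$no_id_rate[classes]
    rows <- lapply(seq_len(k), function(i) {
      if (noid[i]) {
        data.frame(class = classes[i], id = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        sk <- synthetic_key(classes[i], ranks[i])
        data.frame(class = sk$class, id = sk$id, stringsAsFactors = FALSE)
      }
    })
    df <- do.call(rbind, rows)
    # repeat mentions
    rep_extra <- df[stats::runif(k) < spec$mention_multiplicity, , drop = FALSE]
    doc_keys[[d]] <- rbind(df, rep_extra)
  }

  # --- planted pairs: strip every planted key from the background once,
  # then inject each pair into its sampled documents (a key shared by
  # several pairs, e.g. a planted hub, keeps all its injections) ---
  planted <- list()
  if (length(spec$planted_pairs)) {
    keysets <- lapply(spec$planted_pairs, function(pp) {
      k1 <- split_canonical(pp[[1]]); k2 <- split_canonical(pp[[2]])
      list(k1 = k1, k2 = k2,
           can1 = paste0(k1$class, "_", k1$id),
           can2 = paste0(k2$class, "_", k2$id))
    })
    all_planted <- unique(unlist(lapply(keysets, function(k) c(k$can1, k$can2))))
    for (d in seq_len(n)) {
      df <- doc_keys[[d]]
      if (is.null(df)) next
      can <- canonical_label(df$class, df$id)
      drop <- !is.na(can) & can %in% all_planted
      if (any(drop)) doc_keys[[d]] <- df[!drop, , drop = FALSE]
    }
    for (i in seq_along(spec$planted_pairs)) {
      ks <- keysets[[i]]
      target <- sample.int(n, spec$planted_pairs[[i]][[3]])
      for (d in target) {
        have <- canonical_label(doc_keys[[d]]$class, doc_keys[[d]]$id)
        add_can <- setdiff(c(ks$can1, ks$can2), have)
        if (length(add_can)) {
          which_add <- match(add_can, c(ks$can1, ks$can2))
          add <- data.frame(
            class = c(ks$k1$class, ks$k2$class)[which_add],
            id = c(ks$k1$id, ks$k2$id)[which_add],
            stringsAsFactors = FALSE)
          doc_keys[[d]] <- rbind(doc_keys[[d]], add)
        }
      }
      planted[[i]] <- list(key1 = ks$can1, key2 = ks$can2,
                           n_shared = length(target),
                           docs = pmids[sort(target)])
    }
  }

  # --- materialise documents with spliced mention text ---
  documents <- vector("list", n)
  for (d in seq_len(n)) {
    df <- doc_keys[[d]]
    title <- paste0("Synthetic proteome study ", pmids[d], ".")
    if (is.null(df) || nrow(df) == 0L) {
      documents[[d]] <- annotated_document(pmids[d], title,
                                           "No entities were annotated.")
      next
    }
    mention <- ifelse(is.na(df$id),
                      paste0("unreg-", tolower(df$class)),
                      paste0("ent-", tolower(gsub("[^A-Za-z0-9]", "", df$id))))
    # abstract = mentions joined by single spaces; offsets in title+sep+abstract
    offs <- cumsum(c(0L, nchar(mention) + 1L))[seq_along(mention)]
    base <- nchar(title) + 1L   # 1-char separator after title
    ann <- data.frame(start = base + offs,
                      end = base + offs + nchar(mention),
                      mention = mention, class = df$class, id = df$id,
                      stringsAsFactors = FALSE)
    documents[[d]] <- annotated_document(pmids[d], title,
                                         paste(mention, collapse = " "), ann)
  }

  # --- citations ---
  years <- sample(spec$years, n, replace = TRUE,
                  prob = spec$year_weights / sum(spec$year_weights))
  journals <- sample(spec$journals, n, replace = TRUE,
                     prob = spec$journal_weights / sum(spec$journal_weights))
  mesh_w <- zipf_weights(spec$mesh_vocab_size, spec$zipf_exponent)
  mesh_vocab <- sprintf("keyword %02d", seq_len(spec$mesh_vocab_size))
  mesh <- lapply(seq_len(n), function(d) {
    k <- min(spec$mesh_vocab_size,
             max(1L, stats::rpois(1, spec$mesh_per_doc)))
    sort(sample(mesh_vocab, k, prob = mesh_w))
  })
  citations <- tibble(
    pmid = pmids, year = as.integer(years),
    journal_full = journals,
    journal_abbrev = unname(abbreviate(journals, minlength = 8, dot = FALSE)),
    mesh = mesh
  )
  attr(citations, "skipped") <- 0L

  # --- subheading membership ---
  member <- matrix(FALSE, n, length(spec$subheadings),
                   dimnames = list(pmids, spec$subheadings))
  for (s in seq_along(spec$subheadings)) {
    member[, s] <- stats::runif(n) < spec$subheading_probs[s]
  }
  subheading_lists <- lapply(seq_along(spec$subheadings),
                             function(s) pmids[member[, s]])
  names(subheading_lists) <- spec$subheadings

  # --- ground-truth ledger (direct tallies over what was drawn) ---
  all_ann <- do.call(rbind, c(Filter(Negate(is.null), doc_keys),
                              list(data.frame(class = character(),
                                              id = character(),
                                              stringsAsFactors = FALSE))))
  can <- canonical_label(all_ann$class, all_ann$id)
  led_stats <- tibble(
    class = bioconcept_classes,
    total = as.integer(table(factor(all_ann$class, levels = bioconcept_classes))),
    unique = as.integer(table(factor(
      sub("_.*$", "", unique(can[!is.na(can)])), levels = bioconcept_classes))),
    no_id = as.integer(table(factor(all_ann$class[is.na(all_ann$id)],
                                    levels = bioconcept_classes)))
  )
  ledger <- list(
    concept_stats = led_stats,
    year_counts = table(years),
    journal_counts = table(journals),
    planted = planted,
    membership = member,
    mesh_record_counts = table(unlist(lapply(mesh, unique)))
  )
  list(documents = documents, citations = citations,
       subheading_lists = subheading_lists, ledger = ledger)
}

#' The 43-bioconcept maximum-profile document
#'
#' Constructs a single annotated document with exactly 43 unique
#' ID-bearing bioconcepts: 32 genes, 8 chemicals, 2 diseases and one
#' species — the per-article annotation maximum profile observed in
#' large annotated proteome corpora. Useful as a boundary fixture for
#' per-document concept extraction.
#'
#' @param seed Integer seed (affects only the synthetic PMID; the
#'   profile is deterministic).
#' @return An [annotated_document] with 43 annotations.
#' @export
fixture_43 <- function(seed = 1L) {
  counts <- c(Gene = 32L, Chemical = 8L, Disease = 2L, Species = 1L)
  rows <- dplyr::bind_rows(lapply(names(counts), function(cl) {
    ks <- lapply(seq_len(counts[[cl]]), synthetic_key, class = cl)
    tibble(class = cl, id = vapply(ks, `[[`, character(1), "id"))
  }))
  mention <- paste0("ent-", tolower(gsub("[^A-Za-z0-9]", "", rows$id)))
  title <- sprintf("Synthetic maximum-annotation document %d.", as.integer(seed))
  offs <- cumsum(c(0L, nchar(mention) + 1L))[seq_along(mention)]
  base <- nchar(title) + 1L
  ann <- data.frame(start = base + offs, end = base + offs + nchar(mention),
                    mention = mention, class = rows$class, id = rows$id,
                    stringsAsFactors = FALSE)
  annotated_document(sprintf("SYNMAX%04d", as.integer(seed)), title,
                     paste(mention, collapse = " "), ann)
}

#' Write a generated corpus to disk
#'
#' Serialises the three inputs of the pipeline: the PubTator
#' annotation file, the MEDLINE citation file and one PMID list per
#' subheading (plain text, one PMID per line).
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subdir <- file.path(dir, "subheadings")
  dir.create(subdir, showWarnings = FALSE)
  pub <- file.path(dir, "annotations.pubtator")
  write_pubtator(corpus$documents, pub)
  med <- file.path(dir, "citations.medline")
  writeLines(format_medline(corpus$citations), med)
  lists <- vapply(names(corpus$subheading_lists), function(s) {
    p <- file.path(subdir, paste0(gsub("[^A-Za-z0-9]+", "_", s), ".txt"))
    writeLines(corpus$subheading_lists[[s]], p)
    p
  }, character(1))
  invisible(list(annotations = pub, citations = med, subheading_lists = lists))
}

# minimal MEDLINE writer for synthetic citations (round-trips through
# parse_medline for the fields the pipeline uses)
format_medline <- function(citations) {
  unlist(lapply(seq_len(nrow(citations)), function(i) {
    r <- citations[i, ]
    c(paste0("PMID- ", r$pmid),
      paste0("DP  - ", ifelse(is.na(r$year), "unknown", paste0(r$year, " Jan"))),
      paste0("TA  - ", r$journal_abbrev),
      paste0("JT  - ", r$journal_full),
      paste0("MH  - ", r$mesh[[1]]),
      "")
  }))
}
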