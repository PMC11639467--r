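#' Match a vocabulary against a record's MeSH descriptors
#'
#' A vocabulary term matches when its canonical form equals the canonical
#' descriptor name of at least one MeSH heading of the record; qualifiers
#' and the major-topic marker are ignored. Descriptor names are folded
#' through the vocabulary's synonym map before comparison, so a variant
#' spelling on the record side still hits the canonical term.
#'
#' @param record one record: either a one-row slice of a record table or a
#'   list with a `mesh` element.
#' @param vocab a [vocabulary()].
#' @return Character vector of matched canonical terms (subset of
#'   `vocab$terms`).
#' @export
match_mesh <- function(record, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  mesh <- if (is.data.frame(record)) record$mesh[[1L]] else record$mesh
  if (is.null(mesh) || nrow(mesh) == 0L) return(character(0))
  names <- apply_synonyms(mesh$name, vocab$synonyms)
  sort(intersect(names, vocab$terms))
}

# Build one regex per vocabulary term that matches the term as a whole
# phrase: no alphanumeric character may directly precede or follow it
# ("painstaking" does not contain "pain"), and any run of non-alphanumeric
# characters stands in for internal whitespace ("neck-pain" matches
# "neck pain"). Synonym variants of a term are folded into its pattern.
term_patterns <- function(vocab) {
  variants <- lapply(vocab$terms, function(term) {
    v <- term
    if (!is.null(vocab$synonyms)) {
      v <- c(v, names(vocab$synonyms)[vocab$synonyms == term])
    }
    v
  })
  vapply(variants, function(v) {
    alts <- vapply(v, function(t) {
      words <- strsplit(t, " ", fixed = TRUE)[[1]]
      words <- vapply(words, function(w)
        gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", w), character(1))
      paste(words, collapse = "[^[:alnum:]]+")
    }, character(1))
    sprintf("(?<![[:alnum:]])(%s)(?![[:alnum:]])",
            paste(alts, collapse = "|"))
  }, character(1))
}

#' Match a vocabulary against a record's abstract text
#'
#' Case-insensitive whole-phrase matching at word boundaries: a term matches
#' only where no alphanumeric character directly precedes or follows it, and
#' internal whitespace of multi-word terms matches any run of
#' non-alphanumeric characters (hyphens, line-wrap artefacts). Intended for
#' `mesh_and_abstract` vocabularies (clinical signs, pain types).
#'
#' @inheritParams match_mesh
#' @return Character vector of matched canonical terms.
#' @export
match_abstract <- function(record, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  abstract <- if (is.data.frame(record)) record$abstract[[1L]] else record$abstract
  if (is.null(abstract) || is.na(abstract) || !nzchar(abstract)) return(character(0))
  pats <- term_patterns(vocab)
  hit <- vapply(pats, grepl, logical(1), x = abstract,
                perl = TRUE, ignore.case = TRUE)
  sort(vocab$terms[hit])
}

#' Annotate a corpus against a set of vocabularies
#'
#' For every record and category, collects the vocabulary terms matched in
#' the record's MeSH descriptor list and — for `mesh_and_abstract`
#' vocabularies — in its abstract text. A term counts once per record and
#' category however many surfaces it matched; the surfaces are recorded.
#' Deterministic, and independent of record order up to the corresponding
#' permutation of rows.
#'
#' @param corp a [corpus()].
#' @param vocabularies a list of [vocabulary()] objects (e.g.
#'   [default_vocabularies()]); categories must be unique.
#' @return An object of class `corpus_annotation`: `species_label`,
#'   `n_records`, `pmids` (in corpus order), `vocabularies`, and `hits`, a
#'   tibble with one row per (pmid, category, term) and logical columns
#'   `in_mesh`, `in_abstract`.
#' @export
annotate_corpus <- function(corp, vocabularies) {
  stopifnot(inherits(corp, "corpus"), is.list(vocabularies),
            length(vocabularies) > 0L)
  stopifnot(all(vapply(vocabularies, inherits, logical(1), "vocabulary")))
  cats <- vapply(vocabularies, `[[`, character(1), "category")
  if (anyDuplicated(cats)) stop("duplicate vocabulary categories", call. = FALSE)
  names(vocabularies) <- cats
  records <- corp$records
  n <- nrow(records)

  per_vocab <- lapply(vocabularies, function(vocab) {
    if (n == 0L) {
      return(tibble::tibble(pmid = character(0), category = character(0),
                            term = character(0), in_mesh = logical(0),
                            in_abstract = logical(0)))
    }
    # MeSH surface: canonical descriptor names intersected with the term set.
    mesh_terms <- lapply(records$mesh, function(m) {
      if (is.null(m) || nrow(m) == 0L) return(character(0))
      intersect(apply_synonyms(m$name, vocab$synonyms), vocab$terms)
    })
    # Abstract surface, only where the vocabulary allows it: one regex per
    # term, vectorized over all abstracts.
    abs_terms <- rep(list(character(0)), n)
    if (vocab$surface == "mesh_and_abstract") {
      pats <- term_patterns(vocab)
      nonempty <- !is.na(records$abstract) & nzchar(records$abstract)
      if (any(nonempty)) {
        hitmat <- vapply(pats, grepl, logical(sum(nonempty)),
                         x = records$abstract[nonempty],
                         perl = TRUE, ignore.case = TRUE)
        hitmat <- matrix(hitmat, nrow = sum(nonempty))
        idx <- which(nonempty)
        for (j in seq_along(idx)) {
          abs_terms[[idx[j]]] <- vocab$terms[hitmat[j, ]]
        }
      }
    }
    terms_list <- mapply(function(a, b) sort(unique(base::c(a, b))),
                         mesh_terms, abs_terms, SIMPLIFY = FALSE)
    len <- lengths(terms_list)
    if (sum(len) == 0L) return(NULL)
    rec_idx <- rep.int(seq_len(n), len)
    term <- unlist(terms_list, use.names = FALSE)
    in_mesh <- unlist(mapply(`%in%`, terms_list, mesh_terms, SIMPLIFY = FALSE),
                      use.names = FALSE)
    in_abstract <- unlist(mapply(`%in%`, terms_list, abs_terms, SIMPLIFY = FALSE),
                          use.names = FALSE)
    tibble::tibble(pmid = records$pmid[rec_idx], category = vocab$category,
                   term = term, in_mesh = in_mesh, in_abstract = in_abstract)
  })
  per_vocab <- per_vocab[!vapply(per_vocab, is.null, logical(1))]
  hits <- if (length(per_vocab) == 0L) {
    tibble::tibble(pmid = character(0), category = character(0),
                   term = character(0), in_mesh = logical(0),
                   in_abstract = logical(0))
  } else {
    tibble::as_tibble(do.call(rbind, per_vocab))
  }
  # Canonical row order: corpus record order, then category, then term.
  ord <- order(match(hits$pmid, records$pmid), hits$category, hits$term)
  hits <- hits[ord, , drop = FALSE]

  structure(
    list(species_label = corp$species_label, n_records = n,
         pmids = records$pmid, vocabularies = vocabularies, hits = hits),
    class = "corpus_annotation"
  )
}

#' @export
print.corpus_annotation <- function(x, ...) {
  cat(sprintf("<corpus_annotation> %s: %d records, %d hits over %d categories\n",
              x$species_label, x$n_records, nrow(x$hits),
              length(x$vocabularies)))
  invisible(x)
}

#' Write an annotation audit table
#'
#' One TSV row per (pmid, category, term) with the surfaces it matched on.
#'
#' @param annotation a `corpus_annotation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(inherits(annotation, "corpus_annotation"))
  h <- annotation$hits
  h$surfaces <- paste0(ifelse(h$in_mesh, "mesh", ""),
                       ifelse(h$in_mesh & h$in_abstract, ",", ""),
                       ifelse(h$in_abstract, "abstract", ""))
  utils::write.table(h[, c("pmid", "category", "term", "surfaces")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal accessor with category validation, shared by the statistics layer.
category_hits <- function(annotation, category) {
  stopifnot(inherits(annotation, "corpus_annotation"))
  if (!category %in% names(annotation$vocabularies)) {
    stop(sprintf("category '%s' was not annotated (have: %s)", category,
                 paste(names(annotation$vocabularies), collapse = ", ")),
         call. = FALSE)
  }
  annotation$hits[annotation$hits$category == category, , drop = FALSE]
}
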