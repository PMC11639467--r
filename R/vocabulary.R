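#' Canonicalize a term string
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal runs
#' of whitespace to a single space. All vocabulary terms, MeSH descriptor
#' names and synonym entries pass through this normalization so that
#' "exact match" means equality of canonical forms. Idempotent.
#'
#' @param raw character vector of terms.
#' @return Character vector of canonical terms.
#' @examples
#' normalize_term("  Kidney  Failure, Chronic ")
#' @export
normalize_term <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  stopifnot(is.character(raw))
  out <- tolower(trimws(gsub("[[:space:]]+", " ", raw)))
  if (any(is.na(raw)) || any(!nzchar(out)))
    stop("empty or whitespace-only term", call. = FALSE)
  out
}

#' Construct a category vocabulary
#'
#' A vocabulary is the canonical term set of one mining category together
#' with its matching surface: `mesh_only` categories (diseases, methods,
#' cells, cytokines, tissues) are matched against record MeSH descriptors
#' only; `mesh_and_abstract` categories (clinical signs, pain types) are
#' additionally searched in the abstract text. The number of terms is the
#' category's term universe, used as the background population of the Fisher
#' overlap test.
#'
#' An optional synonym map (named character vector, variant -> canonical)
#' folds spelling variants onto canonical terms; variants are folded both
#' when loading the term list and when matching record text, so e.g. an
#' "anemia" descriptor can hit the canonical term "anaemia".
#'
#' @param terms character vector of terms (canonicalized and de-duplicated
#'   here).
#' @param category category label, e.g. `"disease"` or `"clinical_sign"`.
#' @param surface `"mesh_only"` or `"mesh_and_abstract"`.
#' @param synonyms named character vector mapping variant to canonical form,
#'   or `NULL`.
#' @return An object of class `vocabulary` with fields `category`, `terms`
#'   (sorted), `surface`, `synonyms` and `universe_size`.
#' @export
vocabulary <- function(terms, category,
                       surface = c("mesh_only", "mesh_and_abstract"),
                       synonyms = NULL) {
  surface <- match.arg(surface)
  stopifnot(is.character(category), length(category) == 1L, nzchar(category))
  terms <- normalize_term(terms)
  if (!is.null(synonyms)) {
    stopifnot(is.character(synonyms), !is.null(names(synonyms)))
    names(synonyms) <- normalize_term(names(synonyms))
    synonyms[] <- normalize_term(synonyms)
    terms <- apply_synonyms(terms, synonyms)
  }
  dup <- duplicated(terms)
  if (any(dup)) {
    message(sprintf("vocabulary '%s': folded %d duplicate term(s)",
                    category, sum(dup)))
  }
  terms <- sort(unique(terms))
  if (length(terms) == 0L) stop("vocabulary has no usable terms", call. = FALSE)
  structure(
    list(category = category, terms = terms, surface = surface,
         synonyms = synonyms, universe_size = length(terms)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %s: %d terms, surface = %s\n",
              x$category, x$universe_size, x$surface))
  invisible(x)
}

# Map variant spellings to canonical terms; unmapped terms pass through.
apply_synonyms <- function(terms, synonyms) {
  if (is.null(synonyms) || length(synonyms) == 0L) return(terms)
  hit <- terms %in% names(synonyms)
  terms[hit] <- unname(synonyms[terms[hit]])
  terms
}

#' Load a vocabulary from a term-list file
#'
#' One term per line, UTF-8; blank lines and lines starting with `#` are
#' ignored. Duplicate lines (after canonicalization and synonym folding) are
#' reported and folded. Loading is order-independent: permuting the lines of
#' the file yields an identical vocabulary.
#'
#' @inheritParams vocabulary
#' @param path term-list file.
#' @return A `vocabulary`.
#' @export
load_vocabulary <- function(path, category,
                            surface = c("mesh_only", "mesh_and_abstract"),
                            synonyms = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop(sprintf("no usable terms in '%s'", path), call. = FALSE)
  vocabulary(lines, category, surface, synonyms)
}

#' Load a synonym table
#'
#' Two tab-separated columns: variant, canonical. `#` lines are comments.
#'
#' @param path synonym file.
#' @return Named character vector (names = variants, values = canonical).
#' @export
load_synonyms <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("synonym line without two tab-separated columns: \"%s\"",
                 lines[bad][1L]), call. = FALSE)
  stats::setNames(
    normalize_term(vapply(parts, `[[`, character(1), 2L)),
    normalize_term(vapply(parts, `[[`, character(1), 1L))
  )
}

#' Default category vocabularies shipped with the package
#'
#' Loads the term lists under `inst/extdata/vocab/`. The clinical-sign and
#' pain lists cover the signs and pain types central to renal-disease
#' literature mining (anaemia, vomiting, haemorrhage, polyuria, ...,
#' musculoskeletal pain); the remaining category lists (disease, method,
#' cell, cytokine, tissue) are compact reconstructed samples intended for
#' synthetic corpora and examples, not complete controlled vocabularies —
#' replace them with full published lists for real corpora. British/American
#' spelling variants are folded through the shipped synonym table (e.g.
#' anemia -> anaemia) unless `use_synonyms = FALSE`.
#'
#' Surfaces follow the mining design: clinical signs and pain are matched in
#' both the MeSH list and the abstract text; all other categories in MeSH
#' only.
#'
#' @param categories which categories to load.
#' @param use_synonyms fold spelling variants via the shipped synonym table.
#' @return Named list of `vocabulary` objects.
#' @export
default_vocabularies <- function(categories = c("disease", "method", "cell",
                                                "cytokine", "tissue",
                                                "clinical_sign", "pain"),
                                 use_synonyms = TRUE) {
  dir <- system.file("extdata", "vocab", package = "renalmine")
  if (!nzchar(dir)) stop("shipped vocabularies not found", call. = FALSE)
  syn <- if (use_synonyms) load_synonyms(file.path(dir, "synonyms_gb_us.tsv")) else NULL
  abstract_cats <- c("clinical_sign", "pain")
  out <- lapply(categories, function(cat) {
    load_vocabulary(
      file.path(dir, paste0(cat, ".txt")), cat,
      surface = if (cat %in% abstract_cats) "mesh_and_abstract" else "mesh_only",
      synonyms = syn
    )
  })
  stats::setNames(out, categories)
}
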