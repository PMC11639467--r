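#' Terms of a category captured anywhere in a corpus
#'
#' The capture set of a category is the union, over all records, of the
#' vocabulary terms matched in that category — the quantity whose size is
#' compared between species in the overlap test.
#'
#' @param annotation a `corpus_annotation` from [annotate_corpus()].
#' @param category category label.
#' @return Sorted character vector of captured terms.
#' @export
captured_terms <- function(annotation, category) {
  sort(unique(category_hits(annotation, category)$term))
}

#' Per-term record counts
#'
#' For each captured term of a category, the number of distinct records
#' mentioning it (a record contributes at most once per term).
#'
#' @inheritParams captured_terms
#' @return A tibble with columns `term` and `count`, sorted by decreasing
#'   count and then alphabetically.
#' @export
term_frequencies <- function(annotation, category) {
  h <- category_hits(annotation, category)
  if (nrow(h) == 0L) return(tibble::tibble(term = character(0), count = integer(0)))
  tab <- table(h$term)
  out <- tibble::tibble(term = names(tab), count = as.integer(tab))
  out[order(-out$count, out$term), , drop = FALSE]
}

#' Top-ranked terms by record count
#'
#' Terms with at least `min_count` records, ranked by decreasing count with
#' alphabetical tie-break, truncated to the top `k`. The conventional report
#' uses the top 10 terms with at least 10 records each (fewer where the
#' corpus is small).
#'
#' @param freqs a frequency table from [term_frequencies()].
#' @param k maximum number of terms returned.
#' @param min_count minimum record count for a term to qualify.
#' @return The qualifying rows of `freqs`, ranked and truncated.
#' @export
top_terms <- function(freqs, k = 10L, min_count = 10L) {
  stopifnot(is.data.frame(freqs), k >= 1L, min_count >= 0L)
  keep <- freqs[freqs$count >= min_count, , drop = FALSE]
  keep <- keep[order(-keep$count, keep$term), , drop = FALSE]
  utils::head(keep, k)
}

#' Publication counts per year
#'
#' @param corp a [corpus()].
#' @return A list: `per_year`, a tibble with columns `year` and `count`
#'   sorted by year, and `n_no_year`, the number of records without a
#'   publication year (excluded from the trend).
#' @export
publications_per_year <- function(corp) {
  stopifnot(inherits(corp, "corpus"))
  years <- corp$records$year
  known <- years[!is.na(years)]
  per_year <- if (length(known) == 0L) {
    tibble::tibble(year = integer(0), count = integer(0))
  } else {
    tab <- table(known)
    tibble::tibble(year = as.integer(names(tab)), count = as.integer(tab))
  }
  list(per_year = per_year, n_no_year = sum(is.na(years)))
}

# Log-space hypergeometric machinery ----------------------------------------
#
# The overlap test conditions on the capture-count margins of the 2x2 table
#   a = captured in both corpora          b = first corpus only
#   c = second corpus only                d = in neither
# over the category term universe N = a+b+c+d. All point probabilities are
# computed through lgamma so p-values far below the smallest normal double
# (the strongest associations reach ~1e-313) remain meaningful through their
# log10.

# log-sum-exp, guarded against -Inf inputs.
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Log point probabilities of every feasible table with margins
# (nA = a+b, nB = a+c, N), indexed by the common count k.
hyper_log_pmf <- function(N, nA, nB) {
  lo <- max(0L, nA + nB - N)
  hi <- min(nA, nB)
  k <- lo:hi
  lp <- lchoose(nA, k) + lchoose(N - nA, nB - k) - lchoose(N, nB)
  list(k = k, lp = lp)
}

# Relative slack when comparing point probabilities in the two-sided rule,
# matching the convention of standard exact-test implementations.
.fisher_point_slack <- 1e-7

#' Fisher exact test on a 2x2 table, in log space
#'
#' Conditional exact test on a 2x2 contingency table with fixed margins.
#' `alternative = "greater"` sums the point probabilities of all tables with
#' a common count at least the observed one (association / overlap
#' enrichment); `"less"` the lower tail; `"two.sided"` uses the
#' point-probability rule — every table whose probability does not exceed
#' the observed table's (within a relative slack of 1e-7) contributes.
#' All mass is computed through log-gamma, so p-values below the smallest
#' normal double are still exact on the log10 scale (the linear `p`
#' underflows to 0 there).
#'
#' @param a,b,c,d the four cell counts.
#' @param alternative `"greater"`, `"two.sided"` or `"less"`.
#' @return A list with `p` (capped at 1) and `log10_p`.
#' @seealso [two_sided_fisher()], [fisher_overlap_test()]
#' @export
fisher_exact_log <- function(a, b, c, d,
                             alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  # the cell count argument `c` masks base::c in this scope
  counts <- base::c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  N <- a + b + c + d
  nA <- a + b
  nB <- a + c
  if (N == 0L) return(list(p = 1, log10_p = 0))
  pmf <- hyper_log_pmf(N, nA, nB)
  obs <- pmf$lp[pmf$k == a]
  sel <- switch(alternative,
    greater = pmf$k >= a,
    less = pmf$k <= a,
    two.sided = pmf$lp <= obs + log1p(.fisher_point_slack)
  )
  lp <- logsumexp(pmf$lp[sel])
  lp <- min(lp, 0)
  list(p = min(exp(lp), 1), log10_p = lp / log(10))
}

#' Two-sided Fisher exact test (point-probability rule)
#'
#' Convenience wrapper for [fisher_exact_log()] with
#' `alternative = "two.sided"`: the two-sided p-value is the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability is at most the observed table's, within a relative slack of
#' 1e-7.
#'
#' @inheritParams fisher_exact_log
#' @return A list with `p` and `log10_p`.
#' @export
two_sided_fisher <- function(a, b, c, d) {
  fisher_exact_log(a, b, c, d, alternative = "two.sided")
}

#' Fisher overlap test between two corpora on a category universe
#'
#' Tests whether the sets of category terms captured in two corpora overlap
#' more than expected if each corpus captured terms independently, with the
#' category's full term universe as the background population. The 2x2 table
#' is (common, first-only, second-only, neither), and the default
#' one-sided `"greater"` alternative asks for overlap enrichment — the
#' convention under which the published renal-disease comparisons (e.g.
#' clinical signs human–cat p = 0.18, cytokines human–cat p = 0.20) are
#' reproduced from their printed counts.
#'
#' @param category category label (used in messages and the result).
#' @param universe_size number of terms in the category vocabulary (the
#'   background N).
#' @param captured_first,captured_second numbers of terms captured in each
#'   corpus.
#' @param common number of terms captured in both.
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @return An object of class `category_comparison`: the input counts, the
#'   2x2 `table` (a, b, c, d), `p` and `log10_p`.
#' @export
fisher_overlap_test <- function(category, universe_size, captured_first,
                                captured_second, common,
                                alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  a <- common
  b <- captured_first - common
  c <- captured_second - common
  d <- universe_size - captured_first - captured_second + common
  if (common > min(captured_first, captured_second) ||
      max(captured_first, captured_second) > universe_size ||
      b < 0 || c < 0 || d < 0 || universe_size < 1) {
    stop(sprintf("inconsistent capture counts for category '%s'", category),
         call. = FALSE)
  }
  res <- fisher_exact_log(a, b, c, d, alternative = alternative)
  structure(
    list(category = category, universe_size = universe_size,
         captured_first = captured_first, captured_second = captured_second,
         common = common, table = base::c(a = a, b = b, c = c, d = d),
         alternative = alternative, p = res$p, log10_p = res$log10_p),
    class = "category_comparison"
  )
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf(
    "<category_comparison> %s: N=%d, captured %d vs %d, common %d, p=%s (log10 p=%.3f, %s)\n",
    x$category, x$universe_size, x$captured_first, x$captured_second,
    x$common, format(signif(x$p, 3)), x$log10_p, x$alternative))
  invisible(x)
}

#' Category overlap comparison table from capture counts
#'
#' Comparison-only entry point: applies [fisher_overlap_test()] row-wise to a
#' table of pre-tabulated counts, decoupling the overlap statistics from
#' corpus availability. Input columns: `category`, `universe_size`,
#' `captured_first`, `captured_second`, `common` (an optional `comparison`
#' column labels each row, e.g. `"human_vs_cat"`).
#'
#' @param counts data frame of capture counts, one comparison per row.
#' @inheritParams fisher_overlap_test
#' @return The input tibble with `p` and `log10_p` columns appended.
#' @export
category_comparison_table <- function(counts,
                                      alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  need <- c("category", "universe_size", "captured_first", "captured_second",
            "common")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    fisher_overlap_test(counts$category[[i]], counts$universe_size[[i]],
                        counts$captured_first[[i]], counts$captured_second[[i]],
                        counts$common[[i]], alternative = alternative)
  })
  out <- tibble::as_tibble(counts)
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$log10_p <- vapply(res, `[[`, numeric(1), "log10_p")
  out
}

#' Compare captured category terms between two annotated corpora
#'
#' Computes the capture sets of both corpora for a category and runs the
#' overlap test on their sizes against the category universe.
#'
#' @param annotation_first,annotation_second `corpus_annotation` objects
#'   sharing the category's vocabulary.
#' @param category category label.
#' @inheritParams fisher_overlap_test
#' @return A `category_comparison`.
#' @export
compare_capture <- function(annotation_first, annotation_second, category,
                            alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  s1 <- captured_terms(annotation_first, category)
  s2 <- captured_terms(annotation_second, category)
  N <- annotation_first$vocabularies[[category]]$universe_size
  fisher_overlap_test(category, N, length(s1), length(s2),
                      length(intersect(s1, s2)), alternative = alternative)
}

#' Three-set overlap regions over a term universe
#'
#' Counts the seven Venn regions of three capture sets plus the remainder of
#' the universe outside their union, and the share of the union lying in the
#' triple intersection. The overlap percentage is reported with two
#' denominators: the union of the three capture sets (default headline
#' figure) and the full universe.
#'
#' @param sets named list of three character vectors (capture sets).
#' @param universe_size size of the category term universe.
#' @return A list with `regions` (named counts `n100`, `n010`, `n001`,
#'   `n110`, `n101`, `n011`, `n111` in the order of `sets`), `remainder`,
#'   `triple_over_union` and `triple_over_universe` (proportions in [0, 1]).
#' @export
three_way_overlap <- function(sets, universe_size) {
  stopifnot(is.list(sets), length(sets) == 3L)
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets, use.names = FALSE))
  if (length(u) > universe_size)
    stop("capture sets exceed the stated universe size", call. = FALSE)
  if (length(u) == 0L) {
    zero <- stats::setNames(integer(7), c("n100", "n010", "n001", "n110",
                                          "n101", "n011", "n111"))
    return(list(regions = zero, remainder = universe_size,
                triple_over_union = NA_real_, triple_over_universe = 0))
  }
  inset <- vapply(sets, function(s) u %in% s, logical(length(u)))
  inset <- matrix(inset, nrow = length(u))
  code <- inset[, 1] * 4L + inset[, 2] * 2L + inset[, 3]
  cnt <- function(x) if (length(u) == 0L) 0L else sum(code == x)
  regions <- c(n100 = cnt(4L), n010 = cnt(2L), n001 = cnt(1L),
               n110 = cnt(6L), n101 = cnt(5L), n011 = cnt(3L),
               n111 = cnt(7L))
  triple <- regions[["n111"]]
  list(
    regions = regions,
    remainder = universe_size - length(u),
    triple_over_union = if (length(u) == 0L) NA_real_ else triple / length(u),
    triple_over_universe = triple / universe_size
  )
}

#' Per-term mention proportions of a category
#'
#' Term record counts divided either by the number of records mentioning at
#' least one term of the category (`"records_with_any_hit"`, the default, as
#' used for clinical-sign profiles) or by the corpus size.
#'
#' @inheritParams captured_terms
#' @param denominator `"records_with_any_hit"` or `"corpus_size"`.
#' @return A tibble with columns `term`, `count`, `proportion`.
#' @export
sign_proportions <- function(annotation, category,
                             denominator = c("records_with_any_hit", "corpus_size")) {
  denominator <- match.arg(denominator)
  freqs <- term_frequencies(annotation, category)
  h <- category_hits(annotation, category)
  den <- switch(denominator,
                records_with_any_hit = length(unique(h$pmid)),
                corpus_size = annotation$n_records)
  if (den == 0L) {
    warning(sprintf("no records in the '%s' denominator", denominator),
            call. = FALSE)
    return(tibble::tibble(term = character(0), count = integer(0),
                          proportion = numeric(0)))
  }
  freqs$proportion <- freqs$count / den
  freqs
}

#' Relative term association between two corpora
#'
#' For every term of a category captured in either corpus, pairs its mention
#' proportion in each corpus (0 where absent) and flags which side is
#' higher — the data behind scatter comparisons of term usage between
#' species.
#'
#' @inheritParams compare_capture
#' @inheritParams sign_proportions
#' @return A tibble with columns `term`, `prop_first`, `prop_second`,
#'   `side` (`"first_higher"`, `"second_higher"` or `"equal"`).
#' @export
relative_association_table <- function(annotation_first, annotation_second,
                                       category,
                                       denominator = c("records_with_any_hit",
                                                       "corpus_size")) {
  denominator <- match.arg(denominator)
  p1 <- suppressWarnings(sign_proportions(annotation_first, category, denominator))
  p2 <- suppressWarnings(sign_proportions(annotation_second, category, denominator))
  terms <- sort(union(p1$term, p2$term))
  v1 <- stats::setNames(p1$proportion, p1$term)[terms]
  v2 <- stats::setNames(p2$proportion, p2$term)[terms]
  v1[is.na(v1)] <- 0
  v2[is.na(v2)] <- 0
  tibble::tibble(
    term = terms,
    prop_first = unname(v1),
    prop_second = unname(v2),
    side = unname(ifelse(v1 > v2, "first_higher",
                         ifelse(v2 > v1, "second_higher", "equal")))
  )
}
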