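# Annotation with known hit sets, built directly from records.
plant_annotation <- function(sets, vocab, label = "planted") {
  txt <- unlist(lapply(seq_along(sets), function(i) {
    c(paste0("PMID- ", i),
      if (length(sets[[i]]) > 0L) paste0("MH  - ", sets[[i]]),
      "")
  }))
  annotate_corpus(corpus(parse_medline(txt), label), list(vocab))
}

sign_vocab <- function() {
  vocabulary(c("a", "b", "c", "vomiting", "anaemia"), "clinical_sign",
             "mesh_and_abstract")
}

test_that("captured terms are the union of per-record hits", {
  v <- sign_vocab()
  ann <- plant_annotation(list("a", c("a", "b"), character(0)), v)
  expect_equal(captured_terms(ann, "clinical_sign"), c("a", "b"))
  expect_error(captured_terms(ann, "nope"), "not annotated")
  empty <- plant_annotation(list(character(0)), v)
  expect_equal(captured_terms(empty, "clinical_sign"), character(0))
})

test_that("term frequencies count distinct records per term", {
  v <- sign_vocab()
  ann <- plant_annotation(list("a", "a", "b"), v)
  f <- term_frequencies(ann, "clinical_sign")
  expect_equal(stats::setNames(f$count, f$term), c(a = 2L, b = 1L))
  # counting identity: totals exceed records-with-hits unless all single-hit
  ann2 <- plant_annotation(list(c("a", "b"), "a"), v)
  f2 <- term_frequencies(ann2, "clinical_sign")
  expect_gte(sum(f2$count), length(unique(ann2$hits$pmid)))
})

test_that("top terms rank by count with alphabetical tie-break and threshold", {
  freqs <- tibble::tibble(term = c("c", "b", "a"), count = c(2L, 5L, 5L))
  expect_equal(top_terms(freqs, k = 2, min_count = 3)$term, c("a", "b"))
  expect_equal(nrow(top_terms(freqs[0, ], k = 5, min_count = 0)), 0L)
  expect_equal(top_terms(tibble::tibble(term = "x", count = 9L),
                         k = 10, min_count = 10)$term, character(0))
})

test_that("per-year counts exclude yearless records and conserve the total", {
  txt <- c("PMID- 1", "DP  - 2016 Mar", "", "PMID- 2", "DP  - 2016", "",
           "PMID- 3", "DP  - 1964", "", "PMID- 4")
  cp <- corpus(parse_medline(txt), "x")
  tr <- publications_per_year(cp)
  expect_equal(stats::setNames(tr$per_year$count, tr$per_year$year),
               c("1964" = 1L, "2016" = 2L))
  expect_equal(tr$n_no_year, 1L)
  expect_equal(sum(tr$per_year$count) + tr$n_no_year, nrow(cp$records))
})

test_that("two-sided Fisher equals exhaustive enumeration on random margins", {
  set.seed(2024)
  for (i in 1:400) {
    N <- rint(2L, 60L)
    nA <- rint(0L, N)
    nB <- rint(0L, N)
    lo <- max(0L, nA + nB - N)
    a <- rint(lo, min(nA, nB))
    b <- nA - a; c <- nB - a; d <- N - nA - nB + a
    got <- two_sided_fisher(a, b, c, d)
    expect_equal(got$p, fisher_enum_oracle(a, b, c, d), tolerance = 1e-10)
    # transposition invariance
    expect_equal(two_sided_fisher(a, c, b, d)$p, got$p, tolerance = 1e-12)
  }
})

test_that("Fisher variants agree with the reference implementation", {
  set.seed(77)
  for (i in 1:100) {
    N <- rint(2L, 40L)
    nA <- rint(1L, N)
    nB <- rint(1L, N)
    a <- rint(max(0L, nA + nB - N), min(nA, nB))
    m <- matrix(c(a, nA - a, nB - a, N - nA - nB + a), 2)
    expect_equal(two_sided_fisher(a, nA - a, nB - a, N - nA - nB + a)$p,
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_log(a, nA - a, nB - a, N - nA - nB + a,
                                  "greater")$p,
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("a zero margin forces p = 1; a perfectly aligned table does not", {
  # zero margins admit a single feasible table
  expect_equal(two_sided_fisher(0, 0, 7, 4)$p, 1)
  expect_equal(two_sided_fisher(5, 3, 0, 0)$p, 1)
  expect_equal(two_sided_fisher(0, 4, 0, 6)$p, 1)
  expect_equal(two_sided_fisher(0, 0, 0, 9)$p, 1)
  # first corpus captured the whole universe: the margins force the table
  expect_equal(fisher_overlap_test("x", 10, 10, 3, 3)$p, 1)
  # b = c = 0 with free margins is evidence of association, not degeneracy
  expect_equal(two_sided_fisher(5, 0, 0, 3)$p,
               stats::fisher.test(matrix(c(5, 0, 0, 3), 2))$p.value,
               tolerance = 1e-12)
  expect_error(two_sided_fisher(-1, 2, 3, 4), "non-negative")
})

test_that("extreme overlap p-values stay meaningful through log10", {
  r <- fisher_overlap_test("disease", 8695, 880, 338, 319)
  expect_lt(r$log10_p, -300)
  expect_gt(r$log10_p, -Inf)
  # linear p may underflow but never exceeds 1 and never goes negative
  expect_gte(r$p, 0)
  expect_lte(r$p, 1)
})

test_that("overlap p is non-increasing in the common count beyond independence", {
  N <- 100L; nA <- 40L; nB <- 30L
  indep <- nA * nB / N
  ks <- seq.int(ceiling(indep), min(nA, nB))
  ps <- vapply(ks, function(k)
    fisher_overlap_test("x", N, nA, nB, k)$p, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("inconsistent capture counts are rejected with the category named", {
  expect_error(fisher_overlap_test("cell", 10, 8, 7, 1), "cell")
  expect_error(fisher_overlap_test("cell", 10, 4, 3, 5), "cell")
})

test_that("overlap test under an independent-capture null is calibrated", {
  set.seed(314)
  N <- 200L; p1 <- 0.5; p2 <- 0.4; R <- 600L
  rej <- 0L
  for (r in seq_len(R)) {
    A <- stats::runif(N) < p1
    B <- stats::runif(N) < p2
    ft <- fisher_overlap_test("null", N, sum(A), sum(B), sum(A & B))
    if (ft$p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / R
  se <- sqrt(0.05 * 0.95 / R)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("three-way overlap regions partition the universe", {
  ov <- three_way_overlap(list(s1 = c("a", "b", "c"), s2 = c("b", "c"),
                               s3 = "c"), 5)
  expect_equal(unname(ov$regions[c("n100", "n110", "n111")]), c(1L, 1L, 1L))
  expect_equal(sum(ov$regions), 3L)
  expect_equal(ov$remainder, 2L)
  expect_equal(ov$triple_over_union, 1 / 3)

  empty <- three_way_overlap(list(character(0), character(0), character(0)), 4)
  expect_equal(sum(empty$regions), 0L)
  expect_equal(empty$remainder, 4L)

  same <- three_way_overlap(list(c("x", "y"), c("x", "y"), c("x", "y")), 6)
  expect_equal(unname(same$regions[["n111"]]), 2L)
  expect_equal(sum(same$regions) - same$regions[["n111"]], 0L)
  expect_equal(same$triple_over_union, 1)
  expect_equal(same$triple_over_universe, 2 / 6)

  expect_error(three_way_overlap(list(letters[1:5], "a", "b"), 3), "universe")
  # conservation under random sets
  set.seed(12)
  for (i in 1:20) {
    u <- letters[1:10]
    sets <- lapply(1:3, function(j) sample(u, rint(0L, 10L)))
    ov <- three_way_overlap(sets, 12)
    expect_equal(sum(ov$regions) + ov$remainder, 12L)
  }
})

test_that("sign proportions divide record counts by the chosen denominator", {
  v <- sign_vocab()
  ann <- plant_annotation(list("vomiting", "vomiting", "anaemia", "a",
                               character(0)), v)
  p <- sign_proportions(ann, "clinical_sign")
  expect_equal(p$proportion[p$term == "vomiting"], 2 / 4)
  p2 <- sign_proportions(ann, "clinical_sign", "corpus_size")
  expect_equal(p2$proportion[p2$term == "vomiting"], 2 / 5)

  none <- plant_annotation(list(character(0)), v)
  expect_warning(res <- sign_proportions(none, "clinical_sign"), "denominator")
  expect_equal(nrow(res), 0L)

  all_same <- plant_annotation(list("a", "a", "a"), v)
  expect_equal(sign_proportions(all_same, "clinical_sign")$proportion, 1)
})

test_that("relative association pairs proportions and flags the higher side", {
  v <- sign_vocab()
  ann1 <- plant_annotation(list(c("vomiting", "anaemia"), "vomiting",
                                "anaemia", "a"), v, "first")
  ann2 <- plant_annotation(list("vomiting", "vomiting", "b", "c"), v, "second")
  ra <- relative_association_table(ann1, ann2, "clinical_sign")
  row <- ra[ra$term == "anaemia", ]
  expect_equal(row$prop_first, 2 / 4)
  expect_equal(row$prop_second, 0)
  expect_equal(row$side, "first_higher")
  # hand check: vomiting 2/4 vs 2/4
  expect_equal(ra$side[ra$term == "vomiting"], "equal")

  same <- relative_association_table(ann1, ann1, "clinical_sign")
  expect_true(all(same$side == "equal"))
  expect_equal(same$prop_first, same$prop_second)
})

test_that("capture comparison from annotations matches the count-level test", {
  v <- sign_vocab()
  ann1 <- plant_annotation(list(c("a", "b"), "vomiting"), v, "first")
  ann2 <- plant_annotation(list("a", "c"), v, "second")
  cc <- compare_capture(ann1, ann2, "clinical_sign")
  direct <- fisher_overlap_test("clinical_sign", v$universe_size, 3, 2, 1)
  expect_equal(cc$p, direct$p)
  expect_equal(cc$common, 1L)
})
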