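small_marginals <- function() {
  tibble::tibble(
    category = c("disease", "disease", "clinical_sign", "clinical_sign"),
    term = c("uraemia", "hypertension", "vomiting", "lethargy"),
    prob = c(0.3, 0.2, 0.4, 0.1)
  )
}

test_that("configuration validation rejects bad probabilities and terms", {
  m <- small_marginals()
  expect_s3_class(synthetic_config(10, m), "synthetic_config")
  bad <- m; bad$prob[1] <- 1.2
  expect_error(synthetic_config(10, bad), "\\[0, 1\\]")
  expect_error(
    synthetic_config(10, m, planted_pairs = tibble::tibble(
      term1 = "uraemia", term2 = "ghost", rho = 0.1)), "ghost")
  expect_error(
    synthetic_config(10, m, planted_pairs = tibble::tibble(
      term1 = "uraemia", term2 = "vomiting", rho = 2)), "rho")
})

test_that("generation is seed-deterministic and respects forced marginals", {
  cfg <- synthetic_config(50, small_marginals(), seed = 42L)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(write_medline(g1$corpus$records),
                   write_medline(g2$corpus$records))
  g3 <- generate_corpus(synthetic_config(50, small_marginals(), seed = 43L))
  expect_false(identical(write_medline(g1$corpus$records),
                         write_medline(g3$corpus$records)))

  expect_equal(generate_corpus(synthetic_config(0, small_marginals()))
               $corpus$records |> nrow(), 0L)

  forced <- small_marginals()
  forced$prob[3] <- 1
  gf <- generate_corpus(synthetic_config(30, forced, seed = 9L))
  truth <- gf$ground_truth$records
  expect_equal(sum(truth$term == "vomiting"), 30L)
})

test_that("generated corpora are MEDLINE-valid and years stay in range", {
  cfg <- synthetic_config(40, small_marginals(), year_range = c(1990L, 2000L),
                          seed = 3L)
  gen <- generate_corpus(cfg)
  reparsed <- parse_medline(write_medline(gen$corpus$records))
  expect_records_equal(reparsed, gen$corpus$records)
  expect_true(all(reparsed$year >= 1990L & reparsed$year <= 2000L))
})

test_that("expected pair counts follow the mixture closed form", {
  m <- small_marginals()
  cfg <- synthetic_config(1000, m, planted_pairs = tibble::tibble(
    term1 = "uraemia", term2 = "vomiting", rho = 0.1), seed = 1L)
  # independent pair: n * p1 * p2, binomial sd
  ind <- expected_pair_count(cfg, "hypertension", "lethargy")
  expect_equal(ind$expected, 1000 * 0.2 * 0.1)
  expect_equal(ind$sd, sqrt(1000 * 0.02 * 0.98))
  # planted pair: rho + (1 - rho) p1 p2
  pl <- expected_pair_count(cfg, "vomiting", "uraemia")
  expect_equal(pl$p_joint, 0.1 + 0.9 * 0.3 * 0.4)
  # rho = 1 forces every record; p1 = 0 leaves only the boost
  cfg1 <- synthetic_config(200, m, planted_pairs = tibble::tibble(
    term1 = "uraemia", term2 = "vomiting", rho = 1))
  expect_equal(expected_pair_count(cfg1, "uraemia", "vomiting")$expected, 200)
  m0 <- m; m0$prob[1] <- 0
  cfg0 <- synthetic_config(200, m0, planted_pairs = tibble::tibble(
    term1 = "uraemia", term2 = "vomiting", rho = 0.25))
  expect_equal(expected_pair_count(cfg0, "uraemia", "vomiting")$expected,
               200 * 0.25)
  expect_error(expected_pair_count(cfg, "uraemia", "ghost"), "ghost")

  # marginal closed form accounts for pair boosts
  et <- expected_term_count(cfg, "uraemia")
  expect_equal(et$p_marginal, 1 - (1 - 0.3) * (1 - 0.1))
})

test_that("planted occurrences are exactly recovered by annotation", {
  cfg <- recovery_study_config(seed = 8L, n_records = 250L)
  gen <- generate_corpus(cfg)
  ann <- annotate_corpus(gen$corpus,
                         default_vocabularies(c("disease", "clinical_sign",
                                                "pain")))
  truth_keys <- with(gen$ground_truth$records, paste(pmid, term))
  hit_keys <- with(ann$hits, paste(pmid, term))
  expect_setequal(unique(hit_keys), unique(truth_keys))
})

test_that("decoy sentences embed terms without word boundaries", {
  cfg <- synthetic_config(20, small_marginals(), seed = 12L)
  gen <- generate_corpus(cfg)
  decoys <- grep("pseudo", gen$corpus$records$abstract, value = TRUE)
  expect_gt(length(decoys), 0L)
  expect_match(decoys[1], "pseudo[a-z ]+oid")
})

test_that("ground truth survives the JSON-lines round trip", {
  cfg <- recovery_study_config(seed = 2L, n_records = 50L)
  gen <- generate_corpus(cfg)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_ground_truth(gen$ground_truth, f)
  lines <- readLines(f)
  header <- jsonlite::fromJSON(lines[1])
  expect_equal(header$seed, 2L)
  expect_equal(nrow(header$pair_probs), nrow(cfg$planted_pairs))
  expect_equal(length(lines) - 1L, nrow(gen$ground_truth$records))
})
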