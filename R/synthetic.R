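#' Configuration for a synthetic MEDLINE corpus
#'
#' Describes a corpus with known statistical structure: per-term marginal
#' occurrence probabilities per category, planted pairwise associations, a
#' publication-year distribution, and the probability that clinical-sign and
#' pain terms surface in the abstract text rather than (or as well as) the
#' MeSH list. The generative model is simple by design so that every
#' downstream estimate has a closed-form expectation (see
#' [expected_pair_count()]).
#'
#' A planted pair (t1, t2, rho) is a mixture: with probability `rho` the
#' record receives both terms outright; otherwise the terms are drawn
#' independently from their marginals. The joint occurrence probability is
#' therefore exactly `rho + (1 - rho) * p1 * p2`.
#'
#' @param n_records number of records to generate.
#' @param marginals data frame with columns `category`, `term`, `prob`
#'   (per-record occurrence probability of each term).
#' @param planted_pairs optional data frame with columns `term1`, `term2`,
#'   `rho` (joint boost in [0, 1]); both terms must appear in `marginals`.
#' @param year_range inclusive integer interval of publication years.
#' @param year_weights per-year sampling weights over `year_range`; the
#'   default ramps up linearly, emulating literature growth.
#' @param abstract_emission probability that a `clinical_sign`/`pain` term
#'   occurrence is written into the abstract (otherwise it goes to the MeSH
#'   list; an abstract-emitted term also appears in the MeSH list with
#'   probability 0.3).
#' @param species_label label of the generated corpus.
#' @param seed integer RNG seed; the same configuration always yields a
#'   byte-identical corpus.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records, marginals, planted_pairs = NULL,
                             year_range = c(1945L, 2023L), year_weights = NULL,
                             abstract_emission = 0.5,
                             species_label = "synthetic", seed = 1L) {
  stopifnot(is.numeric(n_records), n_records >= 0,
            is.data.frame(marginals),
            all(c("category", "term", "prob") %in% names(marginals)))
  marginals <- tibble::as_tibble(marginals)
  marginals$term <- normalize_term(marginals$term)
  if (any(marginals$prob < 0 | marginals$prob > 1))
    stop("marginal probabilities must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(marginals$term))
    stop("duplicate terms in marginals (terms must be unique across categories)",
         call. = FALSE)
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("term1", "term2", "rho") %in% names(planted_pairs)))
    planted_pairs <- tibble::as_tibble(planted_pairs)
    planted_pairs$term1 <- normalize_term(planted_pairs$term1)
    planted_pairs$term2 <- normalize_term(planted_pairs$term2)
    if (any(planted_pairs$rho < 0 | planted_pairs$rho > 1))
      stop("planted-pair rho must lie in [0, 1]", call. = FALSE)
    unknown <- setdiff(base::c(planted_pairs$term1, planted_pairs$term2),
                       marginals$term)
    if (length(unknown) > 0L)
      stop(sprintf("planted-pair term(s) not in marginals: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2])
  years <- seq.int(year_range[1], year_range[2])
  if (is.null(year_weights)) year_weights <- seq_along(years)
  stopifnot(length(year_weights) == length(years), all(year_weights >= 0))
  stopifnot(abstract_emission >= 0, abstract_emission <= 1)
  structure(
    list(n_records = as.integer(n_records), marginals = marginals,
         planted_pairs = planted_pairs, year_range = as.integer(year_range),
         year_weights = year_weights, abstract_emission = abstract_emission,
         species_label = species_label, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Abstract sentence templates. The decoy embeds a term inside a longer word
# (no word boundary on either side), so boundary-correct matching must not
# fire on it.
.sentence_template <- "The patients presented with %s during follow-up."
.decoy_template <- "The pseudo%soid assay remained negative."

#' Generate a synthetic MEDLINE corpus with ground truth
#'
#' Draws `n_records` records under the model of [synthetic_config()]:
#' independent per-term Bernoulli draws, planted pair boosts, publication
#' years from the configured distribution. Terms of `mesh_only` categories
#' are written as MeSH headings (a qualified `/veterinary` form and a
#' major-topic `*` are sprinkled in to exercise descriptor normalization);
#' clinical-sign and pain terms are emitted into templated abstract sentences
#' and/or the MeSH list per `abstract_emission`. Additionally, one decoy
#' sentence per configured term embeds the term inside a longer word
#' somewhere in the corpus, so that substring matches would be detectably
#' wrong. Identical seeds give byte-identical corpora.
#'
#' @param config a [synthetic_config()].
#' @return A list with `corpus` (a [corpus()]) and `ground_truth`: `records`
#'   (tibble `pmid`, `category`, `term` of every planted occurrence),
#'   `pair_probs` (per planted pair: `rho`, `p1`, `p2` and the exact joint
#'   probability), and the generator seed.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_records
  m <- config$marginals
  nt <- nrow(m)
  abstract_cats <- base::c("clinical_sign", "pain")
  years_pool <- seq.int(config$year_range[1], config$year_range[2])

  # Term presence matrix: independent draws, then planted-pair overrides.
  present <- matrix(stats::runif(n * nt) < rep(m$prob, each = n), nrow = n)
  if (!is.null(config$planted_pairs) && n > 0L) {
    for (i in seq_len(nrow(config$planted_pairs))) {
      pp <- config$planted_pairs[i, ]
      joint <- stats::runif(n) < pp$rho
      j1 <- match(pp$term1, m$term)
      j2 <- match(pp$term2, m$term)
      present[joint, j1] <- TRUE
      present[joint, j2] <- TRUE
    }
  }

  pmids <- as.character(1000000L + seq_len(n))
  years <- if (n > 0L) sample(years_pool, n, replace = TRUE,
                              prob = config$year_weights) else integer(0)

  # Decide surfaces for every (record, term) occurrence.
  is_abs_cat <- m$category %in% abstract_cats
  occ <- which(present, arr.ind = TRUE)
  occ_abs <- logical(nrow(occ))
  occ_mesh <- rep(TRUE, nrow(occ))
  if (nrow(occ) > 0L) {
    abs_elig <- is_abs_cat[occ[, 2L]]
    to_abs <- abs_elig & (stats::runif(nrow(occ)) < config$abstract_emission)
    occ_abs[to_abs] <- TRUE
    occ_mesh[to_abs] <- stats::runif(sum(to_abs)) < 0.3
  }
  # Qualified / major-topic dressing of MeSH lines.
  qualified <- stats::runif(nrow(occ)) < 0.3
  major <- stats::runif(nrow(occ)) < 0.2

  # One decoy sentence per term, in a uniformly chosen record.
  decoy_rec <- if (n > 0L) sample.int(n, nt, replace = TRUE) else integer(0)

  by_record <- if (nrow(occ) > 0L) split(seq_len(nrow(occ)), occ[, 1L]) else list()
  records <- lapply(seq_len(n), function(i) {
    rows <- by_record[[as.character(i)]]
    mesh_rows <- rows[occ_mesh[rows]]
    abs_rows <- rows[occ_abs[rows]]
    mh <- character(0)
    if (length(mesh_rows) > 0L) {
      terms <- m$term[occ[mesh_rows, 2L]]
      mh <- ifelse(qualified[mesh_rows], paste0(terms, "/veterinary"), terms)
      mh <- ifelse(major[mesh_rows], paste0("*", mh), mh)
    }
    sentences <- "This synthetic study examines renal disease."
    if (length(abs_rows) > 0L) {
      sentences <- base::c(sentences,
                           sprintf(.sentence_template, m$term[occ[abs_rows, 2L]]))
    }
    decoys <- which(decoy_rec == i)
    if (length(decoys) > 0L) {
      sentences <- base::c(sentences, sprintf(.decoy_template, m$term[decoys]))
    }
    list(pmid = pmids[[i]],
         title = sprintf("Synthetic renal disease record %s.", pmids[[i]]),
         abstract = paste(sentences, collapse = " "),
         year = years[[i]],
         mesh = parse_mesh_heading(mh))
  })
  rec_tbl <- tibble::tibble(
    pmid = pmids,
    title = vapply(records, `[[`, character(1), "title"),
    abstract = vapply(records, `[[`, character(1), "abstract"),
    year = if (n > 0L) vapply(records, `[[`, integer(1), "year") else integer(0),
    mesh = lapply(records, `[[`, "mesh")
  )
  corp <- corpus(rec_tbl, config$species_label,
                 query = "synthetic", retrieved_date = NA_character_)

  truth_records <- if (nrow(occ) == 0L) {
    tibble::tibble(pmid = character(0), category = character(0),
                   term = character(0))
  } else {
    tibble::tibble(pmid = pmids[occ[, 1L]],
                   category = m$category[occ[, 2L]],
                   term = m$term[occ[, 2L]])
  }
  pair_probs <- NULL
  if (!is.null(config$planted_pairs)) {
    pp <- config$planted_pairs
    p1 <- m$prob[match(pp$term1, m$term)]
    p2 <- m$prob[match(pp$term2, m$term)]
    pair_probs <- tibble::tibble(term1 = pp$term1, term2 = pp$term2,
                                 rho = pp$rho, p1 = p1, p2 = p2,
                                 p_joint = pp$rho + (1 - pp$rho) * p1 * p2)
  }
  list(corpus = corp,
       ground_truth = list(records = truth_records, pair_probs = pair_probs,
                           seed = config$seed))
}

#' Expected co-mention count of a term pair under the synthetic model
#'
#' For a planted pair the exact joint probability is
#' `rho + (1 - rho) * p1 * p2`; for any other configured pair the terms are
#' independent and it is `p1 * p2`. The count of records mentioning both is
#' Binomial(n, P), giving the returned expectation and standard deviation —
#' the closed-form oracle for edge-weight recovery checks.
#'
#' @param config a [synthetic_config()].
#' @param term1,term2 the pair (must be configured in the marginals).
#' @return A list with `p_joint`, `expected` and `sd`.
#' @export
expected_pair_count <- function(config, term1, term2) {
  stopifnot(inherits(config, "synthetic_config"))
  term1 <- normalize_term(term1)
  term2 <- normalize_term(term2)
  m <- config$marginals
  if (!term1 %in% m$term) stop(sprintf("unknown term '%s'", term1), call. = FALSE)
  if (!term2 %in% m$term) stop(sprintf("unknown term '%s'", term2), call. = FALSE)
  p1 <- m$prob[match(term1, m$term)]
  p2 <- m$prob[match(term2, m$term)]
  rho <- 0
  pp <- config$planted_pairs
  if (!is.null(pp)) {
    hit <- (pp$term1 == term1 & pp$term2 == term2) |
      (pp$term1 == term2 & pp$term2 == term1)
    if (any(hit)) rho <- pp$rho[which(hit)[1L]]
  }
  p_joint <- rho + (1 - rho) * p1 * p2
  n <- config$n_records
  list(p_joint = p_joint, expected = n * p_joint,
       sd = sqrt(n * p_joint * (1 - p_joint)))
}

#' Expected marginal record count of a term under the synthetic model
#'
#' A term in a planted pair occurs when its own Bernoulli draw fires or any
#' of its pair boosts fire: `P = 1 - (1 - p) * prod(1 - rho_i)`. Unplanted
#' terms have `P = p`.
#'
#' @inheritParams expected_pair_count
#' @param term the configured term.
#' @return A list with `p_marginal`, `expected` and `sd`.
#' @export
expected_term_count <- function(config, term) {
  stopifnot(inherits(config, "synthetic_config"))
  term <- normalize_term(term)
  m <- config$marginals
  if (!term %in% m$term) stop(sprintf("unknown term '%s'", term), call. = FALSE)
  p <- m$prob[match(term, m$term)]
  rhos <- numeric(0)
  pp <- config$planted_pairs
  if (!is.null(pp)) rhos <- pp$rho[pp$term1 == term | pp$term2 == term]
  p_marg <- 1 - (1 - p) * prod(1 - rhos)
  n <- config$n_records
  list(p_marginal = p_marg, expected = n * p_marg,
       sd = sqrt(n * p_marg * (1 - p_marg)))
}

#' Write synthetic ground truth as JSON-lines
#'
#' One JSON object per planted (pmid, category, term) occurrence, preceded by
#' one header object carrying the seed and the planted-pair probabilities.
#'
#' @param ground_truth the `ground_truth` element of [generate_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  header <- jsonlite::toJSON(
    list(type = "header", seed = ground_truth$seed,
         pair_probs = ground_truth$pair_probs),
    auto_unbox = TRUE, digits = NA, null = "null")
  rows <- ground_truth$records
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    jsonlite::toJSON(list(type = "occurrence", pmid = rows$pmid[[i]],
                          category = rows$category[[i]], term = rows$term[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(base::c(header, lines), path)
  invisible(path)
}

#' Benchmark configuration for planted-pair recovery studies
#'
#' A fixed synthetic design used to verify that the annotate-and-network
#' stages recover the generator's statistical structure: 2000 records over
#' disease, clinical-sign and pain terms, with six planted pairs at joint
#' boosts rho of 0.05 and 0.2 spanning within- and cross-category
#' associations. The tracked clinical-sign terms are chosen so that none is
#' a whole-phrase substring of another abstract-searchable term — nested
#' terms (e.g. "pain" inside "abdominal pain") pick up extra abstract
#' matches by construction, which is linguistically correct but would make
#' the closed-form binomial oracle inapplicable.
#'
#' @param seed RNG seed.
#' @param n_records corpus size (default 2000).
#' @return A [synthetic_config()].
#' @export
recovery_study_config <- function(seed = 1L, n_records = 2000L) {
  marginals <- tibble::tibble(
    category = base::c(
      rep("clinical_sign", 8L), rep("disease", 8L), rep("pain", 2L)),
    term = base::c(
      "vomiting", "anaemia", "lethargy", "polyuria", "polydipsia", "nausea",
      "weakness", "oedema",
      "peritonitis", "uraemia", "hypertension", "obesity",
      "diabetes mellitus", "glomerulonephritis", "nephritis", "amyloidosis",
      "arthralgia", "headache"),
    prob = base::c(
      0.10, 0.15, 0.06, 0.07, 0.05, 0.08, 0.05, 0.04,
      0.05, 0.08, 0.12, 0.04, 0.06, 0.03, 0.05, 0.02,
      0.03, 0.04)
  )
  planted <- tibble::tibble(
    term1 = base::c("vomiting", "anaemia", "lethargy",
                    "polyuria", "nausea", "weakness"),
    term2 = base::c("peritonitis", "uraemia", "hypertension",
                    "polydipsia", "obesity", "diabetes mellitus"),
    rho = base::c(0.05, 0.20, 0.05, 0.20, 0.05, 0.20)
  )
  synthetic_config(n_records = n_records, marginals = marginals,
                   planted_pairs = planted, abstract_emission = 0.5,
                   species_label = "recovery", seed = seed)
}

#' Default synthetic study configuration for one species corpus
#'
#' Desk-scale stand-ins for the three renal-disease corpora, with marginal
#' term probabilities over the shipped sample vocabularies chosen so that
#' core terms (chronic kidney failure, glomerular filtration rate, anaemia,
#' vomiting, pain) dominate their categories, plus a small set of planted
#' associations (e.g. abdominal pain with peritonitis and vomiting,
#' musculoskeletal pain with fatigue) emulating the co-mention structure the
#' network stage is meant to recover. Corpus sizes default to 3000 (human),
#' 400 (cat) and 800 (dog), preserving the human-dominated size ordering of
#' the real corpora at a size every stage processes in seconds.
#'
#' @param species_label `"human"`, `"cat"` or `"dog"`.
#' @param seed RNG seed.
#' @param n_records corpus size override.
#' @return A [synthetic_config()].
#' @export
default_synthetic_config <- function(species_label = c("human", "cat", "dog"),
                                     seed = 1L, n_records = NULL) {
  species_label <- match.arg(species_label)
  if (is.null(n_records)) {
    n_records <- switch(species_label, human = 3000L, cat = 400L, dog = 800L)
  }
  vocabs <- default_vocabularies()
  # Occurrence probabilities decay down each (sorted) term list from a
  # species-dependent lead probability; humans get the densest indexing.
  lead <- switch(species_label, human = 0.35, cat = 0.20, dog = 0.25)
  marg <- do.call(rbind, lapply(vocabs, function(v) {
    k <- seq_along(v$terms)
    tibble::tibble(category = v$category, term = v$terms,
                   prob = pmin(lead, lead * 2 / (k + 1)))
  }))
  # terms shared between vocabularies (e.g. "abdominal pain" is both a
  # clinical sign and a pain type) are generated under their first category
  marg <- marg[!duplicated(marg$term), , drop = FALSE]
  # Planted associations: pain terms with diseases and clinical signs.
  planted <- tibble::tibble(
    term1 = base::c("abdominal pain", "abdominal pain", "musculoskeletal pain",
                    "musculoskeletal pain", "anaemia"),
    term2 = base::c("peritonitis", "vomiting", "fatigue", "uraemia",
                    "erythropoietin"),
    rho = base::c(0.05, 0.04, 0.03, 0.02, 0.05)
  )
  synthetic_config(
    n_records = n_records, marginals = marg, planted_pairs = planted,
    year_range = base::c(1945L, 2023L), abstract_emission = 0.5,
    species_label = species_label, seed = seed
  )
}
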