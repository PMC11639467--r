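# Shared fixtures and independent oracles, all built in code.

# Two-record MEDLINE fixture exercising qualifiers, the major-topic marker,
# continuation lines and a month-bearing DP field.
fixture_medline_text <- function() {
  paste(
    "PMID- 100",
    "TI  - Chronic kidney disease in cats.",
    "AB  - Patients presented with vomiting and",
    "      lethargy.",
    "DP  - 2016 Mar",
    "MH  - Kidney Failure, Chronic/*veterinary",
    "MH  - Cats",
    "",
    "PMID- 101",
    "TI  - Renal insufficiency follow-up.",
    "AB  - A painstaking analysis of neck-pain and anemia.",
    "DP  - 1999",
    "MH  - Hypertension/complications",
    "MH  - Dogs",
    sep = "\n"
  )
}

# Uniform integer in [lo, hi] that is safe when lo == hi.
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Random valid records for round-trip property tests.
random_records <- function(n) {
  words <- c("renal", "kidney", "chronic", "feline", "canine", "cohort",
             "anemia", "pain", "marker", "study")
  mk_mesh <- function() {
    k <- rint(0L, 4L)
    if (k == 0L) return(renalmine::parse_mesh_heading(character(0)))
    raw <- vapply(seq_len(k), function(i) {
      nm <- paste(sample(words, rint(1L, 3L)), collapse = " ")
      quals <- sample(c("veterinary", "complications", "therapy"), rint(0L, 2L))
      s <- paste(c(nm, quals), collapse = "/")
      if (stats::runif(1) < 0.3) s <- paste0("*", s)
      s
    }, character(1))
    renalmine::parse_mesh_heading(raw)
  }
  tibble::tibble(
    pmid = as.character(sample.int(10000000L, n)),
    title = vapply(seq_len(n), function(i)
      paste(sample(words, rint(1L, 5L)), collapse = " "), character(1)),
    abstract = vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.2) "" else
        paste(sample(words, rint(3L, 12L), replace = TRUE), collapse = " ")
    }, character(1)),
    year = ifelse(stats::runif(n) < 0.15, NA_integer_,
                  as.integer(rint(1900L, 2023L) + integer(n))),
    mesh = lapply(seq_len(n), function(i) mk_mesh())
  )
}

# Field-wise record equality (ignores the raw MH spelling, which the writer
# may regenerate).
expect_records_equal <- function(got, want) {
  expect_equal(got$pmid, want$pmid)
  expect_equal(got$title, want$title)
  expect_equal(got$abstract, want$abstract)
  expect_equal(got$year, want$year)
  expect_equal(length(got$mesh), length(want$mesh))
  for (i in seq_along(want$mesh)) {
    expect_equal(got$mesh[[i]]$name, want$mesh[[i]]$name)
    expect_equal(got$mesh[[i]]$qualifiers, want$mesh[[i]]$qualifiers)
    expect_equal(got$mesh[[i]]$major_topic, want$mesh[[i]]$major_topic)
  }
}

# Independent two-sided Fisher oracle: full enumeration of the feasible
# tables in linear space via choose() (adequate for N <= 60).
fisher_enum_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  nA <- a + b
  nB <- a + c
  lo <- max(0L, nA + nB - N)
  hi <- min(nA, nB)
  k <- lo:hi
  pr <- choose(nA, k) * choose(N - nA, nB - k) / choose(N, nB)
  obs <- pr[k == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Brute-force co-occurrence oracle: double loop over every record's matched
# (category, term) set, counting each unordered pair once per record.
pair_count_oracle <- function(annotation, categories) {
  h <- annotation$hits[annotation$hits$category %in% categories, ]
  keys <- split(paste(h$category, h$term, sep = "|"), h$pmid)
  counts <- new.env(parent = emptyenv())
  for (ks in keys) {
    ks <- sort(unique(ks))
    if (length(ks) < 2L) next
    for (i in seq_len(length(ks) - 1L)) {
      for (j in seq.int(i + 1L, length(ks))) {
        key <- paste(ks[i], ks[j], sep = "&")
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer(0) else out[order(names(out))]
}

# Edge table of a network in the oracle's key format.
edge_key_table <- function(net) {
  if (nrow(net$edges) == 0L) return(integer(0))
  k1 <- paste(net$edges$category1, net$edges$term1, sep = "|")
  k2 <- paste(net$edges$category2, net$edges$term2, sep = "|")
  lo <- pmin(k1, k2)
  hi <- pmax(k1, k2)
  out <- stats::setNames(as.integer(net$edges$weight), paste(lo, hi, sep = "&"))
  out[order(names(out))]
}

# Small in-code vocabularies for annotation tests.
tiny_vocabs <- function() {
  list(
    disease = renalmine::vocabulary(
      c("hypertension", "peritonitis", "uraemia"), "disease", "mesh_only"),
    clinical_sign = renalmine::vocabulary(
      c("vomiting", "lethargy", "anaemia"), "clinical_sign",
      "mesh_and_abstract", synonyms = c(anemia = "anaemia")),
    pain = renalmine::vocabulary(
      c("pain", "neck pain", "abdominal pain"), "pain", "mesh_and_abstract")
  )
}
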