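# Corpus whose records carry exactly the given MeSH term sets.
mesh_corpus <- function(sets, label = "net") {
  txt <- unlist(lapply(seq_along(sets), function(i) {
    c(paste0("PMID- ", i),
      if (length(sets[[i]]) > 0L) paste0("MH  - ", sets[[i]]),
      "")
  }))
  corpus(parse_medline(txt), label)
}

abc_vocab <- function() {
  list(vocabulary(c("a", "b", "c"), "disease", "mesh_only"))
}

test_that("edge weights count co-mentioning records once each", {
  ann <- annotate_corpus(mesh_corpus(list(c("a", "b"), c("a", "c"),
                                          c("a", "b"))), abc_vocab())
  net <- build_network(ann, "disease")
  counts <- stats::setNames(net$nodes$record_count, net$nodes$term)
  expect_equal(counts, c(a = 3L, b = 2L, c = 1L))
  expect_equal(edge_weight(net, "a", "b"), 2L)
  expect_equal(edge_weight(net, "a", "c"), 1L)
  expect_equal(edge_weight(net, "b", "c"), 0L)
  expect_equal(nrow(net$edges), 2L)
  # no self-loops, weights bounded by endpoint record counts
  expect_true(all(paste(net$edges$term1, net$edges$category1) !=
                  paste(net$edges$term2, net$edges$category2)))
  expect_true(all(net$edges$weight <=
                  pmin(counts[net$edges$term1], counts[net$edges$term2])))
})

test_that("records mentioning at most one term give an edgeless network", {
  ann <- annotate_corpus(mesh_corpus(list("a", "b", character(0))), abc_vocab())
  net <- build_network(ann, "disease")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 2L)
  expect_error(build_network(ann, character(0)), "no categories")
  expect_error(build_network(ann, "pain"), "not annotated")
})

test_that("edge weights match brute-force pair counting on random corpora", {
  v <- default_vocabularies(c("disease", "clinical_sign", "pain"))
  cats <- c("disease", "clinical_sign", "pain")
  for (s in 1:25) {
    cfg <- default_synthetic_config("dog", seed = 1000L + s,
                                    n_records = rint(20L, 200L))
    ann <- annotate_corpus(generate_corpus(cfg)$corpus, v)
    net <- build_network(ann, cats)
    expect_identical(edge_key_table(net), pair_count_oracle(ann, cats))
  }
})

test_that("network construction is invariant to record order", {
  set.seed(9)
  cfg <- default_synthetic_config("cat", seed = 77L, n_records = 80L)
  gen <- generate_corpus(cfg)
  v <- default_vocabularies(c("disease", "clinical_sign"))
  net1 <- build_network(annotate_corpus(gen$corpus, v),
                        c("disease", "clinical_sign"))
  perm <- sample.int(nrow(gen$corpus$records))
  net2 <- build_network(
    annotate_corpus(corpus(gen$corpus$records[perm, ], "cat"), v),
    c("disease", "clinical_sign"))
  expect_equal(as.data.frame(net1$nodes), as.data.frame(net2$nodes))
  expect_equal(as.data.frame(net1$edges), as.data.frame(net2$edges))
})

test_that("first-neighbour sub-networks are induced subgraphs", {
  # path a - b - c: seeding at b keeps the whole path
  path_ann <- annotate_corpus(mesh_corpus(list(c("a", "b"), c("b", "c"))),
                              abc_vocab())
  path_net <- build_network(path_ann, "disease")
  sub_b <- first_neighbour_subnetwork(path_net, "b")
  expect_setequal(sub_b$nodes$term, c("a", "b", "c"))
  expect_equal(nrow(sub_b$edges), 2L)

  # triangle: seeding at a keeps the neighbour-neighbour edge b-c
  tri_ann <- annotate_corpus(mesh_corpus(list(c("a", "b"), c("b", "c"),
                                              c("a", "c"))), abc_vocab())
  tri_net <- build_network(tri_ann, "disease")
  sub_a <- first_neighbour_subnetwork(tri_net, "a")
  expect_equal(nrow(sub_a$edges), 3L)
  expect_equal(edge_weight(sub_a, "b", "c"), 1L)

  # isolated seed
  iso_ann <- annotate_corpus(mesh_corpus(list("a", "b")), abc_vocab())
  iso_net <- build_network(iso_ann, "disease")
  sub_iso <- first_neighbour_subnetwork(iso_net, "a")
  expect_equal(sub_iso$nodes$term, "a")
  expect_equal(nrow(sub_iso$edges), 0L)

  expect_error(first_neighbour_subnetwork(tri_net, "zzz"), "zzz")
})

test_that("sub-network extraction is idempotent and subset-closed", {
  cfg <- default_synthetic_config("human", seed = 5L, n_records = 150L)
  ann <- annotate_corpus(generate_corpus(cfg)$corpus,
                         default_vocabularies(c("disease", "clinical_sign",
                                                "pain")))
  net <- build_network(ann, c("disease", "clinical_sign", "pain"))
  seed_term <- net$nodes$term[which.max(net$nodes$record_count)]
  seed_cat <- net$nodes$category[which.max(net$nodes$record_count)]
  sub1 <- first_neighbour_subnetwork(net, seed_term, seed_cat)
  sub2 <- first_neighbour_subnetwork(sub1, seed_term, seed_cat)
  expect_equal(as.data.frame(sub1$nodes), as.data.frame(sub2$nodes))
  expect_equal(as.data.frame(sub1$edges), as.data.frame(sub2$edges))
  expect_true(all(sub1$nodes$term %in% net$nodes$term))
  expect_lte(nrow(sub1$edges), nrow(net$edges))
})

test_that("exports round-trip through GraphML and follow the SIF contract", {
  ann <- annotate_corpus(mesh_corpus(list(c("a", "b"), c("a", "c"), "b")),
                         abc_vocab())
  net <- build_network(ann, "disease")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml, net$provenance)
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))

  # SIF: one line per edge plus one per isolated node
  iso_ann <- annotate_corpus(mesh_corpus(list(c("a", "b"), "c")), abc_vocab())
  iso_net <- build_network(iso_ann, "disease")
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(iso_net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(iso_net$edges) + 1L)
  expect_match(lines[1], "cooccurs_with")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_table")
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("term1", "category1", "term2", "category2",
                             "weight"))
  expect_equal(nrow(tab), nrow(net$edges))

  # empty network exports are valid files
  empty_net <- build_network(
    annotate_corpus(mesh_corpus(list(character(0))), abc_vocab()), "disease")
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty_net, gml2, "graphml")
  expect_equal(nrow(read_network_graphml(gml2)$nodes), 0L)
})
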