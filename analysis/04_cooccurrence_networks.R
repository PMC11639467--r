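#!/usr/bin/env Rscript
# Term co-occurrence networks over disease, clinical-sign and pain terms in
# the simulated human corpus, with first-degree-neighbour sub-networks around
# pain terms of interest. Run 01_simulate_corpora.R first.

suppressPackageStartupMessages(library(renalmine))

out_dir <- "results/networks"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

corp <- read_corpus("results/corpora/human.medline.txt", "human")
vocabs <- default_vocabularies(c("disease", "clinical_sign", "pain"))
ann <- annotate_corpus(corp, vocabs)
net <- build_network(ann, c("disease", "clinical_sign", "pain"))
print(net)

export_network(net, file.path(out_dir, "human.graphml"), "graphml")
export_network(net, file.path(out_dir, "human.sif"), "sif")
export_network(net, file.path(out_dir, "human_edges.tsv"), "edge_table")

for (seed_term in c("musculoskeletal pain", "abdominal pain")) {
  cand <- net$nodes[net$nodes$term == seed_term, ]
  if (nrow(cand) == 0L) {
    cat(sprintf("seed '%s' not present in this corpus\n", seed_term))
    next
  }
  sub <- first_neighbour_subnetwork(net, seed_term, cand$category[[1]])
  slug <- gsub("[^a-z0-9]+", "_", seed_term)
  export_network(sub, file.path(out_dir, paste0("sub_", slug, ".graphml")),
                 "graphml")
  e <- sub$edges
  at_seed <- (e$term1 == seed_term & e$category1 == cand$category[[1]]) |
    (e$term2 == seed_term & e$category2 == cand$category[[1]])
  touching <- e[at_seed, ]
  touching <- touching[order(-touching$weight), ]
  seed_is_1 <- touching$term1 == seed_term &
    touching$category1 == cand$category[[1]]
  other <- ifelse(seed_is_1,
                  paste0(touching$term2, " (", touching$category2, ")"),
                  paste0(touching$term1, " (", touching$category1, ")"))
  cat(sprintf("\n'%s' (%s): %d neighbours; strongest direct associations:\n",
              seed_term, cand$category[[1]], nrow(sub$nodes) - 1L))
  print(utils::head(data.frame(term = other, weight = touching$weight), 8),
        row.names = FALSE)
}
cat(sprintf("\nNetworks written under %s (GraphML/SIF import directly into Cytoscape).\n",
            out_dir))
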