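#!/usr/bin/env Rscript
# Comparative statistics over the simulated corpora: publication trends,
# top-term rankings, clinical-sign proportions, pain relative associations,
# three-way capture overlaps and the Fisher overlap tests — plus the
# comparison-only reproduction of the published capture-count table, which
# needs no corpora at all. Run 01_simulate_corpora.R first.

suppressPackageStartupMessages(library(renalmine))

corpus_dir <- "results/corpora"

## Full pipeline over the synthetic corpora ---------------------------------
cfg <- list(
  corpora = lapply(c("human", "cat", "dog"), function(s)
    list(species_label = s, path = file.path(corpus_dir, paste0(s, ".medline.txt")))),
  reference = "human",
  subnetwork_seeds = c("musculoskeletal pain", "abdominal pain")
)
res <- run_pipeline(cfg, "results/pipeline")
cat("\nFisher overlap tests on the synthetic corpora (human as reference):\n")
print(as.data.frame(res$comparison), digits = 3)

## Published capture counts -> p-values (comparison-only mode) --------------
published <- data.frame(
  comparison = rep(c("human_vs_cat", "human_vs_dog"), each = 6),
  category = rep(c("disease", "method", "cell", "cytokine", "tissue",
                   "clinical_sign"), 2),
  universe_size = rep(c(8695L, 802L, 67L, 86L, 116L, 28L), 2),
  captured_first = rep(c(880L, 608L, 50L, 69L, 100L, 27L), 2),
  captured_second = c(187L, 154L, 18L, 7L, 43L, 23L,
                      338L, 261L, 23L, 21L, 65L, 25L),
  common = c(172L, 152L, 18L, 7L, 43L, 23L,
             319L, 251L, 23L, 21L, 64L, 25L))
cmp <- category_comparison_table(published)
dir.create("results/published_counts", showWarnings = FALSE, recursive = TRUE)
utils::write.table(cmp, "results/published_counts/comparison_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nOverlap tests recomputed from the published capture counts:\n")
print(as.data.frame(cmp), digits = 3)
cat("\nNote the clinical-sign comparisons (p = 0.179 and 0.107): the sign\n")
cat("vocabularies overlap between species about as much as independent\n")
cat("capture would predict, unlike every other category.\n")
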