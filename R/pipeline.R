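#' Read a pipeline configuration file
#'
#' YAML with the fields of [run_pipeline()]'s `config` argument; relative
#' corpus paths are resolved against the configuration file's directory.
#'
#' @param path YAML configuration file.
#' @return A named list usable as `config` in [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (!is.null(cfg$corpora)) {
    cfg$corpora <- lapply(cfg$corpora, function(x) {
      if (!is.null(x$path) && !grepl("^(/|[A-Za-z]:)", x$path)) {
        x$path <- file.path(base, x$path)
      }
      x
    })
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative mining pipeline
#'
#' Orchestrates corpus loading, annotation, trend and association statistics,
#' and network construction from one configuration, writing every table the
#' comparative analysis rests on into `out_dir`:
#'
#' * `years_<label>.tsv` — publications per year, per corpus;
#' * `top_terms_<label>.tsv` — ranked terms per category (top `k` with at
#'   least `min_count` records);
#' * `sign_proportions_<label>.tsv` — clinical-sign mention proportions;
#' * `relative_association_<category>_<first>_vs_<label>.tsv` — paired
#'   proportions of the first (reference) corpus against every other;
#' * `comparison_table.tsv` — capture counts and Fisher overlap p-values
#'   (with log10) for every category and corpus pair against the reference;
#' * `venn_<category>.tsv` — three-set overlap regions (when exactly three
#'   corpora are configured);
#' * `network_<label>.graphml` / `.sif` / `_edges.tsv` and
#'   `subnetwork_<label>_<seed>.graphml` for the configured seed terms;
#' * `manifest.json` — corpus sizes, stage counts, configuration echo.
#'
#' `config` fields: `corpora` (list of `list(species_label=, path=)` MEDLINE
#' files, or `corpus` objects), `vocab_dir` (optional directory of
#' `<category>.txt` lists plus `synonyms_gb_us.tsv`; default = shipped
#' vocabularies), `categories`, `reference` (label of the first corpus in
#' comparisons; default the first configured), `denominator`, `alternative`,
#' `network_categories`, `subnetwork_seeds`, `relative_association_category`,
#' `top_k`, `top_min_count`, `comparison_counts` (optional TSV of
#' pre-tabulated capture counts: comparison-only mode, no corpora needed).
#'
#' @param config named list (or the result of [read_pipeline_config()]).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the annotations, comparison table, networks
#'   and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  # Comparison-only mode: precomputed capture counts in, p-values out.
  comparison_only <- !is.null(config$comparison_counts)
  alternative <- config$alternative %||% "greater"
  if (comparison_only) {
    counts <- utils::read.delim(config$comparison_counts,
                                stringsAsFactors = FALSE)
    cmp <- category_comparison_table(counts, alternative = alternative)
    written <- base::c(written, write_tsv(cmp, file.path(out_dir, "comparison_table.tsv")))
    manifest <- list(mode = "comparison_only",
                     n_comparisons = nrow(cmp), alternative = alternative)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(comparison = cmp, manifest = manifest,
                          files = written)))
  }

  if (is.null(config$corpora) || length(config$corpora) == 0L)
    stop("pipeline config: no corpora configured", call. = FALSE)

  categories <- config$categories %||%
    base::c("disease", "method", "cell", "cytokine", "tissue",
            "clinical_sign", "pain")
  vocabs <- if (is.null(config$vocab_dir)) {
    default_vocabularies(categories)
  } else {
    syn_path <- file.path(config$vocab_dir, "synonyms_gb_us.tsv")
    syn <- if (file.exists(syn_path)) load_synonyms(syn_path) else NULL
    abstract_cats <- base::c("clinical_sign", "pain")
    stats::setNames(lapply(categories, function(cat) {
      load_vocabulary(file.path(config$vocab_dir, paste0(cat, ".txt")), cat,
                      surface = if (cat %in% abstract_cats)
                        "mesh_and_abstract" else "mesh_only",
                      synonyms = syn)
    }), categories)
  }

  corpora <- lapply(config$corpora, function(x) {
    if (inherits(x, "corpus")) return(x)
    read_corpus(x$path, x$species_label)
  })
  labels <- vapply(corpora, `[[`, character(1), "species_label")
  names(corpora) <- labels
  reference <- config$reference %||% labels[[1L]]
  if (!reference %in% labels)
    stop(sprintf("reference corpus '%s' is not configured", reference),
         call. = FALSE)
  denominator <- config$denominator %||% "records_with_any_hit"
  top_k <- config$top_k %||% 10L
  top_min <- config$top_min_count %||% 10L

  message(sprintf("annotate: %d corpora x %d categories",
                  length(corpora), length(categories)))
  annotations <- lapply(corpora, annotate_corpus, vocabularies = vocabs)

  for (lab in labels) {
    trend <- publications_per_year(corpora[[lab]])
    written <- base::c(written, write_tsv(
      trend$per_year, file.path(out_dir, sprintf("years_%s.tsv", lab))))

    tops <- do.call(rbind, lapply(categories, function(cat) {
      tt <- top_terms(term_frequencies(annotations[[lab]], cat),
                      k = top_k, min_count = top_min)
      if (nrow(tt) == 0L) return(NULL)
      cbind(category = cat, tt)
    }))
    if (is.null(tops)) {
      tops <- data.frame(category = character(0), term = character(0),
                         count = integer(0))
    }
    written <- base::c(written, write_tsv(
      tops, file.path(out_dir, sprintf("top_terms_%s.tsv", lab))))

    if ("clinical_sign" %in% categories) {
      props <- suppressWarnings(
        sign_proportions(annotations[[lab]], "clinical_sign", denominator))
      written <- base::c(written, write_tsv(
        props, file.path(out_dir, sprintf("sign_proportions_%s.tsv", lab))))
    }
  }

  ra_cat <- config$relative_association_category %||% "pain"
  if (ra_cat %in% categories) {
    for (lab in setdiff(labels, reference)) {
      ra <- relative_association_table(annotations[[reference]],
                                       annotations[[lab]], ra_cat,
                                       denominator = denominator)
      written <- base::c(written, write_tsv(ra, file.path(
        out_dir, sprintf("relative_association_%s_%s_vs_%s.tsv",
                         ra_cat, reference, lab))))
    }
  }

  cmp_rows <- list()
  for (lab in setdiff(labels, reference)) {
    for (cat in categories) {
      cc <- compare_capture(annotations[[reference]], annotations[[lab]], cat,
                            alternative = alternative)
      cmp_rows[[length(cmp_rows) + 1L]] <- tibble::tibble(
        comparison = sprintf("%s_vs_%s", reference, lab), category = cat,
        universe_size = cc$universe_size, captured_first = cc$captured_first,
        captured_second = cc$captured_second, common = cc$common,
        p = cc$p, log10_p = cc$log10_p)
    }
  }
  cmp <- do.call(rbind, cmp_rows)
  written <- base::c(written, write_tsv(cmp, file.path(out_dir, "comparison_table.tsv")))

  if (length(corpora) == 3L) {
    for (cat in categories) {
      sets <- lapply(annotations, captured_terms, category = cat)
      ov <- three_way_overlap(sets, vocabs[[cat]]$universe_size)
      venn <- tibble::tibble(
        region = base::c(names(ov$regions), "outside_universe",
                         "triple_over_union", "triple_over_universe"),
        value = base::c(unname(ov$regions), ov$remainder,
                        ov$triple_over_union, ov$triple_over_universe))
      written <- base::c(written, write_tsv(
        venn, file.path(out_dir, sprintf("venn_%s.tsv", cat))))
    }
  }

  net_cats <- intersect(
    config$network_categories %||% base::c("disease", "clinical_sign", "pain"),
    categories)
  networks <- list()
  if (length(net_cats) > 0L) {
    for (lab in labels) {
      net <- build_network(annotations[[lab]], net_cats)
      networks[[lab]] <- net
      message(sprintf("network %s: %d nodes, %d edges",
                      lab, nrow(net$nodes), nrow(net$edges)))
      written <- base::c(
        written,
        export_network(net, file.path(out_dir, sprintf("network_%s.graphml", lab)),
                       "graphml"),
        export_network(net, file.path(out_dir, sprintf("network_%s.sif", lab)),
                       "sif"),
        export_network(net, file.path(out_dir, sprintf("network_%s_edges.tsv", lab)),
                       "edge_table"))
      for (seed_term in config$subnetwork_seeds %||% character(0)) {
        st <- normalize_term(seed_term)
        seed_cats <- net$nodes$category[net$nodes$term == st]
        for (sc in seed_cats) {
          sub <- first_neighbour_subnetwork(net, st, category = sc)
          slug <- gsub("[^a-z0-9]+", "_", st)
          # category-qualified filename only when the term is typed twice
          fname <- if (length(seed_cats) > 1L) {
            sprintf("subnetwork_%s_%s__%s.graphml", lab, slug, sc)
          } else {
            sprintf("subnetwork_%s_%s.graphml", lab, slug)
          }
          written <- base::c(written,
                             export_network(sub, file.path(out_dir, fname),
                                            "graphml"))
        }
      }
    }
  }

  manifest <- list(
    mode = "full",
    package_version = as.character(utils::packageVersion("renalmine")),
    reference = reference, alternative = alternative,
    denominator = denominator, categories = categories,
    network_categories = net_cats,
    corpora = lapply(labels, function(lab) list(
      species_label = lab,
      n_records = nrow(corpora[[lab]]$records),
      n_records_annotated = annotations[[lab]]$n_records,
      n_hits = nrow(annotations[[lab]]$hits))),
    files = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(annotations = annotations, comparison = cmp,
                 networks = networks, manifest = manifest, files = written))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
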