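#' Build a term co-occurrence network from an annotated corpus
#'
#' Every captured term of the selected categories becomes a node (typed by
#' category, sized by its record count); an edge joins two nodes when at
#' least one record mentions both terms, and its weight is the number of such
#' records — each record contributes at most 1 to an edge however many
#' surfaces the terms matched on. Edges may join terms of different
#' categories; self-pairs are excluded. Node identity is the (term, category)
#' pair, so the same string appearing in two vocabularies yields two typed
#' nodes.
#'
#' @param annotation a `corpus_annotation`.
#' @param categories category labels to include (must be annotated).
#' @param min_weight drop edges with weight below this (display parity with
#'   thresholded figures; default keeps everything).
#' @return An object of class `cooccurrence_network`: `nodes` (tibble `term`,
#'   `category`, `record_count`), `edges` (tibble `term1`, `category1`,
#'   `term2`, `category2`, `weight`, with endpoint order normalized), and
#'   `provenance`.
#' @export
build_network <- function(annotation, categories, min_weight = 1L) {
  stopifnot(inherits(annotation, "corpus_annotation"))
  if (length(categories) == 0L) stop("no categories selected", call. = FALSE)
  missing_cat <- setdiff(categories, names(annotation$vocabularies))
  if (length(missing_cat) > 0L) {
    stop(sprintf("category '%s' was not annotated", missing_cat[1L]),
         call. = FALSE)
  }
  h <- annotation$hits[annotation$hits$category %in% categories, , drop = FALSE]

  node_key <- function(term, category) paste(category, term, sep = "\r")
  if (nrow(h) == 0L) {
    nodes <- tibble::tibble(term = character(0), category = character(0),
                            record_count = integer(0))
    edges <- tibble::tibble(term1 = character(0), category1 = character(0),
                            term2 = character(0), category2 = character(0),
                            weight = integer(0))
  } else {
    key <- node_key(h$term, h$category)
    ntab <- table(key)
    first <- !duplicated(key)
    nodes <- tibble::tibble(term = h$term[first], category = h$category[first],
                            record_count = as.integer(ntab[key[first]]))
    nodes <- nodes[order(nodes$category, nodes$term), , drop = FALSE]

    # Per record, count each unordered pair of distinct nodes once.
    per_record <- split(key, h$pmid)
    pair_keys <- unlist(lapply(per_record, function(ks) {
      ks <- sort(unique(ks))
      if (length(ks) < 2L) return(character(0))
      idx <- utils::combn(length(ks), 2L)
      paste(ks[idx[1L, ]], ks[idx[2L, ]], sep = "\n")
    }), use.names = FALSE)
    if (length(pair_keys) == 0L) {
      edges <- tibble::tibble(term1 = character(0), category1 = character(0),
                              term2 = character(0), category2 = character(0),
                              weight = integer(0))
    } else {
      etab <- table(pair_keys)
      ends <- strsplit(names(etab), "\n", fixed = TRUE)
      split_key <- function(k) strsplit(k, "\r", fixed = TRUE)[[1L]]
      e1 <- lapply(ends, function(e) split_key(e[[1L]]))
      e2 <- lapply(ends, function(e) split_key(e[[2L]]))
      edges <- tibble::tibble(
        term1 = vapply(e1, `[[`, character(1), 2L),
        category1 = vapply(e1, `[[`, character(1), 1L),
        term2 = vapply(e2, `[[`, character(1), 2L),
        category2 = vapply(e2, `[[`, character(1), 1L),
        weight = as.integer(etab)
      )
      edges <- edges[edges$weight >= min_weight, , drop = FALSE]
      edges <- edges[order(edges$category1, edges$term1,
                           edges$category2, edges$term2), , drop = FALSE]
    }
  }
  structure(
    list(nodes = nodes, edges = edges,
         provenance = list(species_label = annotation$species_label,
                           categories = sort(categories))),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %s [%s]: %d nodes, %d edges\n",
              x$provenance$species_label,
              paste(x$provenance$categories, collapse = ", "),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' First-degree-neighbour sub-network of a seed term
#'
#' The induced subgraph on the seed node and all of its direct neighbours:
#' every edge of the parent network joining two retained nodes is kept,
#' including edges between two neighbours. Idempotent for a fixed seed.
#'
#' @param net a `cooccurrence_network`.
#' @param seed seed term (canonical string).
#' @param category disambiguates the seed when the same term exists in more
#'   than one included category.
#' @return A `cooccurrence_network` restricted to the seed's
#'   first-degree neighbourhood.
#' @export
first_neighbour_subnetwork <- function(net, seed, category = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  seed <- normalize_term(seed)
  cand <- net$nodes[net$nodes$term == seed, , drop = FALSE]
  if (!is.null(category)) cand <- cand[cand$category == category, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop(sprintf("seed term '%s' is not a node of the network", seed),
         call. = FALSE)
  if (nrow(cand) > 1L)
    stop(sprintf("seed term '%s' is ambiguous across categories (%s); give `category`",
                 seed, paste(cand$category, collapse = ", ")), call. = FALSE)
  seed_cat <- cand$category[[1L]]

  e <- net$edges
  touches <- (e$term1 == seed & e$category1 == seed_cat) |
    (e$term2 == seed & e$category2 == seed_cat)
  keyify <- function(term, cat) paste(cat, term, sep = "\r")
  keep_keys <- unique(base::c(
    keyify(seed, seed_cat),
    keyify(e$term1[touches], e$category1[touches]),
    keyify(e$term2[touches], e$category2[touches])
  ))
  node_keys <- keyify(net$nodes$term, net$nodes$category)
  nodes <- net$nodes[node_keys %in% keep_keys, , drop = FALSE]
  keep_edge <- keyify(e$term1, e$category1) %in% keep_keys &
    keyify(e$term2, e$category2) %in% keep_keys
  structure(
    list(nodes = nodes, edges = e[keep_edge, , drop = FALSE],
         provenance = utils::modifyList(net$provenance,
                                        list(subnetwork_seed = seed))),
    class = "cooccurrence_network"
  )
}

#' Look up the weight of one edge
#'
#' @param net a `cooccurrence_network`.
#' @param term1,term2 edge endpoints (canonical terms; endpoint order does
#'   not matter; category qualifiers are ignored, so use distinct terms).
#' @return The edge weight, or 0 when no record co-mentions the two terms.
#' @export
edge_weight <- function(net, term1, term2) {
  stopifnot(inherits(net, "cooccurrence_network"))
  term1 <- normalize_term(term1)
  term2 <- normalize_term(term2)
  e <- net$edges
  hit <- (e$term1 == term1 & e$term2 == term2) |
    (e$term1 == term2 & e$term2 == term1)
  if (!any(hit)) 0L else sum(e$weight[hit])
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Nodes carry `term`, `category` and `record_count` attributes; edges carry
#' `weight`. Vertex names are `category:term` so typed nodes stay distinct.
#'
#' @param net a `cooccurrence_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  vname <- paste(net$nodes$category, net$nodes$term, sep = ":")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = vname,
                            term = net$nodes$term,
                            category = net$nodes$category,
                            record_count = net$nodes$record_count)
  if (nrow(net$edges) > 0L) {
    from <- paste(net$edges$category1, net$edges$term1, sep = ":")
    to <- paste(net$edges$category2, net$edges$term2, sep = ":")
    g <- igraph::add_edges(g, rbind(from, to), weight = net$edges$weight)
  }
  g
}

# Rebuild the S3 network from an igraph graph with the attribute schema of
# as_igraph() (used by the GraphML reader).
network_from_igraph <- function(g, provenance = list()) {
  nodes <- tibble::tibble(
    term = igraph::vertex_attr(g, "term"),
    category = igraph::vertex_attr(g, "category"),
    record_count = as.integer(igraph::vertex_attr(g, "record_count"))
  )
  nodes <- nodes[order(nodes$category, nodes$term), , drop = FALSE]
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0L) {
    t1 <- igraph::vertex_attr(g, "term")[el[, 1]]
    c1 <- igraph::vertex_attr(g, "category")[el[, 1]]
    t2 <- igraph::vertex_attr(g, "term")[el[, 2]]
    c2 <- igraph::vertex_attr(g, "category")[el[, 2]]
    k1 <- paste(c1, t1, sep = "\r")
    k2 <- paste(c2, t2, sep = "\r")
    swap <- k1 > k2
    edges <- tibble::tibble(
      term1 = ifelse(swap, t2, t1), category1 = ifelse(swap, c2, c1),
      term2 = ifelse(swap, t1, t2), category2 = ifelse(swap, c1, c2),
      weight = as.integer(igraph::edge_attr(g, "weight"))
    )
    edges <- edges[order(edges$category1, edges$term1,
                         edges$category2, edges$term2), , drop = FALSE]
  } else {
    edges <- tibble::tibble(term1 = character(0), category1 = character(0),
                            term2 = character(0), category2 = character(0),
                            weight = integer(0))
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "cooccurrence_network")
}

#' Export a co-occurrence network
#'
#' `graphml` (full fidelity, via igraph; re-importable with
#' [read_network_graphml()]), `sif` (Cytoscape simple interaction format,
#' relation `cooccurs_with`, isolated nodes as single-column lines) or
#' `edge_table` (TSV: term1, category1, term2, category2, weight).
#'
#' @param net a `cooccurrence_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"sif"` or `"edge_table"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "sif", "edge_table")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    e <- net$edges
    lines <- sprintf("%s\tcooccurs_with\t%s",
                     paste(e$category1, e$term1, sep = ":"),
                     paste(e$category2, e$term2, sep = ":"))
    in_edge <- paste(net$nodes$category, net$nodes$term, sep = ":") %in%
      base::c(paste(e$category1, e$term1, sep = ":"),
              paste(e$category2, e$term2, sep = ":"))
    isolated <- paste(net$nodes$category[!in_edge], net$nodes$term[!in_edge],
                      sep = ":")
    writeLines(base::c(lines, isolated), path)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a network from GraphML
#'
#' Inverse of [export_network()] with `format = "graphml"`.
#'
#' @param path GraphML file written by this package.
#' @param provenance optional provenance list to attach.
#' @return A `cooccurrence_network`.
#' @export
read_network_graphml <- function(path, provenance = list()) {
  g <- igraph::read_graph(path, format = "graphml")
  network_from_igraph(g, provenance)
}
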