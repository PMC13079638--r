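#' Symptom co-occurrence network
#'
#' Builds an undirected, simple network over the symptoms whose prevalence
#' reaches `node_min_prevalence`. The weight of an edge is the number of
#' respondents reporting both symptoms (codes >= 1); of the candidate edges
#' (weight >= 1), only the top `edge_quantile` fraction by weight is
#' retained (count = ceiling(quantile x candidates)). Ties are broken
#' deterministically by larger combined node occurrence counts, then by
#' lexicographic item-id pair, so raising the quantile never drops a
#' previously retained edge. Nodes isolated after filtering are dropped.
#'
#' @param symptoms n x m severity matrix (codes 0-3, columns named by item).
#' @param cb optional codebook (labels nodes with their system).
#' @param node_min_prevalence minimum item prevalence for node admission.
#' @param edge_quantile fraction of candidate edges to retain, in (0, 1].
#' @return An `ohs_network`: list with `nodes` (id, count, optionally
#'   system), `edges` (from, to, weight), `graph` (igraph), `metrics`, and
#'   `centrality` (per-node degree, normalized degree, normalized
#'   betweenness).
#' @export
cooccurrence_network <- function(symptoms, cb = NULL,
                                 node_min_prevalence = 0.20,
                                 edge_quantile = 0.30) {
  if (!(edge_quantile > 0 && edge_quantile <= 1))
    stop_ohs("edge_quantile must lie in (0, 1]")
  symptoms <- check_severity_matrix(symptoms)
  prev <- item_prevalence(symptoms)
  cand <- prev$item[prev$prevalence >= node_min_prevalence]
  if (length(cand) < 2) {
    warning("fewer than 2 candidate nodes at prevalence >= ",
            node_min_prevalence, "; returning an empty network",
            call. = FALSE)
    return(empty_network())
  }
  pres <- (symptoms[, cand, drop = FALSE] >= 1) * 1L
  counts <- colSums(pres)
  co <- crossprod(pres)

  pairs <- which(upper.tri(co) & co >= 1, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no co-occurring symptom pairs among candidate nodes",
            call. = FALSE)
    return(empty_network())
  }
  edges <- data.frame(from = cand[pairs[, 1]], to = cand[pairs[, 2]],
                      weight = co[pairs], stringsAsFactors = FALSE)
  # Canonical orientation (from < to) so the pair key is unambiguous.
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  combined <- counts[edges$from] + counts[edges$to]
  ord <- order(-edges$weight, -combined, edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  keep <- ceiling(edge_quantile * nrow(edges))
  edges <- edges[seq_len(keep), , drop = FALSE]
  rownames(edges) <- NULL

  used <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(id = used, count = as.integer(counts[used]),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cb)) {
    doms <- item_domains(cb, "symptom")
    nodes$system <- unname(doms[nodes$id])
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  net <- structure(list(nodes = nodes, edges = edges, graph = g),
                   class = "ohs_network")
  m <- network_metrics(net)
  net$metrics <- m$metrics
  net$centrality <- m$centrality
  net
}

empty_network <- function() {
  structure(list(nodes = data.frame(id = character(), count = integer(),
                                    stringsAsFactors = FALSE),
                 edges = data.frame(from = character(), to = character(),
                                    weight = integer(),
                                    stringsAsFactors = FALSE),
                 graph = igraph::make_empty_graph(0, directed = FALSE),
                 metrics = NULL, centrality = NULL),
            class = "ohs_network")
}

#' Topological metrics of a symptom network
#'
#' Density `2E / (N (N - 1))`, average degree `2E / N`, and the average local
#' clustering coefficient (triangles over possible wedges per node, 0 for
#' nodes of degree < 2). Betweenness is computed on the unweighted retained
#' graph and normalized; degree centrality is reported raw and normalized by
#' `N - 1`. Networks with fewer than 2 nodes get `NULL` metrics.
#'
#' @param net an `ohs_network` or an igraph graph (undirected, simple).
#' @return list with `metrics` (n_nodes, n_edges, density, avg_clustering,
#'   avg_degree) and `centrality` (per-node data.frame).
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "ohs_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g) || !igraph::is_simple(g))
    stop_ohs("network metrics require a simple undirected graph")
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N < 2) return(list(metrics = NULL, centrality = NULL))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  metrics <- list(n_nodes = as.integer(N), n_edges = as.integer(E),
                  density = 2 * E / (N * (N - 1)),
                  avg_clustering = mean(loc),
                  avg_degree = 2 * E / N)
  centrality <- data.frame(id = igraph::V(g)$name %||% as.character(seq_len(N)),
                           degree = as.integer(deg),
                           degree_centrality = deg / (N - 1),
                           betweenness = unname(btw),
                           row.names = NULL, stringsAsFactors = FALSE)
  list(metrics = metrics, centrality = centrality)
}

#' Export a symptom network
#'
#' Writes any of: a GraphML file, a plain edge-list CSV
#' (`source,target,weight`), and a JSON metrics file. An optional spring
#' (Fruchterman-Reingold) layout with a fixed seed can be attached to the
#' GraphML export as `x`/`y` vertex attributes; the layout is presentation
#' only and never enters the metrics.
#'
#' @param net an `ohs_network`.
#' @param graphml,edges_csv,metrics_json output paths (`NULL` to skip).
#' @param layout_seed seed for the optional spring layout; `NULL` for no
#'   layout attributes.
#' @return invisible `NULL`.
#' @export
export_network <- function(net, graphml = NULL, edges_csv = NULL,
                           metrics_json = NULL, layout_seed = NULL) {
  stopifnot(inherits(net, "ohs_network"))
  if (!is.null(graphml)) {
    g <- net$graph
    if (!is.null(layout_seed) && igraph::vcount(g) > 0) {
      xy <- with_local_seed(layout_seed, igraph::layout_with_fr(g))
      igraph::V(g)$x <- xy[, 1]
      igraph::V(g)$y <- xy[, 2]
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edges_csv)) {
    e <- net$edges
    names(e) <- c("source", "target", "weight")
    utils::write.csv(e, edges_csv, row.names = FALSE)
  }
  if (!is.null(metrics_json) && !is.null(net$metrics)) {
    jsonlite::write_json(net$metrics, metrics_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' @export
print.ohs_network <- function(x, ...) {
  if (is.null(x$metrics)) {
    cat("<ohs_network> empty\n")
  } else {
    cat(sprintf("<ohs_network> %d nodes, %d edges, density %.3f, avg degree %.2f\n",
                x$metrics$n_nodes, x$metrics$n_edges, x$metrics$density,
                x$metrics$avg_degree))
  }
  invisible(x)
}
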