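# Hub-gene analysis: module graph construction by edge-quantile
# thresholding, per-node topology metrics, and the four-criterion hub score.

#' Build an unweighted graph from a module's within-module weights
#'
#' Keeps within-module edges whose weight reaches the `edge_quantile`
#' quantile of the module's weights (boundary ties are kept) and returns
#' the largest connected component.
#'
#' @param mat gene x gene weight matrix (adjacency or change matrix).
#' @param module character vector of member genes (>= 3).
#' @param edge_quantile quantile in `(0, 1)` above which edges are kept
#'   (default 0.9).
#' @return an [igraph::graph] of the largest component, with an
#'   `isolated` attribute listing genes dropped with the smaller
#'   components.
#' @export
build_module_graph <- function(mat, module, edge_quantile = 0.9) {
  if (edge_quantile <= 0 || edge_quantile >= 1) stopf("edge_quantile must be in (0, 1)")
  if (length(module) < 3) stopf("module must have at least 3 genes")
  idx <- match(module, rownames(mat))
  if (anyNA(idx)) stopf("module gene(s) absent from the weight matrix")
  sub <- mat[idx, idx]
  w <- sub[upper.tri(sub)]
  thr <- stats::quantile(w, edge_quantile, names = FALSE)
  keep <- sub >= thr & upper.tri(sub)
  if (!any(keep)) stopf("no edges at quantile %.2f; lower edge_quantile", edge_quantile)
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = module[ij[, 1]], to = module[ij[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = module)
  )
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  isolated <- igraph::V(g)$name[comp$membership != main]
  g <- igraph::induced_subgraph(g, comp$membership == main)
  attr(g, "isolated") <- isolated
  g
}

#' Per-node topology metrics of an unweighted connected graph
#'
#' Degree (connectivity), unnormalized betweenness centrality, mean
#' shortest-path length to every other node, and the local clustering
#' coefficient (defined as 0 for nodes of degree < 2).
#'
#' @param g connected undirected [igraph::graph] with >= 3 nodes.
#' @return data.frame: `gene`, `connectivity`, `betweenness`,
#'   `path_length`, `clustering_coefficient`.
#' @export
graph_metrics <- function(g) {
  if (igraph::vcount(g) < 3) stopf("graph needs at least 3 nodes")
  if (!igraph::is_connected(g)) stopf("graph must be connected; prune components first")
  dm <- igraph::distances(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  cc[deg < 2] <- 0
  data.frame(
    gene = igraph::V(g)$name,
    connectivity = unname(deg),
    betweenness = unname(igraph::betweenness(g, directed = FALSE, normalized = FALSE)),
    path_length = rowSums(dm) / (nrow(dm) - 1),
    clustering_coefficient = cc,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# qualifying set for "top 20% by rank": boundary ties are inclusive
top_fraction <- function(x, frac = 0.2, lowest = FALSE) {
  n <- length(x)
  k <- ceiling(frac * n)
  cut <- if (lowest) sort(x)[k] else sort(x, decreasing = TRUE)[k]
  if (lowest) x <= cut else x >= cut
}

#' Score module genes for hubness on four topology criteria
#'
#' A gene scores one point for membership of each of: (1) top 20% by
#' connectivity; (2) top 20% by betweenness centrality; (3) bottom 20% by
#' mean path length; (4) bottom 20% by clustering coefficient. Boundary
#' ties are inclusive. Genes with a score of 2 or more are hubs. The
#' report is sorted by descending score, then descending connectivity.
#'
#' @param metrics a [graph_metrics()] table (>= 5 nodes).
#' @return a `hub_scores` data.frame: metrics plus `score` (0-4) and
#'   `is_hub`; attribute `degenerate` is `TRUE` when every node ties into
#'   every criterion set.
#' @export
hub_scores <- function(metrics) {
  if (nrow(metrics) < 5) stopf("hub scoring needs at least 5 nodes")
  crit <- cbind(
    top_fraction(metrics$connectivity),
    top_fraction(metrics$betweenness),
    top_fraction(metrics$path_length, lowest = TRUE),
    top_fraction(metrics$clustering_coefficient, lowest = TRUE)
  )
  out <- metrics
  out$score <- as.integer(rowSums(crit))
  out$is_hub <- out$score >= 2
  out <- out[order(-out$score, -out$connectivity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- all(out$score == 4)
  class(out) <- c("hub_scores", "data.frame")
  out
}

#' Overlap between hub genes and a candidate gene list
#'
#' @param hubs a [hub_scores()] table.
#' @param genes character vector of candidate gene symbols.
#' @param probe_to_gene optional data.frame (`probe_id`, `gene_symbol`)
#'   mapping hub ids to symbols; when `NULL` the hub ids are taken as
#'   symbols directly.
#' @return list with `overlap` (shared symbols), `n_hubs`, `n_candidates`.
#' @export
overlap_with_candidates <- function(hubs, genes, probe_to_gene = NULL) {
  hub_ids <- hubs$gene[hubs$is_hub]
  hub_symbols <- if (is.null(probe_to_gene)) hub_ids else
    unique(probe_to_gene$gene_symbol[match(hub_ids, probe_to_gene$probe_id)])
  hub_symbols <- hub_symbols[!is.na(hub_symbols)]
  list(overlap = sort(intersect(hub_symbols, genes)),
       n_hubs = length(hub_symbols), n_candidates = length(genes))
}
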