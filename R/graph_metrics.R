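#' Degree centrality
#'
#' Number of direct neighbours of each node of a binary interaction network.
#'
#' @param net an undirected [igraph::graph] (e.g. from [build_network]).
#' @return Named numeric vector of degrees, in vertex order.
#' @export
degree_centrality <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Standardized Freeman betweenness centrality
#'
#' For node i, the sum over ordered pairs (j, k) of other nodes of the
#' fraction of equally shortest j-k paths passing through i, divided by
#' `(N - 1)(N - 2)` — twice the number of unordered pairs of nodes other than
#' i — so scores lie in `[0, 1]`. Pairs with no connecting path contribute
#' zero. With fewer than 3 nodes all scores are 0.
#'
#' @param net an undirected [igraph::graph].
#' @return Named numeric vector of standardized betweenness scores.
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  b <- igraph::betweenness(net, directed = FALSE)  # unordered-pair sum
  if (n < 3) return(b * 0)
  2 * b / ((n - 1) * (n - 2))
}

#' Global topology statistics of an interaction network
#'
#' The standard battery for comparing co-occurrence networks across body
#' sites: node and edge counts, the maximum possible edge count
#' `L_max = N(N-1)/2`, density `L / L_max`, diameter (longest finite
#' shortest-path distance), average path length over connected ordered pairs,
#' and transitivity as the mean over nodes of the local clustering
#' coefficient (density of the subgraph induced by each node's neighbours),
#' with nodes of degree < 2 contributing 0.
#'
#' @param net an undirected [igraph::graph] with at least 2 nodes.
#' @return A one-row data frame with columns `nodes`, `edges`, `l_max`,
#'   `density`, `diameter`, `apl`, `transitivity`.
#' @export
global_stats <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("global statistics need at least 2 nodes")
  l <- igraph::ecount(net)
  l_max <- n * (n - 1) / 2
  if (l > 0) {
    diam <- igraph::diameter(net, directed = FALSE, unconnected = TRUE,
                             weights = NA)
    apl <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
    trans <- mean(igraph::transitivity(net, type = "local", isolates = "zero"))
  } else {
    diam <- 0; apl <- NaN; trans <- 0
  }
  data.frame(nodes = n, edges = l, l_max = l_max, density = l / l_max,
             diameter = diam, apl = apl, transitivity = trans)
}

#' Per-node centrality table
#'
#' @param net an undirected [igraph::graph]; `group` vertex attributes are
#'   carried through when present.
#' @return Data frame with columns `otu_id`, `group` (if available),
#'   `degree`, `betweenness`, in vertex order.
#' @export
centrality_table <- function(net) {
  ids <- igraph::V(net)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(net)))
  d <- data.frame(otu_id = ids,
                  degree = unname(degree_centrality(net)),
                  betweenness = unname(betweenness_centrality(net)))
  grp <- igraph::vertex_attr(net, "group")
  if (!is.null(grp)) d <- cbind(d[1], group = grp, d[-1])
  d
}
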