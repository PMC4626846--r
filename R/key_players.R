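#' Size of a top-q fraction of a centrality rank
#'
#' Nearest-integer rounding of `q * N`, half away from zero, with a floor of
#' one node. For a 1254-node network this gives 251 at 20%, 125 at 10% and 63
#' at 5%.
#'
#' @param N network size (number of ranked nodes).
#' @param q fraction in (0, 1].
#' @return Integer top-set size.
#' @export
cutoff_size <- function(N, q) {
  if (N < 1) stop("N must be >= 1")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  max(1L, as.integer(floor(q * N + 0.5)))
}

#' Top set of a centrality ranking
#'
#' Returns the `n_top` highest-scoring nodes. Ties at the boundary are
#' resolved by the stable stored node order (default), giving a deterministic
#' set of exactly `n_top` nodes; with `tie_policy = "include-ties"` every
#' node tied with the boundary score is included and the set may be larger.
#'
#' @param scores named numeric vector of centrality scores (names = node
#'   ids), in stable node order.
#' @param n_top number of nodes to keep; at most `length(scores)`.
#' @param tie_policy `"stable-order"` or `"include-ties"`.
#' @return Character vector of node ids.
#' @export
top_set <- function(scores, n_top,
                    tie_policy = c("stable-order", "include-ties")) {
  tie_policy <- match.arg(tie_policy)
  if (n_top > length(scores)) stop("n_top exceeds number of nodes")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  ord <- order(-scores, seq_along(scores))
  if (tie_policy == "stable-order") {
    ids[ord[seq_len(n_top)]]
  } else {
    boundary <- scores[ord[n_top]]
    ids[scores >= boundary]
  }
}

#' Strict upper tail of the hypergeometric distribution
#'
#' For X ~ Hypergeometric(N, K, n) — x successes in n draws without
#' replacement from a population of N containing K successes — returns
#' `P(X > x)` (the strict tail; the default convention of the group
#' over-representation tables this package produces) or `P(X >= x)` when
#' `strict = FALSE`.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @param x observed number of successes.
#' @param strict if `TRUE` (default) return `P(X > x)`, else `P(X >= x)`.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_upper(1254, 51, 251, 14)  # 0.0670
#' @export
hypergeom_upper <- function(N, K, n, x, strict = TRUE) {
  if (K > N || n > N || x < 0 || x > min(K, n))
    stop("require 0 <= x <= min(K, n), K <= N, n <= N")
  q <- if (strict) x else x - 1
  stats::phyper(q, K, N - K, n, lower.tail = FALSE)
}

#' Group over-representation in a top-centrality set
#'
#' One row per distinct group: total group size K, overlap x with the top
#' set, and the strict upper-tail hypergeometric probability of seeing more
#' than x group members in a random set of the same size. Significance is
#' raw `p < alpha` per group (no multiple-testing correction, which is the
#' reporting convention of the tables this reproduces); a Benjamini-Hochberg
#' adjusted column `p_bh` is emitted alongside for reference but never
#' drives the `significant` flag.
#'
#' @param groups data frame with columns `otu_id` and `group` covering every
#'   network node (see [group_map]).
#' @param top character vector of node ids forming the top set.
#' @param alpha significance level; default 0.05.
#' @return Data frame of class `enrichment_table` with columns `group`, `K`,
#'   `x`, `n`, `N`, `p`, `p_bh`, `significant`.
#' @export
enrich_groups <- function(groups, top, alpha = 0.05) {
  if (nrow(groups) == 0) stop("empty network")
  if (!all(top %in% groups$otu_id)) stop("top set contains unknown node ids")
  N <- nrow(groups)
  n <- length(top)
  K <- table(groups$group)
  x <- table(factor(groups$group[groups$otu_id %in% top],
                    levels = names(K)))
  p <- mapply(function(K, x) hypergeom_upper(N, K, n, x),
              as.integer(K), as.integer(x))
  out <- data.frame(group = names(K), K = as.integer(K), x = as.integer(x),
                    n = n, N = N, p = p,
                    p_bh = stats::p.adjust(p, "BH"),
                    significant = p < alpha, row.names = NULL)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Flag dominant groups
#'
#' A group is dominant when it supplies at least `dominance_fraction` of the
#' nodes in the top-centrality set — important by sheer numbers, whether or
#' not it is statistically over-represented. By convention dominance is
#' evaluated on the top-20% set.
#'
#' @param rows an `enrichment_table` from [enrich_groups].
#' @param dominance_fraction inclusive threshold on `x / n`; default 0.10.
#' @return `rows` with a logical `dominant` column added (or replaced).
#' @export
dominant_groups <- function(rows, dominance_fraction = 0.10) {
  rows$dominant <- rows$x / rows$n >= dominance_fraction
  rows
}

#' Key-player analysis of a network: rank, cut, test
#'
#' Runs the full local analysis for one network: ranks nodes by each
#' requested centrality metric, forms top sets at each cutoff fraction,
#' tests every group for over-representation and flags dominant groups on
#' the top-20% degree set (or the largest requested cutoff if 20% is not
#' among them).
#'
#' @param net an undirected [igraph::graph] with `name` and `group` vertex
#'   attributes.
#' @param metrics subset of `c("degree", "betweenness")`.
#' @param cutoffs fractions in (0, 1]; default `c(0.05, 0.10, 0.20)`.
#' @param alpha significance level for over-representation; default 0.05.
#' @param dominance_fraction see [dominant_groups]; default 0.10.
#' @param tie_policy see [top_set].
#' @return Data frame: the stacked enrichment tables with `metric` and
#'   `cutoff` columns, plus `dominant` (evaluated once per group as above).
#' @export
key_players <- function(net, metrics = c("degree", "betweenness"),
                        cutoffs = c(0.05, 0.10, 0.20), alpha = 0.05,
                        dominance_fraction = 0.10,
                        tie_policy = "stable-order") {
  metrics <- match.arg(metrics, several.ok = TRUE)
  groups <- data.frame(otu_id = igraph::V(net)$name,
                       group = igraph::V(net)$group)
  N <- nrow(groups)
  score_of <- list(degree = degree_centrality,
                   betweenness = betweenness_centrality)
  out <- list()
  for (m in metrics) {
    sc <- score_of[[m]](net)
    names(sc) <- groups$otu_id
    for (q in cutoffs) {
      top <- top_set(sc, cutoff_size(N, q), tie_policy)
      e <- enrich_groups(groups, top, alpha)
      e$metric <- m; e$cutoff <- q
      out[[paste(m, q)]] <- e
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # dominance: top-20% degree set (or largest cutoff available)
  qd <- if (0.20 %in% cutoffs) 0.20 else max(cutoffs)
  md <- if ("degree" %in% metrics) "degree" else metrics[1]
  dom <- dominant_groups(res[res$metric == md & res$cutoff == qd, ],
                         dominance_fraction)
  res$dominant <- dom$dominant[match(res$group, dom$group)]
  attr(res, "tie_policy") <- tie_policy
  res
}
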