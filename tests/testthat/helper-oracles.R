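# Independent oracles used across the suite. These deliberately avoid the
# code paths of the implementation they check (igraph betweenness, phyper).

# Strict upper hypergeometric tail by direct p.m.f. summation.
hyper_upper_enum <- function(N, K, n, x) {
  y <- seq.int(x + 1, min(K, n))
  if (x + 1 > min(K, n)) return(0)
  sum(exp(lchoose(K, y) + lchoose(N - K, n - y) - lchoose(N, n)))
}

# Standardized betweenness by explicit shortest-path counting from an
# adjacency matrix: BFS distances and path counts per source, then for each
# interior node i sum sigma(j->i) * sigma(i->k) / sigma(j->k) over pairs
# whose shortest paths can pass through i.
bc_enum <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- d
          nxt <- union(nxt, w)
        }
        if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- nxt
    }
  }
  bc <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i == j || i == k || j == k) next
      if (is.infinite(dist[j, k])) next
      if (dist[j, i] + dist[i, k] == dist[j, k])
        tot <- tot + sigma[j, i] * sigma[i, k] / sigma[j, k]
    }
    bc[i] <- tot / ((n - 1) * (n - 2))
  }
  bc
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(stats::runif(sum(up)) < p)
  adj + t(adj)
}

graph_from_adj <- function(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")

# toy OTU table written to a temp file
write_toy_table <- function(path,
                            ids = c("o1", "o2", "o3"),
                            counts = matrix(c(1, 0, 3, 4, 5, 0, 0, 2, 8,
                                              1, 1, 1), 3, 4),
                            lineages = c("k__Bacteria;g__Dorea",
                                         "k__Bacteria;f__Lachnospiraceae;g__",
                                         "k__Bacteria;g__Blautia")) {
  d <- data.frame(`#OTU ID` = ids, counts, taxonomy = lineages,
                  check.names = FALSE)
  colnames(d)[2:(1 + ncol(counts))] <- paste0("s", seq_len(ncol(counts)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
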