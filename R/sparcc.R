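#' Variance of a log-ratio of two components
#'
#' The building block of the sparCC procedure: for components i and j with
#' strictly positive fractions across samples, the sample variance of
#' `log(x_i / x_j)`. It is symmetric in (i, j) and zero when i == j or when
#' the two components are proportional.
#'
#' @param fractions strictly positive matrix, rows = components (OTUs),
#'   columns = samples.
#' @param i,j row indices.
#' @return The sample variance (denominator n - 1) of the log-ratio.
#' @export
log_ratio_variance <- function(fractions, i, j) {
  if (ncol(fractions) < 2) stop("need at least 2 samples")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  if (i == j) return(0)
  stats::var(log(fractions[i, ] / fractions[j, ]))
}

# Full log-ratio variance matrix T: t_ij = Var log(x_i/x_j)
# via t_ij = v_i + v_j - 2 cov_ij on the log scale.
variation_matrix <- function(fractions) {
  L <- log(fractions)
  C <- stats::cov(t(L))
  v <- diag(C)
  T <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * C
  T[T < 0] <- 0                      # numerical noise on proportional pairs
  diag(T) <- 0
  T
}

#' Basis correlations from a log-ratio variance matrix
#'
#' Solves the sparCC linear system for the basis (latent absolute-abundance)
#' variances under the sparsity assumption that most basis correlations are
#' near zero, then converts to correlations
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clamped to `[-1, 1]`.
#' Strongly correlated pairs violate the sparsity assumption, so the single
#' strongest pair with `|rho|` above `exclusion_threshold` is excluded from
#' the system and the basis variances re-solved, up to `max_exclusions`
#' times.
#'
#' A basis variance that comes out non-positive (possible on small or
#' degenerate tables) is clamped to a small positive value with a warning;
#' the affected correlations are still reported, clamped to `[-1, 1]`.
#'
#' @param T symmetric log-ratio variance matrix with zero diagonal (from
#'   [log_ratio_variance] over all pairs).
#' @param exclusion_threshold exclude pairs with `|rho|` above this; default
#'   0.1.
#' @param max_exclusions maximum number of excluded pairs; default 10.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
basis_correlations <- function(T, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  D <- nrow(T)
  if (D < 4) stop("sparCC basis approximation needs at least 4 components")
  if (!isSymmetric(unname(T), tol = 1e-8)) stop("T must be symmetric")
  excluded <- matrix(FALSE, D, D)
  solve_rho <- function() {
    # M w2 = t, with M = diag(active counts) + adjacency of active pairs
    active <- !excluded
    diag(active) <- FALSE
    M <- matrix(1, D, D)
    M[excluded] <- 0
    diag(M) <- rowSums(active) - 1
    t_i <- rowSums(T * active)
    w2 <- tryCatch(solve(M, t_i), error = function(e) rep(NA_real_, D))
    if (anyNA(w2) || any(w2 <= 0)) {
      bad <- is.na(w2) | w2 <= 0
      warning(sum(bad), " non-positive basis variance(s); clamped")
      w2[bad] <- .Machine$double.eps^0.5
    }
    w <- sqrt(w2)
    rho <- (outer(w2, w2, "+") - T) / (2 * outer(w, w))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  for (k in seq_len(max_exclusions)) {
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    rho <- solve_rho()
  }
  rho
}

# one Dirichlet-resampled fraction matrix: per sample, a draw from
# Dirichlet(counts + 1); guarantees strictly positive fractions
dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts))
  sweep(g, 2, colSums(g), "/")
}

#' sparCC correlation estimate for an OTU table
#'
#' Averages [basis_correlations] over `n_resamples` Dirichlet-resampled
#' fraction matrices (per sample, a draw from Dirichlet(counts + 1), which
#' handles zero counts without a log-of-zero). Deterministic given `seed`.
#'
#' @param table an [otu_table] (typically already prevalence-filtered), or a
#'   bare count matrix (rows = OTUs).
#' @param n_resamples number of Dirichlet resamples to average; default 20.
#' @param seed integer seed; default 1.
#' @param exclusion_threshold,max_exclusions passed to [basis_correlations].
#' @return Symmetric correlation matrix (OTU x OTU, unit diagonal) with OTU
#'   ids as dimnames when available.
#' @export
sparcc_estimate <- function(table, n_resamples = 20, seed = 1,
                            exclusion_threshold = 0.1, max_exclusions = 10) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (nrow(counts) < 4) stop("sparCC needs at least 4 OTUs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rho <- matrix(0, nrow(counts), nrow(counts))
  for (r in seq_len(n_resamples)) {
    fr <- dirichlet_fractions(counts)
    rho <- rho + basis_correlations(variation_matrix(fr),
                                    exclusion_threshold, max_exclusions)
  }
  rho <- rho / n_resamples
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  rho
}

# save/restore the global RNG state so seeded estimation does not
# perturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Permutation pseudo-p-values for sparCC correlations
#'
#' Builds an edgewise null by independently shuffling each OTU's counts
#' across samples and re-running [sparcc_estimate] on each permuted table.
#' The two-sided pseudo-p-value for edge (i, j) is
#' `(1 + #{|rho_null| >= |rho_obs|}) / (1 + n_permutations)`, so p-values are
#' never 0 and never exceed 1.
#'
#' @param table the [otu_table] (or count matrix) `rho_observed` came from.
#' @param rho_observed correlation matrix from [sparcc_estimate].
#' @param n_permutations number of permuted tables; at least 19 (the
#'   resolution floor for a 0.05 significance level); default 100.
#' @param seed integer seed; default 1. Uses a stream distinct from the one
#'   `sparcc_estimate(seed)` uses for its resampling.
#' @param n_resamples Dirichlet resamples per permuted estimate; default 20.
#' @param exclusion_threshold,max_exclusions passed to [basis_correlations].
#' @return Symmetric matrix of pseudo-p-values in (0, 1]; diagonal set to NA.
#' @export
permutation_pvalues <- function(table, rho_observed, n_permutations = 100,
                                seed = 1, n_resamples = 20,
                                exclusion_threshold = 0.1,
                                max_exclusions = 10) {
  if (n_permutations < 19)
    stop("n_permutations must be >= 19: with fewer, the smallest attainable ",
         "p-value 1/(n_permutations + 1) exceeds 0.05")
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  stopifnot(nrow(counts) == nrow(rho_observed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_permutations)
  exceed <- matrix(0, nrow(counts), nrow(counts))
  abs_obs <- abs(rho_observed)
  for (p in seq_len(n_permutations)) {
    set.seed(perm_seeds[p])
    shuffled <- t(apply(counts, 1, sample))
    rho_null <- sparcc_estimate(shuffled, n_resamples = n_resamples,
                                seed = perm_seeds[p] %% 1000003L,
                                exclusion_threshold = exclusion_threshold,
                                max_exclusions = max_exclusions)
    exceed <- exceed + (abs(rho_null) >= abs_obs)
  }
  pvals <- (1 + exceed) / (1 + n_permutations)
  diag(pvals) <- NA_real_
  dimnames(pvals) <- dimnames(rho_observed)
  pvals
}

#' Full sparCC correlation + significance run
#'
#' Convenience wrapper bundling [sparcc_estimate] and [permutation_pvalues]
#' into a single result object.
#'
#' @inheritParams sparcc_estimate
#' @inheritParams permutation_pvalues
#' @return A list of class `sparcc_result` with elements `rho`, `pvals`,
#'   `n_resamples`, `n_permutations`, `seed`.
#' @export
sparcc_correlation <- function(table, n_resamples = 20, n_permutations = 100,
                               seed = 1, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  rho <- sparcc_estimate(table, n_resamples, seed,
                         exclusion_threshold, max_exclusions)
  pvals <- permutation_pvalues(table, rho, n_permutations, seed = seed + 1L,
                               n_resamples = n_resamples,
                               exclusion_threshold = exclusion_threshold,
                               max_exclusions = max_exclusions)
  structure(list(rho = rho, pvals = pvals, n_resamples = n_resamples,
                 n_permutations = n_permutations, seed = seed),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat(sprintf("sparcc_result: %d OTUs, %d resamples, %d permutations, seed %d\n",
              nrow(x$rho), x$n_resamples, x$n_permutations, x$seed))
  invisible(x)
}

#' Build the binary interaction network of significant correlations
#'
#' An edge joins OTUs i and j when their permutation pseudo-p-value is
#' strictly below `alpha`; the sign and magnitude of the correlation are not
#' used (edges are unweighted and undirected). Every OTU stays in the network
#' as a node even when isolated.
#'
#' @param rho correlation matrix (used for shape/ids only).
#' @param pvals p-value matrix from [permutation_pvalues].
#' @param alpha significance level; edges require `p < alpha` (strict);
#'   default 0.05.
#' @param nodes OTU ids; default taken from matrix dimnames.
#' @param groups optional group label per node, attached as the `group`
#'   vertex attribute.
#' @return An undirected simple [igraph::graph] with `name` (and optionally
#'   `group`) vertex attributes and an `alpha` graph attribute.
#' @export
build_network <- function(rho, pvals, alpha = 0.05, nodes = rownames(rho),
                          groups = NULL) {
  if (!all(dim(rho) == dim(pvals)))
    stop("rho and pvals must have the same shape")
  if (is.null(nodes)) nodes <- paste0("otu", seq_len(nrow(rho)))
  if (length(nodes) != nrow(rho))
    stop("node list length does not match matrix shape")
  sig <- !is.na(pvals) & pvals < alpha
  sig[lower.tri(sig, diag = TRUE)] <- FALSE
  idx <- which(sig, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(idx) > 0)
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
  if (!is.null(groups)) {
    if (length(groups) != length(nodes))
      stop("groups length does not match node list")
    g <- igraph::set_vertex_attr(g, "group", value = groups)
  }
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g
}
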