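#' Specification of a synthetic microbial community
#'
#' Describes a community with known ground truth for exercising the whole
#' pipeline: OTUs partitioned into labelled groups, a subset of "hub" groups
#' whose members have a planted pairwise latent correlation, heavy-tailed
#' baseline abundances, and fixed-depth compositional sampling.
#'
#' @param n_otus total number of OTUs.
#' @param n_samples number of samples.
#' @param groups named integer vector: group label -> number of OTUs; sizes
#'   must sum to `n_otus`.
#' @param hub_groups character vector of group labels with planted
#'   within-group correlation; must be a subset of `names(groups)` and each
#'   must have size >= 2.
#' @param block_rho latent correlation planted within each hub group, in
#'   (0, 1); default 0.8.
#' @param log_mean,log_sd mean and standard deviation of the per-sample
#'   latent log-abundance fluctuation; defaults 0 and 1.
#' @param base_sd standard deviation of the per-OTU baseline log-mean
#'   (controls how heavy-tailed the relative abundances are across OTUs);
#'   default 1.5.
#' @param depth reads per sample (every sample is sampled to exactly this
#'   depth); default 5000.
#' @param seed integer seed; default 1.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_otus = 60, n_samples = 300,
                           groups = stats::setNames(rep(10L, 6),
                                                    paste0("Group", LETTERS[1:6])),
                           hub_groups = "GroupA", block_rho = 0.8,
                           log_mean = 0, log_sd = 1, base_sd = 1.5,
                           depth = 5000, seed = 1) {
  if (sum(groups) != n_otus) stop("group sizes must sum to n_otus")
  if (!all(hub_groups %in% names(groups)))
    stop("hub_groups must be a subset of group labels")
  if (any(groups[hub_groups] < 2))
    stop("a hub group needs at least 2 OTUs to correlate")
  if (length(hub_groups) > 0 && (block_rho <= 0 || block_rho >= 1))
    stop("block_rho must be in (0, 1)")
  if (depth <= 0) stop("depth must be positive")
  structure(list(n_otus = n_otus, n_samples = n_samples, groups = groups,
                 hub_groups = hub_groups, block_rho = block_rho,
                 log_mean = log_mean, log_sd = log_sd, base_sd = base_sd,
                 depth = depth, seed = seed),
            class = "community_spec")
}

#' Generate a synthetic OTU table with planted hub structure
#'
#' Latent log-abundances are drawn per sample from a multivariate normal
#' whose correlation matrix is `block_rho` between members of the same hub
#' group and 0 elsewhere; per-OTU baseline log-means are drawn once from
#' `N(log_mean, base_sd)` to give heavy-tailed relative abundances. Counts
#' are drawn per sample as a multinomial of size `depth` over the
#' exponentiated, normalised latent abundances, so each sample's counts sum
#' to `depth` exactly (compositional closure). Greengenes-style lineage
#' strings are synthesised per group so the lineage parser is exercised for
#' real. Fully deterministic given `spec$seed`.
#'
#' @param spec a [community_spec].
#' @return An [otu_table] with attributes `truth` (character vector of hub
#'   group labels), `groups` (the [group_map]-style data frame) and `latent`
#'   (the latent log-abundance matrix, OTU x sample, for calibration
#'   checks).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  D <- spec$n_otus; S <- spec$n_samples
  labels <- rep(names(spec$groups), spec$groups)
  base <- stats::rnorm(D, spec$log_mean, spec$base_sd)
  # block-correlated latent fluctuations via a shared group factor:
  # z = sqrt(rho) * u_group + sqrt(1-rho) * eps has corr rho within blocks
  eps <- matrix(stats::rnorm(D * S), D, S)
  z <- eps
  for (hg in spec$hub_groups) {
    idx <- which(labels == hg)
    u <- stats::rnorm(S)
    z[idx, ] <- sqrt(spec$block_rho) * matrix(u, length(idx), S, byrow = TRUE) +
      sqrt(1 - spec$block_rho) * eps[idx, , drop = FALSE]
  }
  latent <- base + spec$log_sd * z
  abund <- exp(latent)
  frac <- sweep(abund, 2, colSums(abund), "/")
  counts <- apply(frac, 2, function(p) stats::rmultinom(1, spec$depth, p))
  otu_ids <- sprintf("otu%04d", seq_len(D))
  within <- stats::ave(seq_len(D), labels, FUN = seq_along)
  lineages <- sprintf("k__Bacteria;p__SimPhylum;c__SimClass;o__SimOrder;f__%s;g__%s;s__sp%d",
                      paste0(labels, "ceae"), labels, within)
  tab <- otu_table(counts, otu_ids, lineages, site = "synthetic")
  attr(tab, "truth") <- spec$hub_groups
  attr(tab, "groups") <- data.frame(otu_id = otu_ids, group = labels)
  attr(tab, "latent") <- latent
  tab
}

#' Ground-truth key groups of a synthetic community
#'
#' The hub groups a correct pipeline should flag as key (over-represented in
#' the top of the centrality rank).
#'
#' @param spec a [community_spec].
#' @return Character vector of group labels (possibly empty).
#' @export
ground_truth_keys <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  spec$hub_groups
}
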