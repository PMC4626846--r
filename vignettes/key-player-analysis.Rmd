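---
title: "Identifying key taxonomic groups in microbial co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying key taxonomic groups in microbial co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microkey)
```

## The problem

Amplicon surveys of host-associated microbial communities yield OTU count
tables: for each body site, integer read counts of hundreds to thousands of
operational taxonomic units across many samples. Which organisms hold these
communities together? Two distinct notions of importance are in play:

* **key (keystone-like) groups** — taxonomic groups whose members sit in
  disproportionately central positions of the co-occurrence network, more
  often than their abundance alone would predict; and
* **dominant groups** — groups that supply a large share of the central
  nodes by sheer numbers, whether or not that share is statistically
  surprising.

`microkey` implements the full chain from a raw count table to these two
calls: prevalence filtering, compositional correlation inference (sparCC),
binary network construction at a significance threshold, topology and
centrality computation, and a hypergeometric over-representation test of
each group in the top of the centrality rank.

## The pipeline, stage by stage

### Prevalence filtering

Per body site, only OTUs detected (count > 0) in at least a fraction
`theta` of the samples are retained; the default `theta = 0.20` focuses the
network on the resident community rather than sporadic visitors. The
boundary is inclusive ("at least 20%"): an OTU present in exactly 4 of 20
samples survives. Samples with a zero total count are dropped first, with a
warning, so prevalence is always a well-defined fraction. Filtering is
idempotent and monotone in `theta`.

### sparCC correlations

Read counts are compositional: only relative abundances are observed, so
naive Pearson correlations between fractions are spurious. sparCC works
from the variances of pairwise log-ratios,
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$, which are invariant to per-sample
scaling. Writing $\omega_i^2$ for the latent (basis) variance of component
$i$, $t_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$. Under
the sparsity assumption that most basis correlations are near zero, the
row sums of the $t$ matrix give a linear system for the $\omega_i^2$, and

$$\rho_{ij} = \frac{\omega_i^2 + \omega_j^2 - t_{ij}}{2\,\omega_i\omega_j},$$

clamped to $[-1, 1]$. Pairs whose estimated $|\rho|$ exceeds an exclusion
threshold violate the sparsity assumption, so the single strongest such
pair is removed from the system and the basis variances re-solved, up to
`max_exclusions` times.

Zero counts are handled by resampling: each sample's fraction vector is
drawn from a Dirichlet with parameters `counts + 1`, and the correlation
estimate is the average over `n_resamples` such draws. All randomness is
governed by an explicit seed, and the caller's RNG state is untouched.

Tunable parameters, with defaults:

| parameter             | default | meaning |
|-----------------------|---------|---------|
| `n_resamples`         | 20      | Dirichlet resamples averaged per estimate |
| `exclusion_threshold` | 0.1     | \|rho\| above which a pair is excluded from the basis system |
| `max_exclusions`      | 10      | cap on excluded pairs |
| `n_permutations`      | 100     | permuted tables for the significance null |
| `alpha`               | 0.05    | edge-selection threshold (strict `p < alpha`) |

These are the conventional settings of the sparCC procedure; all are
configurable per run.

### Significance and the binary network

The null distribution for each pair is built by independently shuffling
each OTU's counts across samples and re-running the full estimator on every
permuted table. The two-sided pseudo-p-value is
$(1 + \#\{|\rho_{\mathrm{null}}| \ge |\rho_{\mathrm{obs}}|\})/(1 + P)$ with
$P$ permutations — never exactly zero, never above one. With the default
$P = 100$ the smallest attainable p-value is $1/101 \approx 0.0099$ and the
largest attainable value below 0.05 is $5/101 \approx 0.0495$, so the
nominal 0.05 level is effectively achievable; $P \ge 19$ is enforced
because below that no p-value can clear 0.05 at all. An edge joins two
OTUs when `p < alpha`, strictly; the sign of the correlation is discarded,
so edges are binary and undirected, and isolated OTUs remain as network
nodes.

### Topology and centrality

Global statistics per network: node and edge counts, density
$L / \binom{N}{2}$, diameter (longest finite shortest-path distance),
average path length over connected pairs, and transitivity as the mean
over nodes of the local clustering coefficient — the density of the
subgraph induced by a node's neighbours — with nodes of degree < 2
contributing zero to the mean. Counting degree-<2 nodes as zero (rather
than dropping them) keeps the average over all nodes; this is the common
convention and the one the statistic battery here follows. Distances are
unweighted hop counts. Disconnected pairs are excluded from the average
path length and ignored for the diameter; in dense co-occurrence networks
(diameters of 2–3) this rarely matters, but it makes the statistics well
defined on sparse synthetic networks too.

Local centralities are the degree (neighbour count) and the standardized
Freeman betweenness

$$BC_i = \frac{\sum_{j \ne k \ne i} g_{jk}(i)/g_{jk}}{(N-1)(N-2)},$$

where $g_{jk}$ counts equally shortest $j$–$k$ paths and $g_{jk}(i)$ those
passing through $i$; the sum runs over ordered pairs and the denominator is
twice the number of pairs excluding $i$, so scores lie in $[0, 1]$. (The
field sometimes labels this index "non-normalized"; the formula implemented
is the standardized form with that explicit denominator, which is what the
scores in this package's outputs mean.) Shortest-path machinery is
delegated to igraph; the standardized scores are checked in the test suite
against an independent exhaustive shortest-path-counting oracle.

### Key and dominant groups

Nodes are ranked by a centrality metric and the top fraction $q$ is cut at
`cutoff_size(N, q)` — nearest-integer rounding of $qN$, half away from
zero, floor of one. For a 1254-node network this yields 251, 125 and 63
nodes at $q = 0.20, 0.10, 0.05$; the rounding rule is pinned down by all
three sizes (a ceiling rule would give 126 at 10% and contradict the
singleton-group probabilities it implies). Boundary ties are broken by
stable stored node order by default, which makes runs deterministic; an
`include-ties` policy that admits every boundary-tied node is available,
and the policy used is recorded in the report.

Each group with $K$ members in an $N$-node network, $x$ of them inside a
top set of size $n$, is tested with the **strict** upper hypergeometric
tail $P(X > x)$. The strict tail (rather than $P(X \ge x)$) is the
convention of the group tables this package emits: under it a singleton
group outside the top set scores $P(X \ge 1) = n/N$ and a singleton group
inside it scores exactly 0. The conventional $P(X \ge x)$ is available via
`strict = FALSE`. Significance is the raw `p < alpha` per group — no
multiple-testing correction, matching the reporting convention of such
tables — but a Benjamini–Hochberg column is emitted alongside for readers
who want it; it never drives the `significant` flag.

A group is **dominant** when it supplies at least `dominance_fraction`
(default 10%, inclusive) of the top-20% set, regardless of significance.
Dominance is evaluated on the top-20% degree set even when other cutoffs
are also requested.

## The synthetic community generator

Real per-site tables from public repositories require downloads and
processing choices that are out of scope here, so the package ships a
generator with known ground truth. Latent per-sample log-abundances are
multivariate normal with correlation `block_rho` between members of
designated *hub groups* and zero elsewhere; per-OTU baseline log-means are
drawn from $N(\texttt{log\_mean}, \texttt{base\_sd})$, giving heavy-tailed
relative abundances; counts are a fixed-depth multinomial over the
exponentiated, normalised abundances, so column sums equal `depth` exactly
and the data are genuinely compositional. A log-normal latent law with
multinomial closure (rather than a Dirichlet-multinomial) is used so the
planted correlation structure survives closure in a controlled way. Hub
groups become central purely through correlation density — every
within-block pair is correlated — mirroring how degree concentrates in a
sparCC graph; no degree sequence is imposed. Lineage strings are
synthesised in rank-prefixed form so the real taxonomy parser is exercised
end to end.

Defaults: 60 OTUs in six groups of ten, one hub group at
`block_rho = 0.8`, 300 samples at depth 5000, `base_sd = 1.5` (relative
abundances spanning roughly three orders of magnitude, as in real 16S
census data) and unit per-sample log fluctuation. What the generator does
*not* emulate: real taxon frequency distributions, body-site-specific
compositions, overdispersion beyond the log-normal latent variance, or
sequencing noise. Tests that pass on these communities demonstrate that
the statistical machinery behaves as designed under its own model; they do
not certify recovery rates on real survey data.

## Numerical and design choices

* Compositional closure attenuates planted correlations: a hub block at
  latent $\rho = 0.8$ typically shows sparCC estimates near 0.4–0.5, which
  is expected (the block occupies a sixth of the community) and still
  separates cleanly from the near-zero background.
* A non-positive basis variance can arise on small or degenerate tables;
  it is clamped to a small positive value with a warning rather than
  aborting, and the affected correlations remain clamped to $[-1, 1]$.
* Problem sizes used by the test suite: the type-I-error study runs 20
  seeds of a 50-OTU, 200-sample independent community with 100
  permutations; the recovery study runs 20 seeds of the default planted-hub
  community. Both reflect the study conditions stated above.
* The permutation seed stream is derived from, but distinct from, the
  estimation seed, so estimate and null never share draws.

## Limitations

* Co-occurrence is not interaction: significant sparCC edges may reflect
  indirect effects or shared habitat preference, and edge signs are
  deliberately discarded.
* The pipeline pools samples per site; individual-level variability is out
  of reach by design.
* The hypergeometric test treats the top set as a simple random draw under
  the null; correlated centralities within a group make the test
  anti-conservative in principle, which is one reason the dominant-group
  criterion is reported alongside.

## A worked example

```{r example, eval = FALSE}
spec <- community_spec(seed = 7)          # 60 OTUs, hub GroupA at rho = 0.8
tab  <- prevalence_filter(generate_table(spec), 0.20)
cr   <- sparcc_correlation(tab, seed = 7)
gm   <- group_map(tab)
net  <- build_network(cr$rho, cr$pvals, alpha = 0.05,
                      nodes = gm$otu_id, groups = gm$group)
global_stats(net)
kp <- key_players(net)
subset(kp, metric == "degree" & cutoff == 0.20)
```

The hub group ends up with essentially all of its members in the top-20%
degree set (`x` close to 10 of `n = 12`) and a tail probability
indistinguishable from zero, while non-hub groups hover at unremarkable
p-values — the behaviour the recovery tests quantify over 20 seeds.
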