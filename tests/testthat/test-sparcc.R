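test_that("log-ratio variance matches a hand-computed oracle and is symmetric", {
  fr <- matrix(c(0.1, 0.3, 0.2, 0.4,
                 0.5, 0.2, 0.1, 0.2,
                 0.4, 0.5, 0.7, 0.4), 3, 4, byrow = TRUE)
  lr <- log(fr[1, ] / fr[2, ])
  expect_equal(log_ratio_variance(fr, 1, 2), sum((lr - mean(lr))^2) / 3)
  expect_equal(log_ratio_variance(fr, 1, 2), log_ratio_variance(fr, 2, 1))
  expect_equal(log_ratio_variance(fr, 2, 2), 0)
  # proportional components have zero log-ratio variance
  fr2 <- rbind(fr, 2 * fr[1, ])
  expect_equal(log_ratio_variance(fr2, 1, 4), 0)
  expect_error(log_ratio_variance(fr[, 1, drop = FALSE], 1, 2), "2 samples")
  # the full matrix agrees with the pairwise definition
  Tm <- microkey:::variation_matrix(fr)
  for (i in 1:3) for (j in 1:3)
    expect_equal(Tm[i, j], log_ratio_variance(fr, i, j), tolerance = 1e-12)
})

test_that("basis correlations are near zero for independent components", {
  set.seed(42)
  ab <- matrix(exp(rnorm(50 * 200)), 50, 200)
  fr <- sweep(ab, 2, colSums(ab), "/")
  rho <- basis_correlations(microkey:::variation_matrix(fr))
  expect_equal(diag(rho), rep(1, 50))
  off <- rho[upper.tri(rho)]
  expect_lt(mean(abs(off)), 0.1)
  expect_true(all(abs(off) <= 1))
})

test_that("a planted perfectly co-varying pair is recovered after exclusions", {
  set.seed(7)
  ab <- matrix(exp(rnorm(50 * 200)), 50, 200)
  ab[2, ] <- 3 * ab[1, ] * exp(rnorm(200, sd = 0.05))
  fr <- sweep(ab, 2, colSums(ab), "/")
  rho <- basis_correlations(microkey:::variation_matrix(fr))
  expect_gt(rho[1, 2], 0.9)
})

test_that("sparcc estimates are deterministic, symmetric and clamped", {
  set.seed(5)
  counts <- matrix(rpois(20 * 40, 30), 20, 40)
  r1 <- sparcc_estimate(counts, n_resamples = 5, seed = 99)
  r2 <- sparcc_estimate(counts, n_resamples = 5, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1, t(r1))
  expect_true(all(r1 >= -1 & r1 <= 1))
  expect_error(sparcc_estimate(counts[1:3, ]), "at least 4")
})

test_that("log-ratio machinery is invariant to per-sample rescaling", {
  set.seed(8)
  ab <- matrix(exp(rnorm(10 * 50)), 10, 50)
  scaled <- sweep(ab, 2, runif(50, 0.1, 10), "*")
  fr1 <- sweep(ab, 2, colSums(ab), "/")
  fr2 <- sweep(scaled, 2, colSums(scaled), "/")
  expect_equal(microkey:::variation_matrix(fr1),
               microkey:::variation_matrix(fr2), tolerance = 1e-12)
})

test_that("Monte-Carlo averaging tightens the estimate", {
  set.seed(3)
  counts <- matrix(rnbinom(30 * 80, mu = 40, size = 1), 30, 80)
  d <- function(nr) {
    a <- sparcc_estimate(counts, n_resamples = nr, seed = 1)
    b <- sparcc_estimate(counts, n_resamples = nr, seed = 2)
    mean(abs(a - b))
  }
  expect_lt(d(20), d(1))
})

test_that("permutation p-values respect the +1 correction and its bounds", {
  set.seed(21)
  counts <- matrix(rpois(8 * 30, 20), 8, 30)
  rho <- sparcc_estimate(counts, n_resamples = 3, seed = 1)
  # small permuted tables occasionally trip the clamped-basis-variance
  # fallback; that warning is its documented behaviour, not a failure here
  pv <- suppressWarnings(
    permutation_pvalues(counts, rho, n_permutations = 19, seed = 2,
                        n_resamples = 3))
  off <- pv[upper.tri(pv)]
  expect_true(all(off >= 1 / 20 & off <= 1))
  expect_equal(pv, t(pv))
  expect_true(all(is.na(diag(pv))))
  # an observed correlation of 0 can never beat the null
  pv0 <- suppressWarnings(
    permutation_pvalues(counts, matrix(0, 8, 8), n_permutations = 19,
                        seed = 2, n_resamples = 3))
  expect_true(all(pv0[upper.tri(pv0)] == 1))
  expect_error(permutation_pvalues(counts, rho, n_permutations = 10),
               "resolution|>= 19|floor")
})

test_that("network edges require strictly significant p-values", {
  rho <- diag(5); pv <- matrix(1, 5, 5)
  pv[1, 2] <- pv[2, 1] <- 0.04
  pv[1, 3] <- pv[3, 1] <- 0.05      # boundary: excluded
  pv[2, 4] <- pv[4, 2] <- 0.001
  pv[3, 5] <- pv[5, 3] <- 0.01
  net <- build_network(rho, pv, alpha = 0.05,
                       nodes = letters[1:5], groups = rep("g", 5))
  expect_equal(igraph::ecount(net), 3)
  expect_equal(igraph::vcount(net), 5)
  expect_false(igraph::are_adjacent(net, "a", "c"))
  # all p = 1: nodes persist, no edges
  net0 <- build_network(rho, matrix(1, 5, 5), nodes = letters[1:5])
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 5)
  expect_error(build_network(rho, matrix(1, 4, 4)), "shape")
})
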