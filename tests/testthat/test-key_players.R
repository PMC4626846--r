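test_that("cutoff sizes use nearest-integer rounding with a floor of one", {
  expect_identical(cutoff_size(1254, 0.20), 251L)
  expect_identical(cutoff_size(1254, 0.10), 125L)
  expect_identical(cutoff_size(1254, 0.05), 63L)
  expect_identical(cutoff_size(10, 0.24), 2L)
  expect_identical(cutoff_size(10, 0.25), 3L)   # half rounds away from zero
  expect_identical(cutoff_size(3, 0.05), 1L)    # floor of one
  expect_error(cutoff_size(100, 0), "q")
  expect_error(cutoff_size(100, 1.5), "q")
})

test_that("top sets honour the tie policy", {
  sc <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  expect_equal(top_set(sc, 2), c("a", "b"))
  tied <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(top_set(tied, 2, "stable-order"), c("a", "b"))
  sc2 <- c(a = 5, b = 3, c = 3, d = 1)
  expect_equal(top_set(sc2, 2, "stable-order"), c("a", "b"))
  expect_setequal(top_set(sc2, 2, "include-ties"), c("a", "b", "c"))
  expect_error(top_set(sc, 6), "n_top")
})

test_that("strict upper tail matches exhaustive p.m.f. summation (N <= 30)", {
  for (N in 2:30) {
    for (K in 0:N) {
      for (n in c(0, 1, N %/% 3, N %/% 2, N - 1, N)) {
        for (x in 0:min(K, n)) {
          expect_equal(hypergeom_upper(N, K, n, x),
                       hyper_upper_enum(N, K, n, x), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("tail conventions, complements and monotonicity behave", {
  expect_equal(hypergeom_upper(50, 10, 20, 3, strict = FALSE),
               hypergeom_upper(50, 10, 20, 2, strict = TRUE))
  # complement: P(X > x) + P(X <= x) = 1
  for (x in 0:8)
    expect_equal(hypergeom_upper(40, 8, 15, x) +
                   phyper(x, 8, 32, 15), 1, tolerance = 1e-12)
  # p decreases in x until the tail empties, increases in K at fixed x
  p_x <- vapply(0:8, function(x) hypergeom_upper(40, 8, 15, x), numeric(1))
  expect_true(all(diff(p_x) < 0))
  p_K <- vapply(3:20, function(K) hypergeom_upper(40, K, 15, 3), numeric(1))
  expect_true(all(diff(p_K) > 0))
  expect_error(hypergeom_upper(10, 11, 5, 1), "K <= N")
  expect_error(hypergeom_upper(10, 5, 5, 6), "x")
})

test_that("the published stool group table reproduces at all four cutoffs", {
  d <- stool_groups()
  N <- 1254
  expect_equal(sum(d$total), N)
  cols <- list(c("d20", "p_d20", 0.20), c("b20", "p_b20", 0.20),
               c("d10", "p_d10", 0.10), c("d5", "p_d5", 0.05))
  for (cl in cols) {
    n_top <- cutoff_size(N, as.numeric(cl[3]))
    expect_equal(sum(d[[cl[1]]]), n_top)
    p <- mapply(function(K, x) hypergeom_upper(N, K, n_top, x),
                d$total, d[[cl[1]]])
    expect_equal(round(p, 4), d[[cl[2]]])
  }
})

test_that("group enrichment accounts for every node exactly once", {
  set.seed(9)
  groups <- data.frame(otu_id = sprintf("o%03d", 1:120),
                       group = sample(LETTERS[1:6], 120, replace = TRUE))
  sc <- stats::setNames(rnorm(120), groups$otu_id)
  top <- top_set(sc, cutoff_size(120, 0.2))
  e <- enrich_groups(groups, top)
  expect_equal(sum(e$K), 120)
  expect_equal(sum(e$x), length(top))
  expect_true(all(e$p >= 0 & e$p <= 1))
  expect_true(all(e$x <= pmin(e$K, e$n)))
  # a group covering the whole population saturates the top set with p = 0
  g1 <- data.frame(otu_id = groups$otu_id, group = "all")
  e1 <- enrich_groups(g1, top)
  expect_equal(e1$x, length(top))
  expect_equal(e1$p, 0)
  expect_error(enrich_groups(groups[0, ], top), "empty")
})

test_that("dominance is an inclusive 10% share of the top set", {
  rows <- data.frame(group = c("big", "edge", "under"),
                     K = c(640, 30, 30), x = c(157, 26, 25),
                     n = 251, N = 1254, p = 0.5, significant = FALSE)
  out <- dominant_groups(rows)
  expect_equal(out$dominant, c(TRUE, TRUE, FALSE))  # 26/251 >= 0.1 > 25/251
})

test_that("key_players stacks metrics and cutoffs coherently", {
  set.seed(31)
  adj <- random_graph(30, 0.2)
  g <- graph_from_adj(adj)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("o%02d", 1:30))
  g <- igraph::set_vertex_attr(g, "group",
                               value = rep(c("A", "B", "C"), each = 10))
  kp <- key_players(g)
  expect_equal(nrow(kp), 3 * 3 * 2)  # groups x cutoffs x metrics
  expect_true(all(tapply(kp$x, interaction(kp$metric, kp$cutoff), sum) ==
                    tapply(kp$n, interaction(kp$metric, kp$cutoff), unique)))
  expect_false(any(is.na(kp$dominant)))
})
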