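test_that("window counts match hand-enumerated examples", {
  # symmetric scatter, focal at the middle value
  wc <- window_counts(1:5, 1:5, k = 3, b = 0.4)
  expect_equal(wc[c("n_x", "n_y", "n_xy")], list(n_x = 2L, n_y = 2L, n_xy = 2L))
  # perfect anti-correlation still co-localizes windows at the extremes
  wc2 <- window_counts(1:5, 5:1, k = 1, b = 0.4)
  expect_equal(wc2$n_xy, 2L)
  # window fraction covering everything
  wc3 <- window_counts(runif(6), runif(6), k = 2, b = 0.99)
  expect_equal(wc3[c("n_x", "n_y", "n_xy")], list(n_x = 6L, n_y = 6L, n_xy = 6L))
  expect_error(window_counts(1:2, 1:2, 1, 0.5), class = "igan_too_few_pairs")
})

test_that("window counts equal exhaustive enumeration on random scatters", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    # mix of continuous and heavily tied marginals
    x <- if (rep %% 2) runif(n) else rpois(n, 1.5)
    y <- if (rep %% 3) rnorm(n) else rpois(n, 1)
    k <- sample(n, 1)
    b <- runif(1, 0.05, 0.9)
    tie <- sample(n) # an arbitrary explicit tie order, shared by both paths
    expect_identical(window_counts(x, y, k, b, tie_order = tie)[c("n_x", "n_y", "n_xy")],
                     oracle_window_counts(x, y, k, b, tie_order = tie))
  }
})

test_that("association statistic matches the closed form and flags degeneracy", {
  s <- association_statistic(list(n_x = 10, n_y = 10, n_xy = 10), n = 100)
  expect_equal(s, 9.9499, tolerance = 1e-4)
  expect_equal(s, oracle_statistic(10, 10, 10, 100), tolerance = 1e-12)
  # independence point: n_xy = n_x n_y / n exactly
  expect_equal(association_statistic(list(n_x = 20, n_y = 10, n_xy = 2), 100), 0)
  # empty joint window is negative evidence
  expect_lt(association_statistic(list(n_x = 5, n_y = 5, n_xy = 0), 50), 0)
  # degenerate marginals
  expect_true(is.na(association_statistic(list(n_x = 0, n_y = 5, n_xy = 0), 50)))
  expect_true(is.na(association_statistic(list(n_x = 50, n_y = 5, n_xy = 5), 50)))
  # vectorized over several counts at once
  sv <- association_statistic(list(n_x = c(10, 20), n_y = c(10, 10),
                                   n_xy = c(10, 2)), 100)
  expect_equal(sv[2], 0)
})

test_that("gene-pair test: degenerate marginals and strong coupling", {
  n <- 200
  expect_equal(sum(test_gene_pair(rep(2, n), rnorm(n))), 0L) # constant x
  set.seed(11)
  # perfectly rank-correlated pair lights up far beyond the nominal level
  x <- sort(runif(n))
  h <- test_gene_pair(x, x^2, b = 0.1, alpha = 0.01)
  expect_gt(mean(h), 0.2)
  # and far beyond its own shuffled control
  h0 <- test_gene_pair(x, sample(x^2), b = 0.1, alpha = 0.01)
  expect_gt(sum(h), 10 * max(sum(h0), 1))
})

test_that("type-I error stays near the nominal level for independent scatters", {
  set.seed(23)
  n <- 500
  rates <- replicate(4, mean(test_gene_pair(runif(n), runif(n))))
  band <- 3 * sqrt(0.01 * 0.99 / n)
  expect_lt(abs(mean(rates) - 0.01), band)
})

test_that("copula-coupled pairs are detected above the downstream threshold", {
  set.seed(31)
  n <- 200
  detected <- replicate(10, {
    z <- rnorm(n)
    y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n) # rank correlation ~ 0.89
    sum(test_gene_pair(z, y)) > 0.01 * n
  })
  expect_gt(mean(detected), 0.5)
})

test_that("pair order permutation permutes the indicators identically", {
  set.seed(13)
  n <- 120
  x <- rnorm(n); y <- 0.5 * x + rnorm(n) # continuous: tie order irrelevant
  h <- test_gene_pair(x, y)
  p <- sample(n)
  hp <- test_gene_pair(x[p], y[p])
  expect_identical(as.integer(hp), as.integer(h)[p])
})

test_that("networks are directional and consistent with the standalone test", {
  sim <- simulate_spatial(sim_config("pairs", n_pairs = 120, n_genes = 6,
                                     n_ligands = 2, seed = 5))
  ds <- sim$dataset
  g <- build_neighbor_graph(ds)
  pr_ab <- collect_cell_pairs(g, ds$cell_type, "A", "B")
  pr_ba <- collect_cell_pairs(g, ds$cell_type, "B", "A")
  nrm <- normalize_dataset(ds)
  nw_ab <- build_networks(ds, pr_ab, ds$gene_ids[1:2], ds$gene_ids, norm = nrm)
  nw_ba <- build_networks(ds, pr_ba, ds$gene_ids[1:2], ds$gene_ids, norm = nrm)
  # directionality: the planted coupling g01 -> g03 shows in A->B, not B->A
  cnt <- function(nw, i, j) sum(nw$edges$gene_i == i & nw$edges$gene_j == j)
  expect_gt(cnt(nw_ab, "g01", "g03"), 0.01 * nw_ab$n)
  expect_lt(cnt(nw_ba, "g01", "g03"), cnt(nw_ab, "g01", "g03"))
  # batch path equals the standalone test for every tested gene pair
  for (i in c("g01", "g02")) for (j in c("g03", "g05")) {
    h <- test_gene_pair(nrm[i, pr_ab$a], nrm[j, pr_ab$b])
    expect_equal(cnt(nw_ab, i, j), sum(h))
  }
})

test_that("network construction guards degenerate inputs", {
  expr <- matrix(3, 2, 24, dimnames = list(c("gA", "gB"), paste0("c", 1:24)))
  ds <- toy_dataset(expr, cbind(rep(1:12, each = 2), rep(c(0, 1), 12)),
                    types = rep(c("X", "Y"), 12))
  g <- build_neighbor_graph(ds, threshold = 1)
  pr <- collect_cell_pairs(g, ds$cell_type, "X", "Y")
  nw <- build_networks(ds, pr, "gA", "gB") # constant expression everywhere
  expect_equal(nrow(nw$edges), 0L)
  expect_error(build_networks(ds, pr, "gA", "gB", min_pairs = 1000),
               class = "igan_too_few_pairs")
  expect_error(build_networks(ds, pr, character(), "gB"), "non-empty")
})
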