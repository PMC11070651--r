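test_that("communication matrix matches hand evaluation of the type-pair mean", {
  # 2 types, 3 (X,Y) pairs with ligand row sums {2, 0, 1} -> sending 1.0
  pairs_df <- data.frame(a = c(1L, 2L, 3L), b = c(4L, 5L, 6L))
  edges <- data.frame(k = c(1, 1, 3), cell_a = c(1, 1, 3), cell_b = c(4, 4, 6),
                      gene_i = "lig", gene_j = c("t1", "t2", "t1"),
                      stringsAsFactors = FALSE)
  nw <- planted_networks(edges, pairs_df, "X", "Y", "lig", c("t1", "t2"))
  expect_warning(Cs <- build_comm_matrix(list(nw), c("X", "Y"), "lig", "sending"),
                 "without inter-type") # Y never sends in this one-way fixture

  expect_equal(Cs["X", "lig"], 1.0)
  expect_equal(Cs["Y", "lig"], 0)
  # receiving: the (X,Y) networks carry what Y receives from X
  expect_warning(Cr <- build_comm_matrix(list(nw), c("X", "Y"), "lig", "receiving"))
  expect_equal(Cr["Y", "lig"], 1.0)
  # all-zero networks give a zero matrix
  nw0 <- planted_networks(edges[0, ], pairs_df, "X", "Y", "lig", c("t1", "t2"))
  expect_warning(C0 <- build_comm_matrix(list(nw0), c("X", "Y"), "lig", "sending"),
                 "without inter-type")
  expect_equal(unname(C0), matrix(0, 2, 1))
})

test_that("with two types, symmetric couplings give matching send/recv", {
  # build a fixture symmetric by construction: identical edge sets in both
  # orientations
  pairs_xy <- data.frame(a = 1:3, b = 4:6)
  pairs_yx <- data.frame(a = 4:6, b = 1:3)
  e_xy <- data.frame(k = 1:2, cell_a = 1:2, cell_b = 4:5, gene_i = "lig",
                     gene_j = "t1", stringsAsFactors = FALSE)
  e_yx <- data.frame(k = 1:2, cell_a = 4:5, cell_b = 1:2, gene_i = "lig",
                     gene_j = "t1", stringsAsFactors = FALSE)
  nets <- list(planted_networks(e_xy, pairs_xy, "X", "Y", "lig", "t1"),
               planted_networks(e_yx, pairs_yx, "Y", "X", "lig", "t1"))
  Cs <- build_comm_matrix(nets, c("X", "Y"), "lig", "sending")
  Cr <- build_comm_matrix(nets, c("X", "Y"), "lig", "receiving")
  expect_equal(Cs, Cr)
})

test_that("microenvironment tabulation: row sums, segregation, degeneracy", {
  co <- unit_grid(10, 4)
  types <- ifelse(co[, 1] <= 5, "L", "R")
  g <- build_neighbor_graph(co, threshold = 1)
  me <- simple_microenvironments(g, types, n_env = 2, seed = 1)
  # row sums are the per-type cell counts
  expect_equal(unname(rowSums(me$E)), unname(as.numeric(table(types))))
  # two homogeneous halves: interior cells recover the two zones
  interior <- co[, 1] %in% c(1, 2, 3, 8, 9, 10)
  ari <- compare_clusterings(me$env[interior], types[interior])$ari
  expect_gt(ari, 0.95)
  # single type: compositions identical, everything collapses to one env
  expect_warning(me1 <- simple_microenvironments(g, rep("only", 40), n_env = 3),
                 "distinct compositions")
  expect_equal(unique(me1$env), 1L)
  expect_error(simple_microenvironments(g, types, n_env = 100), "exceeds")
})

test_that("NMF: exact low-rank recovery, nesting, determinism", {
  set.seed(6)
  w <- rgamma(5, 2); h <- rgamma(7, 2)
  rank1 <- outer(w, h)
  d1 <- nmf_patterns(rank1, 1, seed = 3)
  expect_lt(d1$error, 1e-6)
  mat <- matrix(rgamma(35, 2), 5, 7)
  errs <- vapply(1:5, function(k) nmf_patterns(mat, k, seed = 3)$error, 1.0)
  expect_true(all(diff(errs) < 1e-6)) # error non-increasing in k
  expect_equal(nmf_patterns(mat, 3, seed = 9)$loadings,
               nmf_patterns(mat, 3, seed = 9)$loadings) # fixed seed, fixed factors
  expect_error(nmf_patterns(matrix(0, 3, 3), 2), "all-zero")
  expect_error(nmf_patterns(mat, 6), "exceeds")
  scan <- nmf_rank_scan(mat, 1:3, seed = 3)
  expect_equal(scan$error, errs[1:3])
})

test_that("weighted KL: identity, permutation alignment, worked value", {
  mkdec <- function(W, Hb) structure(list(loadings = W, basis = Hb,
                                          k = ncol(W), seed = 0, error = 0),
                                     class = "pattern_decomposition")
  Ea <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  base <- mkdec(Ea, matrix(0.5, 2, 2)) # pattern weights (1, 1)
  expect_equal(weighted_kl(base, mkdec(Ea, matrix(1, 2, 2)), c(10, 10))$kl, 0)
  # column-swapped loadings are aligned back to zero divergence
  swapped <- mkdec(Ea[, 2:1], matrix(1, 2, 2))
  res <- weighted_kl(base, swapped, c(10, 10))
  expect_equal(res$kl, 0, tolerance = 1e-10)
  expect_equal(res$alignment, c(2L, 1L))
  # single type, W_pattern = (1, 1): direct arithmetic of the divergence
  one <- mkdec(matrix(c(0.9, 0.1), 1), matrix(0.5, 2, 2))
  flat <- mkdec(matrix(c(0.5, 0.5), 1), matrix(0.5, 2, 2))
  expect_equal(weighted_kl(one, flat, 5)$kl,
               0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5), tolerance = 1e-9)
  expect_error(weighted_kl(base, mkdec(matrix(1, 2, 3), matrix(1, 3, 2)),
                           c(1, 1)), "differ")
})

test_that("weighted KL is non-negative over random decomposition pairs", {
  set.seed(77)
  mkdec <- function(W, Hb) structure(list(loadings = W, basis = Hb,
                                          k = ncol(W), seed = 0, error = 0),
                                     class = "pattern_decomposition")
  worst <- Inf
  for (i in 1:300) {
    m <- sample(3:7, 1); k <- sample(2:4, 1)
    dE <- mkdec(matrix(rgamma(m * k, 1), m), matrix(runif(k * 6), k))
    dC <- mkdec(matrix(rgamma(m * k, 1), m), matrix(runif(k * 6), k))
    kl <- weighted_kl(dE, dC, rgamma(m, 2))$kl
    worst <- min(worst, kl)
    expect_gte(kl, 0)
  }
  expect_gte(worst, 0)
})

test_that("pattern benchmark separates matched from shuffled methods", {
  set.seed(15)
  datasets <- lapply(1:5, function(i) {
    E <- matrix(rpois(12, 30) * rbinom(12, 1, 0.6), 4, 3) + 1
    Cm <- E + matrix(rpois(12, 2), 4, 3) # C mirroring E's structure
    Cshuf <- Cm[sample(4), ]
    list(E = E, cell_counts = rowSums(E),
         comm = list(matched = list(sending = Cm, receiving = Cm),
                     shuffled = list(sending = Cshuf, receiving = Cshuf)))
  })
  bm <- benchmark_patterns(datasets, k = 2, seed = 1)
  expect_equal(nrow(bm$scores), 20L) # 5 datasets x 2 methods x 2 directions
  med <- tapply(bm$scores$kl, bm$scores$method, median)
  expect_lt(med["matched"], med["shuffled"])
  expect_equal(nrow(bm$tests), 1L)
  expect_true(is.finite(bm$tests$p) || is.na(bm$tests$p))
  # identical score vectors: test is NA by convention
  same <- benchmark_patterns(lapply(1:5, function(i) {
    E <- matrix(rpois(12, 20), 4, 3) + 1
    list(E = E, cell_counts = rowSums(E),
         comm = list(a = list(sending = E), b = list(sending = E)))
  }), k = 2, seed = 1)
  expect_true(is.na(same$tests$p))
})

test_that("paired Wilcoxon in the benchmark matches a direct small-n call", {
  set.seed(44)
  datasets <- lapply(1:6, function(i) {
    E <- matrix(rpois(12, 25), 4, 3) + 1
    list(E = E, cell_counts = rowSums(E),
         comm = list(m1 = list(sending = E + matrix(rpois(12, 1), 4, 3)),
                     m2 = list(sending = E[sample(4), ])))
  })
  bm <- benchmark_patterns(datasets, k = 2, seed = 2)
  a <- bm$scores$kl[bm$scores$method == "m1"]
  b <- bm$scores$kl[bm$scores$method == "m2"]
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  expect_equal(bm$tests$p, ref)
})
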