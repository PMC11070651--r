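# Eq.-style aggregation checks use a hand-built 3-cell fixture:
# cell 1 (type X) has neighbors 2 and 3 (type Y), so t_1 = 2.

test_that("sending/receiving activity matches the hand-evaluated toy", {
  g <- line3_graph()
  # outgoing ligand row sums 3 (to cell 2) and 1 (to cell 3);
  # incoming 0 (from 2) and 2 (from 3)
  edges <- data.frame(
    k = 1L,
    cell_a = c(1, 1, 1, 1, 3, 3),
    cell_b = c(2, 2, 2, 3, 1, 1),
    gene_i = "lig",
    gene_j = c("t1", "t2", "t3", "t1", "t1", "t2"),
    stringsAsFactors = FALSE)
  nw <- planted_networks(edges, data.frame(a = 1L, b = 2L), "X", "Y",
                         "lig", c("t1", "t2", "t3"))
  act <- compute_activity(nw, g, "lig")
  expect_equal(unname(act$send[1, "lig"]), 2)   # (3 + 1) / t_1 = 2
  expect_equal(unname(act$recv[1, "lig"]), 1)   # (0 + 2) / t_1 = 1
  expect_equal(unname(act$strength[1]), 3)
  # strength is exactly the ligand sum of send + recv for every cell
  expect_equal(act$strength, rowSums(act$send) + rowSums(act$recv))
})

test_that("isolated cells and uncovered ligands yield zero activity", {
  g <- build_neighbor_graph(cbind(c(0, 1, 10), c(0, 0, 0)), threshold = 1)
  expect_equal(g$t[3], 0L)
  nw <- planted_networks(
    data.frame(k = 1L, cell_a = 1, cell_b = 2, gene_i = "lig", gene_j = "t1"),
    data.frame(a = 1L, b = 2L), "X", "Y", "lig", "t1")
  expect_warning(act <- compute_activity(nw, g, c("lig", "ghost")), "ghost")
  expect_equal(unname(act$strength[3]), 0)
  expect_equal(unname(act$send[, "ghost"]), c(0, 0, 0))
})

test_that("activity conserves total association counts", {
  sim <- simulate_spatial(sim_config("checkerboard", seed = 9))
  fit <- igan(sim$dataset, sim$lr, verbose = FALSE)
  act <- fit$activity
  total_out <- sum(vapply(fit$networks, function(nw)
    sum(nw$edges$gene_i %in% fit$ligands), 1L))
  expect_equal(sum(act$t * act$send), total_out)
  expect_equal(sum(act$t * act$recv), total_out) # every edge is received once
  # relabeling cell types leaves activity untouched (depends on H + adjacency)
  act2 <- compute_activity(fit$networks, fit$graph, fit$ligands)
  expect_equal(act2$strength, act$strength)
})

test_that("strength map exports coordinates and the log1p column", {
  g <- line3_graph()
  nw <- planted_networks(
    data.frame(k = 1L, cell_a = 1, cell_b = 2, gene_i = "lig", gene_j = "t1"),
    data.frame(a = 1L, b = 2L), "X", "Y", "lig", "t1")
  act <- compute_activity(nw, g, "lig")
  sm <- strength_map(act, cbind(x = c(0, 1, -1), y = c(0, 0, 0)))
  expect_equal(sm$log_strength, log1p(sm$strength))
  # all-zero networks give a constant-zero map
  nw0 <- planted_networks(nw$edges[0, ], data.frame(a = 1L, b = 2L),
                          "X", "Y", "lig", "t1")
  sm0 <- strength_map(compute_activity(nw0, g, "lig"),
                      cbind(c(0, 1, -1), c(0, 0, 0)))
  expect_equal(sm0$strength, c(0, 0, 0))
})

test_that("interface cells carry more strength than interior cells", {
  # couplings act only across the A|B interface; cross-type communication
  # therefore concentrates on the two interface columns
  sim <- simulate_spatial(sim_config("boundary", seed = 21))
  fit <- igan(sim$dataset, sim$lr, combinations = "inter", verbose = FALSE)
  x <- sim$dataset$coords[, "x"]
  interface <- x %in% c(2, 3)
  interior <- x %in% c(1, 4)
  expect_gt(mean(fit$activity$strength[interface]),
            mean(fit$activity$strength[interior]))
  expect_gt(mean(fit$activity$strength[interface]), 0.2)
})

test_that("region comparison finds planted differences and no null ones", {
  set.seed(4)
  n <- 60
  act <- structure(list(
    send = cbind(ligA = c(rgamma(n / 2, 5), rgamma(n / 2, 1)), # region effect
                 ligB = rgamma(n, 2),                          # null ligand
                 ligC = rep(0, n)),                            # silent ligand
    recv = cbind(ligA = rgamma(n, 2), ligB = rgamma(n, 2), ligC = rep(0, n)),
    strength = rep(1, n), t = rep(1L, n), cell_ids = paste0("c", 1:n)),
    class = "igan_activity")
  region <- rep(c("r1", "r2"), each = n / 2)
  res <- region_ligand_test(act, region)
  expect_false("ligC" %in% res$ligand) # identically zero: excluded
  expect_true(res$significant[res$ligand == "ligA" & res$direction == "send"])
  expect_false(any(res$significant[res$ligand == "ligB"]))
  expect_error(region_ligand_test(act, rep(c("a", "b", "c"), 20)), "two region")
  expect_error(region_ligand_test(act, c("a", rep("b", n - 1))), "at least 3")
})

test_that("label-permuted regions are almost never significant", {
  set.seed(8)
  hits <- replicate(10, {
    n <- 40
    act <- structure(list(
      send = cbind(l1 = rgamma(n, 2), l2 = rgamma(n, 2), l3 = rgamma(n, 2)),
      recv = cbind(l1 = rgamma(n, 2), l2 = rgamma(n, 2), l3 = rgamma(n, 2)),
      strength = rep(1, n), t = rep(1L, n), cell_ids = paste0("c", 1:n)),
      class = "igan_activity")
    any(region_ligand_test(act, sample(rep(c("x", "y"), n / 2)))$significant)
  })
  expect_lte(mean(hits), 0.05 + 0.2) # >= 95% of runs clean, with MC slack
})

test_that("high-activity ligand selection ranks by mean and floors at zero", {
  act <- structure(list(
    send = cbind(hi = c(4, 4), mid = c(1, 1), zero = c(0, 0)),
    recv = cbind(hi = c(0, 0), mid = c(0, 0), zero = c(0, 0)),
    strength = c(5, 5), t = c(1L, 1L), cell_ids = c("c1", "c2")),
    class = "igan_activity")
  expect_identical(top_ligands(act, direction = "send", n_top = 10),
                   c("hi", "mid")) # zero-mean ligand never selected
  expect_identical(top_ligands(act, direction = "send", n_top = 1), "hi")
})
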