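test_that("downstream selection applies the strict count-over-pairs rule", {
  N <- 200
  pairs_df <- data.frame(a = seq_len(N), b = seq_len(N) + N)
  edges <- data.frame(
    k = c(rep(1:3, 1), rep(4:5, 1)), # gene tA in 3 pairs, tB in 2 pairs
    cell_a = 1, cell_b = 2,
    gene_i = "lig",
    gene_j = c(rep("tA", 3), rep("tB", 2)),
    stringsAsFactors = FALSE)
  nw <- planted_networks(edges, pairs_df, "X", "Y", "lig", c("tA", "tB"))
  sel <- select_downstream_genes(nw, "lig")
  expect_identical(sel, "tA")              # 3 > 2 selected, 2 > 2 is false
  expect_identical(select_downstream_genes(nw, "absent"), character())
})

test_that("selection frequency under independent indicators is binomial", {
  # the rule itself, fed directly with independent Bernoulli indicators
  set.seed(17)
  N <- 200; alpha <- 0.01; genes <- 400
  h <- matrix(rbinom(genes * N, 1, alpha), genes, N)
  selected <- rowSums(h) > 0.01 * N
  p_expected <- pbinom(2, N, alpha, lower.tail = FALSE)
  se <- sqrt(p_expected * (1 - p_expected) / genes)
  expect_lt(abs(mean(selected) - p_expected), 4 * se)
})

test_that("hypergeometric enrichment matches exact arithmetic", {
  gs <- gene_sets(list(inside = paste0("g", 1:5),
                       other = paste0("g", 11:15)))
  universe <- paste0("g", 1:20)
  res <- enrich_sets(paste0("g", 1:5), gs, universe)
  # all five query genes inside a 5-gene set: p = 1 / C(20,5)
  expect_equal(res$p[res$set == "inside"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "other"], 1) # disjoint: no enrichment signal
  # duplicated set names are rejected; identical sets share p and q
  gs2 <- gene_sets(list(a = paste0("g", 1:5), b = paste0("g", 1:5)))
  res2 <- enrich_sets(paste0("g", 1:5), gs2, universe)
  expect_equal(res2$p[1], res2$p[2])
  expect_equal(res2$q[1], res2$q[2])
  expect_equal(res2$q, p.adjust(res2$p, "BH"))
  expect_error(enrich_sets("outside", gs, universe), "subset")
  expect_equal(nrow(enrich_sets(character(), gs, universe)), 0L)
})

test_that("sankey graph wires ligand -> receptor -> pathway with exact weights", {
  fx <- sankey_fixture()
  sk <- build_sankey(fx$act, fx$nw, fx$lr, fx$pathway_sets, fx$ontology_sets,
                     cell_type = c("X", "Y"))
  expect_s3_class(sk, "sankey_graph")
  link_rp <- sk$links[sk$links$tier_from == 3, ]
  expect_identical(link_rp$from, "R1_R2")
  expect_identical(link_rp$to, "P")
  expect_equal(link_rp$weight, 5) # |downstream(L) ∩ P| exactly
  expect_false("DECOY" %in% sk$nodes$id)  # receptor filter excludes it
  expect_true(all(c("L", "R1_R2", "P") %in% sk$nodes$id))
  # receptor filter invariant on the output: every tier-4 node intersects
  # the subunits of a linked receptor unit
  for (r in which(sk$links$tier_from == 3)) {
    rec <- sk$links$from[r]
    sub <- strsplit(rec, "_")[[1]]
    expect_gt(length(intersect(sub, fx$pathway_sets[[sk$links$to[r]]])), 0)
  }
})

test_that("removing a gene set never adds sankey nodes or links", {
  fx <- sankey_fixture()
  full <- build_sankey(fx$act, fx$nw, fx$lr, fx$pathway_sets, fx$ontology_sets,
                       cell_type = c("X", "Y"))
  smaller <- build_sankey(fx$act, fx$nw, fx$lr,
                          gene_sets(fx$pathway_sets["DECOY"]),
                          fx$ontology_sets, cell_type = c("X", "Y"))
  expect_true(all(smaller$nodes$id %in% full$nodes$id))
  expect_lte(nrow(smaller$links), nrow(full$links))
})

test_that("ligands without downstream genes or activity give an empty graph", {
  fx <- sankey_fixture()
  # empty networks: nothing passes the 0.01 N rule
  nw0 <- planted_networks(fx$nw$edges[0, ], fx$nw$pairs, "X", "Y",
                          "L", fx$nw$target_genes)
  act0 <- compute_activity(nw0, build_neighbor_graph(cbind(c(0, 1), c(0, 0)),
                                                     threshold = 1), "L")
  expect_warning(sk <- build_sankey(act0, nw0, fx$lr, fx$pathway_sets),
                 "no ligand")
  expect_equal(nrow(sk$nodes), 0L)
  expect_equal(nrow(sk$links), 0L)
})

test_that("sankey export writes JSON nodes/links and a links CSV", {
  fx <- sankey_fixture()
  sk <- build_sankey(fx$act, fx$nw, fx$lr, fx$pathway_sets, fx$ontology_sets,
                     cell_type = c("X", "Y"))
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_sankey(sk, jf, cf)
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_setequal(names(parsed), c("nodes", "links"))
  expect_equal(nrow(parsed$links), nrow(sk$links))
  expect_equal(read.csv(cf)$weight, sk$links$weight)
})
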