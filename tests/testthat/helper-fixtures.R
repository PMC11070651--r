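# Shared fixture builders and independent oracles.

# tiny dense dataset on a line/grid
toy_dataset <- function(expr, coords, types = NULL, platform = "bead") {
  spatial_dataset(expr, coords,
                  gene_ids = rownames(expr) %||% paste0("g", seq_len(nrow(expr))),
                  cell_ids = colnames(expr) %||% paste0("c", seq_len(ncol(expr))),
                  cell_type = types, platform = platform)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

unit_grid <- function(nx, ny) {
  cbind(x = as.numeric(rep(seq_len(nx), times = ny)),
        y = as.numeric(rep(seq_len(ny), each = nx)))
}

# Independent O(n^2) oracle for window counts: repeatedly extract the
# minimum-distance candidate (distance ties by tie_order), never sorting.
oracle_window_counts <- function(x, y, k, b, tie_order = seq_along(x)) {
  n <- length(x)
  w <- ceiling(b * n)
  pick <- function(v) {
    d <- abs(v - v[k])
    chosen <- k # focal forced in
    for (step in seq_len(w - 1L)) {
      best <- 0L
      for (i in seq_len(n)) {
        if (i %in% chosen) next
        if (best == 0L || d[i] < d[best] ||
            (d[i] == d[best] && tie_order[i] < tie_order[best])) best <- i
      }
      chosen <- c(chosen, best)
    }
    chosen
  }
  list(n_x = w, n_y = w,
       n_xy = length(intersect(pick(x), pick(y))))
}

# direct evaluation of the association statistic formula
oracle_statistic <- function(nxy, nx, ny, n) {
  nxy <- as.numeric(nxy); nx <- as.numeric(nx); ny <- as.numeric(ny)
  n <- as.numeric(n)
  (nxy / n - (nx / n) * (ny / n)) /
    sqrt(nx * ny * (n - nx) * (n - ny) / (n^4 * (n - 1)))
}

# planted sankey fixture: ligand L couples to 5 target genes inside pathway
# P, which also contains L's receptor subunit; a decoy pathway holds the
# same genes but no receptor subunit.
sankey_fixture <- function() {
  N <- 100
  targets <- paste0("t", 1:5)
  noise <- paste0("n", 1:10)
  edges <- do.call(rbind, lapply(targets, function(tg)
    data.frame(k = 1:10, cell_a = 1, cell_b = 2, gene_i = "L", gene_j = tg,
               stringsAsFactors = FALSE)))
  nw <- planted_networks(edges, data.frame(a = rep(1L, N), b = rep(2L, N)),
                         "X", "Y", "L", c(targets, noise))
  g <- build_neighbor_graph(cbind(c(0, 1), c(0, 0)), threshold = 1)
  act <- compute_activity(nw, g, "L")
  lr <- lr_db("L", "R1_R2", "P")
  list(nw = nw, act = act, lr = lr,
       pathway_sets = gene_sets(list(P = c("R1", targets),
                                     DECOY = c(targets, "n1"))),
       ontology_sets = gene_sets(list(GO_term = c("L", "other_lig"))))
}

# a hand-built networks object: edge list over given cell pairs
planted_networks <- function(edges, pairs_df, A, B, source_genes, target_genes) {
  pairs <- structure(pairs_df, A = A, B = B, n = nrow(pairs_df),
                     class = c("cell_pair_set", "data.frame"))
  structure(list(edges = edges, pairs = pairs, n = nrow(pairs_df),
                 A = A, B = B, source_genes = source_genes,
                 target_genes = target_genes,
                 params = list(b = 0.1, alpha = 0.01)),
            class = "igan_networks")
}

# simple two-cell-type line fixture used by activity tests:
# cell 1 (type X) adjacent to cells 2 and 3 (type Y)
line3_graph <- function() {
  build_neighbor_graph(cbind(x = c(0, 1, -1), y = c(0, 0, 0)), threshold = 1)
}
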