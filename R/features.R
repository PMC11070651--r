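# CCC feature matrix and communication-feature clustering.

#' Build the cells x 2p CCC feature matrix
#'
#' Column layout: `send_<ligand_1> .. send_<ligand_p>,
#' recv_<ligand_1> .. recv_<ligand_p>`, exactly equal to the activity table's
#' sending and receiving signals.
#'
#' @param activity an [compute_activity()] result.
#' @param ligands ligand vector defining `p` and the column order; must be
#'   covered by the activity table.
#' @return Numeric matrix cells x `2p`.
#' @export
build_feature_matrix <- function(activity, ligands) {
  stopifnot(inherits(activity, "igan_activity"))
  ligands <- as.character(ligands)
  if (!length(ligands)) stop("ligand list is empty (p = 0)")
  if (!all(ligands %in% colnames(activity$send)))
    stop("ligand(s) missing from the activity table")
  FF <- cbind(activity$send[, ligands, drop = FALSE],
              activity$recv[, ligands, drop = FALSE])
  colnames(FF) <- c(paste0("send_", ligands), paste0("recv_", ligands))
  FF
}

#' Cluster cells on CCC features, expression, or both
#'
#' Pipeline: `log1p` + per-feature z-score standardization, PCA, shared
#' nearest-neighbor graph, modularity (Louvain) community detection at the
#' given resolution. `mode = "combined"` concatenates the standardized
#' expression PCs with the standardized CCC-feature PCs scaled by weight `w`
#' before graph construction; `w = 0` reproduces expression-only clustering.
#'
#' @param F CCC feature matrix (cells x features), e.g.
#'   [build_feature_matrix()]; may be `NULL` for `mode = "expression_only"`.
#' @param expr normalized expression matrix (genes x cells), required for
#'   `"expression_only"` and `"combined"`.
#' @param mode `"ccc_only"`, `"expression_only"`, or `"combined"`.
#' @param n_pcs number of principal components (reduced with a warning when
#'   the data has lower rank / fewer cells).
#' @param resolution Louvain resolution (default 1).
#' @param k_nn neighbors for the SNN graph (default 15).
#' @param w weight of the CCC PC block in combined mode (default 1).
#' @param seed RNG seed; results are reproducible bit-for-bit under a fixed
#'   seed and configuration.
#' @return Integer cluster labels (1-based) with attribute `params`.
#' @export
cluster_cells <- function(F = NULL, expr = NULL,
                          mode = c("ccc_only", "expression_only", "combined"),
                          n_pcs = 20L, resolution = 1.0, k_nn = 15L, w = 1.0,
                          seed = 0L) {
  mode <- match.arg(mode)
  if (mode != "expression_only" && is.null(F)) stop("mode needs F")
  if (mode != "ccc_only" && is.null(expr)) stop("mode needs expr")

  pcs_of <- function(mat) { # cells x features
    xs <- log1p(mat)
    xs <- suppressWarnings(scale(xs)) # zero-variance columns handled below
    xs[!is.finite(xs)] <- 0
    if (all(xs == 0)) return(NULL) # fully degenerate block
    npc <- min(n_pcs, nrow(xs) - 1L, ncol(xs))
    if (npc < n_pcs)
      warning(sprintf("reducing n_pcs to %d (rank/cell limit)", npc))
    p <- stats::prcomp(xs, rank. = npc)$x
    scale(p, center = FALSE, scale = apply(p, 2, stats::sd) + 1e-12)
  }

  emb <- switch(mode,
    ccc_only = pcs_of(F),
    expression_only = pcs_of(t(expr)),
    combined = {
      pe <- pcs_of(t(expr)); pf <- pcs_of(F)
      if (is.null(pf) || w == 0) pe else cbind(pe, w * pf)
    })
  n_cells <- if (!is.null(F)) nrow(F) else ncol(expr)
  if (is.null(emb)) { # all-zero features: single cluster
    out <- rep(1L, n_cells)
    attr(out, "params") <- list(mode = mode, degenerate = TRUE)
    return(out)
  }

  k <- min(k_nn, nrow(emb) - 1L)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  # SNN edge weight: Jaccard overlap of neighbor lists
  adj <- matrix(0, nrow(emb), nrow(emb))
  for (i in seq_len(nrow(emb))) adj[i, nn[i, ]] <- 1
  shared <- adj %*% t(adj)
  uni <- 2 * k - shared
  snn <- shared / uni
  snn[adj == 0 & t(adj) == 0] <- 0 # keep only kNN-connected pairs
  snn[snn < 1 / 15] <- 0
  diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "max", weighted = TRUE)
  cl <- with_private_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  out <- as.integer(igraph::membership(cl))
  attr(out, "params") <- list(mode = mode, n_pcs = n_pcs,
                              resolution = resolution, k_nn = k_nn, w = w,
                              seed = seed)
  out
}

#' Compare two clusterings
#'
#' @param labels1,labels2 label vectors over the same cells.
#' @return List with `ari` (adjusted Rand index) and `table` (contingency
#'   cross-tabulation).
#' @export
compare_clusterings <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("clusterings must cover the same cells")
  list(ari = mclust::adjustedRandIndex(labels1, labels2),
       table = table(labels1, labels2))
}
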