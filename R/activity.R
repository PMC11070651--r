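# Per-cell communication activity: ligand-wise sending/receiving signals and
# overall CCC strength, aggregated from the per-pair association networks.

#' Per-cell ligand sending/receiving activity and CCC strength
#'
#' For cell `a` with `t_a` spatial neighbors, the sending signal of ligand `i`
#' is the average, over `a`'s neighbors, of the number of target genes
#' associated with ligand `i` of `a`:
#' \deqn{send(a,i) = \frac{1}{t_a}\sum_{k=1}^{t_a}\sum_j H_{ij}^{(a b_k)}}
#' and the receiving signal mirrors it with the neighbor as source:
#' \deqn{recv(a,i) = \frac{1}{t_a}\sum_{k=1}^{t_a}\sum_j H_{ij}^{(b_k a)}.}
#' The overall CCC strength of a cell is the sum over ligands of sending plus
#' receiving activity. Isolated cells (`t_a = 0`) have all activities defined
#' as zero. Neighbors whose cell-type combination was skipped (too few pairs)
#' contribute zero but still count in `t_a`, which stays a purely spatial
#' quantity.
#'
#' @param networks a single `igan_networks` or a list of them (one per
#'   ordered cell-type combination), e.g. `fit$networks` from [igan()].
#' @param graph the [build_neighbor_graph()] the networks were built on.
#' @param ligands ligand gene vector defining the activity columns; ligands
#'   absent from the networks' source sets yield zero columns with a warning.
#' @return An object of class `igan_activity`: list with matrices `send`,
#'   `recv` (cells x ligands), vector `strength`, neighbor counts `t`, and
#'   `cell_ids`.
#' @export
compute_activity <- function(networks, graph, ligands) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (inherits(networks, "igan_networks")) networks <- list(networks)
  ligands <- unique(as.character(ligands))
  n_cells <- length(graph$t)
  send <- matrix(0, n_cells, length(ligands),
                 dimnames = list(graph$cell_ids, ligands))
  recv <- send
  covered <- unique(unlist(lapply(networks, function(nw) nw$source_genes)))
  missing <- setdiff(ligands, covered)
  if (length(missing))
    warning("ligand(s) absent from the networks' source genes: ",
            paste(missing, collapse = ", "))
  for (nw in networks) {
    e <- nw$edges
    e <- e[e$gene_i %in% ligands, , drop = FALSE]
    if (!nrow(e)) next
    li <- match(e$gene_i, ligands)
    # outgoing: source cell sends its ligand's associations
    inc <- table(factor(e$cell_a, levels = seq_len(n_cells)), factor(li, levels = seq_along(ligands)))
    send <- send + as.matrix(inc)
    # incoming: target cell receives the neighbor-ligand associations
    inc2 <- table(factor(e$cell_b, levels = seq_len(n_cells)), factor(li, levels = seq_along(ligands)))
    recv <- recv + as.matrix(inc2)
  }
  pos <- graph$t > 0
  send[pos, ] <- send[pos, , drop = FALSE] / graph$t[pos]
  recv[pos, ] <- recv[pos, , drop = FALSE] / graph$t[pos]
  send[!pos, ] <- 0; recv[!pos, ] <- 0
  dimnames(send) <- dimnames(recv) <- list(graph$cell_ids, ligands)
  structure(list(send = send, recv = recv,
                 strength = rowSums(send) + rowSums(recv),
                 t = graph$t, cell_ids = graph$cell_ids),
            class = "igan_activity")
}

#' @export
print.igan_activity <- function(x, ...) {
  cat(sprintf("igan_activity: %d cells x %d ligands; mean CCC strength %.3f\n",
              nrow(x$send), ncol(x$send), mean(x$strength)))
  invisible(x)
}

#' Per-cell CCC strength field for plotting/export
#'
#' @param activity an [compute_activity()] result.
#' @param coords per-cell coordinate matrix aligned with the activity cells.
#' @return Data frame `cell_id`, `x`, `y`, `strength`, `log_strength`
#'   (`log1p` of strength, the scale usually mapped to color).
#' @export
strength_map <- function(activity, coords) {
  stopifnot(inherits(activity, "igan_activity"))
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(activity$strength))
  data.frame(cell_id = activity$cell_ids,
             x = coords[, 1], y = coords[, 2],
             strength = unname(activity$strength),
             log_strength = log1p(unname(activity$strength)))
}

#' Compare ligand activity between two regions
#'
#' Per ligand, a Wilcoxon rank-sum test of the sending (and receiving)
#' activity between the two regions, with Benjamini-Hochberg correction per
#' direction. Ligands with identically zero activity everywhere are excluded.
#'
#' @param activity an [compute_activity()] result.
#' @param region_labels per-cell factor with exactly two levels.
#' @param q_cut significance threshold on the BH-adjusted q-value.
#' @return Data frame with one row per tested (ligand, direction): `ligand`,
#'   `direction`, `stat`, `p`, `q`, `significant`.
#' @export
region_ligand_test <- function(activity, region_labels, q_cut = 0.05) {
  stopifnot(inherits(activity, "igan_activity"))
  region_labels <- as.factor(region_labels)
  if (nlevels(region_labels) != 2L) stop("exactly two region labels required")
  if (any(table(region_labels) < 3L)) stop("each region needs at least 3 cells")
  res <- list()
  for (dir in c("send", "recv")) {
    mat <- activity[[dir]]
    keep <- colSums(mat != 0) > 0
    if (!any(keep)) next
    mat <- mat[, keep, drop = FALSE]
    p <- vapply(seq_len(ncol(mat)), function(j) {
      suppressWarnings(stats::wilcox.test(mat[, j] ~ region_labels)$p.value)
    }, 1.0)
    st <- vapply(seq_len(ncol(mat)), function(j) {
      suppressWarnings(unname(stats::wilcox.test(mat[, j] ~ region_labels)$statistic))
    }, 1.0)
    res[[dir]] <- data.frame(ligand = colnames(mat), direction = dir,
                             stat = st, p = p, q = stats::p.adjust(p, "BH"),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$q < q_cut
  out
}

#' Select high-activity ligands
#'
#' Ranks ligands by their mean activity over a cell subset and keeps the top
#' `n_top` with strictly positive mean (there is no canonical cut-off for
#' "high activity"; the rank rule is recorded in run manifests).
#'
#' @param activity an [compute_activity()] result.
#' @param cells optional logical/integer subset of cells (e.g. one cell type);
#'   default all cells.
#' @param direction `"send"`, `"recv"` or `"total"`.
#' @param n_top number of ligands to keep (default 10).
#' @return Character vector of selected ligand genes, best first.
#' @export
top_ligands <- function(activity, cells = NULL, direction = c("send", "recv", "total"),
                        n_top = 10L) {
  stopifnot(inherits(activity, "igan_activity"))
  direction <- match.arg(direction)
  idx <- cells %||% seq_len(nrow(activity$send))
  mat <- switch(direction,
                send = activity$send[idx, , drop = FALSE],
                recv = activity$recv[idx, , drop = FALSE],
                total = activity$send[idx, , drop = FALSE] +
                        activity$recv[idx, , drop = FALSE])
  mu <- colMeans(mat)
  mu <- mu[mu > 0]
  names(sort(mu, decreasing = TRUE))[seq_len(min(n_top, length(mu)))]
}
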