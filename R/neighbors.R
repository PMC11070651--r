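# Spatial adjacency: threshold distance, neighbor graph, ordered cell pairs.

#' Adjacency threshold distance for a slide
#'
#' For bead platforms the threshold is the 99th percentile (linear
#' interpolation between order statistics) of the per-cell nearest-neighbor
#' distances, which is robust to isolated outlier beads. For regular-grid
#' platforms it is the minimum distance over all cell pairs (the grid pitch).
#'
#' @param coords two-column matrix of cell positions.
#' @param platform `"bead"` or `"grid10x"`.
#' @return A single positive length in the units of `coords`.
#' @export
threshold_distance <- function(coords, platform = c("bead", "grid10x")) {
  platform <- match.arg(platform)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least two cells")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  thr <- if (platform == "bead") {
    nn <- apply(d, 1L, min)
    unname(stats::quantile(nn, 0.99, type = 7))
  } else {
    min(d)
  }
  if (!is.finite(thr) || thr <= 0)
    stop("degenerate geometry: zero threshold distance (coincident cells)")
  thr
}

#' Build the spatial neighbor graph
#'
#' Two cells are adjacent iff `0 < d(a, b) <= threshold`. Isolated cells are
#' kept with a neighbor count of zero.
#'
#' @param dataset a [spatial_dataset()], or a two-column coordinate matrix.
#' @param threshold adjacency threshold; defaults to
#'   [threshold_distance()] for the dataset's platform.
#' @param platform used when `dataset` is a bare coordinate matrix.
#' @return An object of class `neighbor_graph`: list with `threshold`,
#'   `adjacency` (per-cell integer index list), `t` (per-cell neighbor counts),
#'   `edges` (undirected edge matrix with columns `a`, `b`, `dist`, each edge
#'   once with `a < b`), and `cell_ids`.
#' @export
build_neighbor_graph <- function(dataset, threshold = NULL,
                                 platform = c("bead", "grid10x")) {
  if (inherits(dataset, "spatial_dataset")) {
    coords <- dataset$coords
    platform <- dataset$platform
    cell_ids <- dataset$cell_ids
  } else {
    platform <- match.arg(platform)
    coords <- as.matrix(dataset)
    cell_ids <- rownames(coords) %||% paste0("cell_", seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (is.null(threshold)) threshold <- threshold_distance(coords, platform)
  d <- as.matrix(stats::dist(coords))
  adj_mask <- d > 0 & d <= threshold
  adjacency <- lapply(seq_len(n), function(i) which(adj_mask[i, ]))
  t_a <- lengths(adjacency)
  ut <- which(upper.tri(d) & adj_mask, arr.ind = TRUE)
  edges <- cbind(a = ut[, 1L], b = ut[, 2L])
  structure(
    list(threshold = threshold, adjacency = adjacency, t = t_a,
         edges = cbind(edges, dist = d[ut]), cell_ids = cell_ids),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, %d undirected edges, threshold %.4g\n",
              length(x$t), nrow(x$edges), x$threshold))
  cat(sprintf("neighbor counts: min %d, median %g, max %d; %d isolated\n",
              min(x$t), stats::median(x$t), max(x$t), sum(x$t == 0)))
  invisible(x)
}

#' Collect ordered adjacent cell pairs for a directed type combination
#'
#' Returns every ordered pair `(a, b)` of adjacent cells with `type(a) = A`
#' and `type(b) = B`. When `A == B`, both orientations of each undirected
#' edge are included. With no qualifying pair, a condition of class
#' `igan_no_pairs` is signalled so callers can skip the combination.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param cell_type per-cell label vector aligned with the graph's cells.
#' @param A,B source and target cell types.
#' @return An object of class `cell_pair_set`: data frame with integer columns
#'   `a`, `b` (cell indices) and attributes `A`, `B`, `n`.
#' @export
collect_cell_pairs <- function(graph, cell_type, A, B) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cell_type <- as.character(cell_type)
  if (length(cell_type) != length(graph$t))
    stop("cell_type must cover every cell in the graph")
  if (!A %in% cell_type || !B %in% cell_type)
    stop("both cell types must be present")
  e <- graph$edges
  ta <- cell_type[e[, "a"]]; tb <- cell_type[e[, "b"]]
  fw <- ta == A & tb == B            # orientation (a -> b)
  bw <- tb == A & ta == B            # orientation (b -> a)
  pairs <- rbind(
    cbind(a = e[fw, "a"], b = e[fw, "b"]),
    cbind(a = e[bw, "b"], b = e[bw, "a"])
  )
  pairs <- unique(pairs)
  if (nrow(pairs) == 0L)
    stop_typed("igan_no_pairs",
               sprintf("no adjacent cell pairs for (%s -> %s)", A, B))
  out <- data.frame(a = as.integer(pairs[, "a"]), b = as.integer(pairs[, "b"]))
  structure(out, A = A, B = B, n = nrow(out),
            class = c("cell_pair_set", "data.frame"))
}
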