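#' Fit intercellular gene association networks for a spatial dataset
#'
#' The main entry point. Builds the spatial neighbor graph, collects ordered
#' adjacent cell pairs for every directed cell-type combination, tests every
#' (source gene, target gene) combination on each pair scatter, and
#' aggregates the per-pair binary networks into per-cell ligand
#' sending/receiving activity and overall CCC strength.
#'
#' By default source genes are the ligand genes of `lr` present in the data,
#' and target genes are all sufficiently expressed genes — every downstream
#' quantity consumes ligand rows of the networks, and the full gene x gene
#' mode grows quadratically. Pass explicit `source_genes`/`target_genes` to
#' override.
#'
#' @param dataset a [spatial_dataset()]. If it has no cell-type labels, cells
#'   are pre-clustered on expression ([cluster_cells()] with k-means fallback)
#'   into `precluster_k` groups.
#' @param lr an [lr_db()]; optional when `source_genes` is given.
#' @param source_genes,target_genes gene subsets; defaults described above.
#' @param b window fraction for the association test (default 0.1).
#' @param alpha per-test significance level (default 0.01).
#' @param threshold adjacency threshold; default [threshold_distance()].
#' @param min_pairs minimum cell-pair count per directed type combination;
#'   combinations below it are skipped with a warning (default 10).
#' @param min_cells_frac a gene is "expressed" (eligible as target) when
#'   detected in at least this fraction of the cells of some type
#'   (default 0.05).
#' @param method,tie_break decision rule details, see [test_gene_pair()].
#' @param combinations `"all"` tests every ordered cell-type combination
#'   (including same-type pairs); `"inter"` restricts to cross-type
#'   communication.
#' @param precluster_k number of expression pre-clusters when labels are
#'   absent.
#' @param verbose print progress.
#' @return An object of class `igan`: list with `graph`, `networks` (list of
#'   `igan_networks`, named `"A->B"`), `skipped` (combinations without enough
#'   pairs), `activity` (see [compute_activity()]), `ligands`,
#'   `source_genes`, `target_genes`, `cell_type`, `params`.
#' @examples
#' sim <- simulate_spatial(sim_config("checkerboard", nx = 6, ny = 6,
#'                                    n_genes = 8, seed = 1))
#' fit <- igan(sim$dataset, sim$lr, verbose = FALSE)
#' fit
#' @export
igan <- function(dataset, lr = NULL, source_genes = NULL, target_genes = NULL,
                 b = 0.1, alpha = 0.01, threshold = NULL, min_pairs = 10L,
                 min_cells_frac = 0.05, method = c("exact", "normal"),
                 tie_break = c("scramble", "index"),
                 combinations = c("all", "inter"), precluster_k = 4L,
                 verbose = TRUE) {
  method <- match.arg(method)
  tie_break <- match.arg(tie_break)
  combinations <- match.arg(combinations)
  stopifnot(inherits(dataset, "spatial_dataset"))

  cell_type <- dataset$cell_type
  if (is.null(cell_type)) {
    if (verbose) message("no cell-type labels: pre-clustering expression")
    norm0 <- normalize_dataset(dataset)
    cell_type <- paste0("pc", precluster_expression(norm0, k = precluster_k))
  }

  graph <- build_neighbor_graph(dataset, threshold = threshold)
  norm <- normalize_dataset(dataset)

  detected <- dataset$expr > 0
  types <- sort(unique(cell_type))
  frac_by_type <- vapply(types, function(tt)
    Matrix::rowMeans(detected[, cell_type == tt, drop = FALSE]), numeric(nrow(detected)))
  expressed <- dataset$gene_ids[apply(frac_by_type, 1L, max) >= min_cells_frac]

  if (is.null(source_genes)) {
    if (is.null(lr)) stop("either `lr` or `source_genes` must be given")
    source_genes <- intersect(ligands(lr), expressed)
    if (!length(source_genes))
      stop("no ligand gene of the database is expressed in the dataset")
  }
  target_genes <- target_genes %||% expressed
  if (!length(target_genes)) stop("no expressed target genes")

  networks <- list()
  skipped <- character()
  for (A in types) for (B in types) {
    if (combinations == "inter" && A == B) next
    key <- paste0(A, "->", B)
    pr <- tryCatch(collect_cell_pairs(graph, cell_type, A, B),
                   igan_no_pairs = function(e) NULL)
    if (is.null(pr) || attr(pr, "n") < min_pairs) {
      skipped <- c(skipped, key)
      next
    }
    if (verbose) message(sprintf("  %s: %d pairs", key, attr(pr, "n")))
    networks[[key]] <- build_networks(dataset, pr, source_genes, target_genes,
                                      b = b, alpha = alpha, method = method,
                                      tie_break = tie_break,
                                      min_pairs = min_pairs, norm = norm)
  }
  if (length(skipped) && verbose)
    message("skipped (too few pairs): ", paste(skipped, collapse = ", "))

  activity <- compute_activity(networks, graph, source_genes)
  structure(
    list(graph = graph, networks = networks, skipped = skipped,
         activity = activity, ligands = source_genes,
         source_genes = source_genes, target_genes = target_genes,
         cell_type = cell_type,
         params = list(b = b, alpha = alpha, min_pairs = min_pairs,
                       min_cells_frac = min_cells_frac, method = method,
                       tie_break = tie_break, threshold = graph$threshold)),
    class = "igan")
}

# expression pre-clustering fallback when no labels are supplied:
# z-scored genes -> PCA -> k-means (deterministic: seeded internally)
precluster_expression <- function(norm, k) {
  xs <- t(scale(t(norm)))
  xs[!is.finite(xs)] <- 0
  npc <- min(20L, nrow(xs) - 1L, ncol(xs) - 1L)
  pc <- stats::prcomp(t(xs), rank. = npc)$x
  with_private_seed(7L, stats::kmeans(pc, centers = min(k, nrow(pc)), nstart = 10)$cluster)
}

#' @export
print.igan <- function(x, ...) {
  cat("Intercellular gene association network fit\n")
  cat(sprintf("  cells: %d; cell types: %d; undirected edges: %d (threshold %.4g)\n",
              length(x$graph$t), length(unique(x$cell_type)),
              nrow(x$graph$edges), x$graph$threshold))
  cat(sprintf("  source genes (ligands): %d; target genes: %d\n",
              length(x$source_genes), length(x$target_genes)))
  cat(sprintf("  type combinations tested: %d (skipped: %d)\n",
              length(x$networks), length(x$skipped)))
  cat(sprintf("  associations: %d; mean CCC strength: %.3f\n",
              sum(vapply(x$networks, function(nw) nrow(nw$edges), 1L)),
              mean(x$activity$strength)))
  invisible(x)
}

#' @export
summary.igan <- function(object, ...) {
  per_tp <- data.frame(
    combination = names(object$networks),
    n_pairs = vapply(object$networks, function(nw) nw$n, 1L),
    associations = vapply(object$networks, function(nw) nrow(nw$edges), 1L),
    row.names = NULL)
  per_type <- tapply(object$activity$strength, object$cell_type, mean)
  out <- list(combinations = per_tp,
              mean_strength_by_type = per_type,
              params = object$params, skipped = object$skipped)
  class(out) <- "summary.igan"
  out
}

#' @export
print.summary.igan <- function(x, ...) {
  cat("Associations per directed type combination:\n")
  print(x$combinations, row.names = FALSE)
  cat("\nMean CCC strength by cell type:\n")
  print(round(x$mean_strength_by_type, 3))
  if (length(x$skipped))
    cat("\nSkipped combinations:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell ligand activity coefficients of a fit
#'
#' @param object an [igan()] fit.
#' @param ... unused.
#' @return Matrix cells x (2 x ligands): sending then receiving columns.
#' @export
coef.igan <- function(object, ...) {
  build_feature_matrix(object$activity, object$ligands)
}

#' Plot the spatial CCC strength field of a fit
#'
#' @param x an [igan()] fit.
#' @param coords coordinate matrix; defaults to the graph's geometry is not
#'   stored, so pass the dataset's `coords`.
#' @param log use the `log1p` scale (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.igan <- function(x, coords, log = TRUE, ...) {
  sm <- strength_map(x$activity, coords)
  v <- if (log) sm$log_strength else sm$strength
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[cut(v, breaks = 64, labels = FALSE, include.lowest = TRUE)]
  if (length(unique(v)) == 1L) col <- pal[1]
  graphics::plot(sm$x, sm$y, col = col, pch = 16,
                 xlab = "x", ylab = "y",
                 main = if (log) "CCC strength (log1p)" else "CCC strength", ...)
  invisible(sm)
}
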