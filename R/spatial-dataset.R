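#' Construct a spatial expression dataset
#'
#' Bundles a genes x cells expression matrix with per-cell spatial coordinates
#' and (optionally) cell-type labels. This is the universal input container of
#' the package: every downstream step (neighbor graph, association networks,
#' activity, clustering, pattern benchmarking) consumes it.
#'
#' @param expr numeric matrix or `Matrix::dgCMatrix` of non-negative counts or
#'   normalized values, genes in rows, cells in columns.
#' @param coords two-column numeric matrix or data frame of per-cell `(x, y)`
#'   positions, in the slide's length units; rows match columns of `expr`.
#' @param gene_ids,cell_ids character vectors of unique identifiers; default to
#'   the dimnames of `expr`.
#' @param cell_type optional per-cell label vector covering every cell.
#' @param platform `"bead"` for near-cellular bead platforms (Slide-seq-like)
#'   or `"grid10x"` for regular-grid spot platforms; controls the default
#'   adjacency threshold rule (see [threshold_distance()]).
#' @return An object of class `spatial_dataset`: a list with elements `expr`,
#'   `gene_ids`, `cell_ids`, `coords`, `cell_type`, `platform`.
#' @seealso [read_spatial_dataset()], [normalize_dataset()], [igan()]
#' @export
spatial_dataset <- function(expr, coords, gene_ids = rownames(expr),
                            cell_ids = colnames(expr), cell_type = NULL,
                            platform = c("bead", "grid10x")) {
  platform <- match.arg(platform)
  expr <- methods::as(methods::as(Matrix::Matrix(expr, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(expr)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(expr)))
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("`coords` must have two columns (x, y)")
  colnames(coords) <- c("x", "y")

  if (length(gene_ids) != nrow(expr))
    stop("length(gene_ids) must equal nrow(expr)")
  if (length(cell_ids) != ncol(expr) || nrow(coords) != ncol(expr))
    stop("cell_ids and coords must match the number of expression columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (any(expr@x < 0)) stop("expression values must be non-negative")
  if (!is.null(cell_type)) {
    cell_type <- as.character(cell_type)
    if (length(cell_type) != ncol(expr))
      stop("cell_type must cover every cell")
    if (anyNA(cell_type)) stop("cell_type contains missing labels")
  }
  dimnames(expr) <- list(gene_ids, cell_ids)
  rownames(coords) <- cell_ids
  structure(
    list(expr = expr, gene_ids = gene_ids, cell_ids = cell_ids,
         coords = coords, cell_type = cell_type, platform = platform),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids), x$platform))
  if (!is.null(x$cell_type)) {
    tab <- table(x$cell_type)
    cat("cell types:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  } else cat("cell types: none\n")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expr)

#' Library-size normalization
#'
#' Scales each cell to the median library size and applies `log1p`. This is the
#' default transform on which association windows are computed; the raw counts
#' are left untouched in the dataset.
#'
#' @param dataset a [spatial_dataset()].
#' @return A dense numeric matrix (genes x cells) of normalized values.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  counts <- as.matrix(dataset$expr)
  sf <- colSums(counts)
  med <- stats::median(sf[sf > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  sf[sf == 0] <- med # empty cells stay all-zero after scaling
  log1p(sweep(counts, 2, sf, "/") * med)
}
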