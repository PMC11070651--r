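# Readers and writers for the external formats the pipeline touches:
# expression (Matrix Market triplets + ID sidecars, or dense CSV), coordinate
# CSV, cell-type CSV, ligand-receptor CSV, GMT gene sets.

#' Read a spatial dataset from disk
#'
#' Expression can be either a Matrix Market `.mtx` file (genes x cells) with
#' plain-text gene/cell ID sidecar files, or a dense CSV with gene rows and a
#' header of cell IDs (first column = gene ID). Coordinates are a CSV with
#' columns `cell_id,x,y`. Cells are reordered to the intersection of the
#' expression and coordinate IDs, in coordinate-file order; dropped IDs are
#' reported with a warning.
#'
#' @param expr_path path to `.mtx` or dense CSV expression file.
#' @param coords_path path to the coordinates CSV (`cell_id,x,y`).
#' @param labels_path optional path to a cell-type CSV (`cell_id,type`).
#' @param platform `"bead"` or `"grid10x"`.
#' @param genes_path,cells_path ID sidecar files (one ID per line), required
#'   for MTX input; ignored for CSV.
#' @return A [spatial_dataset()].
#' @export
read_spatial_dataset <- function(expr_path, coords_path, labels_path = NULL,
                                 platform = c("bead", "grid10x"),
                                 genes_path = NULL, cells_path = NULL) {
  platform <- match.arg(platform)
  if (grepl("\\.mtx$", expr_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs `genes_path` and `cells_path` ID sidecars")
    expr <- Matrix::readMM(expr_path)
    gene_ids <- trimws(readLines(genes_path))
    cell_ids <- trimws(readLines(cells_path))
    if (length(gene_ids) != nrow(expr) || length(cell_ids) != ncol(expr))
      stop("ID sidecar lengths do not match the MTX dimensions")
    dimnames(expr) <- list(gene_ids, cell_ids)
  } else {
    tab <- utils::read.csv(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- trimws(as.character(tab[[1]]))
    expr <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(expr) <- "double"
    dimnames(expr) <- list(gene_ids, trimws(colnames(tab)[-1]))
  }
  if (any(expr < 0)) stop("negative expression values in ", expr_path)

  coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(coords)))
    stop("coordinates file must have columns cell_id,x,y")
  coords$cell_id <- trimws(as.character(coords$cell_id))
  if (anyDuplicated(coords$cell_id)) stop("duplicate cell IDs in coordinates")
  if (anyDuplicated(colnames(expr))) stop("duplicate cell IDs in expression")

  keep <- coords$cell_id[coords$cell_id %in% colnames(expr)]
  if (length(keep) == 0L) stop("no overlap between expression and coordinate cell IDs")
  dropped <- setdiff(union(coords$cell_id, colnames(expr)), keep)
  if (length(dropped))
    warning(sprintf("dropping %d cell(s) absent from expression or coordinates", length(dropped)))

  expr <- expr[, keep, drop = FALSE]
  coords <- coords[match(keep, coords$cell_id), , drop = FALSE]

  cell_type <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "type") %in% names(lab)))
      stop("labels file must have columns cell_id,type")
    lab$cell_id <- trimws(as.character(lab$cell_id))
    idx <- match(keep, lab$cell_id)
    if (anyNA(idx)) stop("labels file does not cover every retained cell")
    cell_type <- as.character(lab$type)[idx]
  }

  spatial_dataset(expr, coords[, c("x", "y")], gene_ids = rownames(expr),
                  cell_ids = keep, cell_type = cell_type, platform = platform)
}

#' Write a spatial dataset to disk
#'
#' Writes the expression matrix as Matrix Market triplets with gene/cell ID
#' sidecars, the coordinates as CSV, and (if present) cell-type labels as CSV.
#' `read_spatial_dataset()` on the written files round-trips values and IDs.
#'
#' @param dataset a [spatial_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_spatial_dataset <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "spatial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expr = file.path(dir, paste0(prefix, "_expr.mtx")),
    genes = file.path(dir, paste0(prefix, "_genes.txt")),
    cells = file.path(dir, paste0(prefix, "_cells.txt")),
    coords = file.path(dir, paste0(prefix, "_coords.csv"))
  )
  Matrix::writeMM(dataset$expr, paths["expr"])
  writeLines(dataset$gene_ids, paths["genes"])
  writeLines(dataset$cell_ids, paths["cells"])
  utils::write.csv(
    data.frame(cell_id = dataset$cell_ids,
               x = dataset$coords[, "x"], y = dataset$coords[, "y"]),
    paths["coords"], row.names = FALSE)
  if (!is.null(dataset$cell_type)) {
    paths["labels"] <- file.path(dir, paste0(prefix, "_labels.csv"))
    utils::write.csv(data.frame(cell_id = dataset$cell_ids, type = dataset$cell_type),
                     paths["labels"], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a ligand-receptor interaction table
#'
#' Expects a CSV with columns `ligand,receptor,pathway` in the CellChatDB-like
#' layout: multi-subunit receptor units are written as subunit gene symbols
#' joined by `"_"` (e.g. `Itgax_Itgb2`). Gene symbols are compared
#' case-sensitively after whitespace stripping.
#'
#' @param path CSV path.
#' @return An object of class `lr_db`: a data frame with columns `ligand`,
#'   `receptor`, `pathway` plus a list column `subunits`, and attributes
#'   `ligands` (ligand gene list de-duplicated preserving first occurrence)
#'   and `subunit_genes` (all receptor subunit genes).
#' @export
read_lr_database <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pathway")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("ligand-receptor table lacks column(s): ",
                         paste(miss, collapse = ", "))
  lr_db(tab$ligand, tab$receptor, tab$pathway)
}

#' Construct a ligand-receptor database in memory
#'
#' @param ligand,receptor,pathway character vectors of equal length; receptor
#'   subunits joined by `"_"`.
#' @return An `lr_db` object; see [read_lr_database()].
#' @export
lr_db <- function(ligand, receptor, pathway = rep("", length(ligand))) {
  ligand <- trimws(as.character(ligand))
  receptor <- trimws(as.character(receptor))
  pathway <- trimws(as.character(pathway))
  if (any(ligand == "") || any(receptor == ""))
    stop("empty gene symbols in ligand-receptor table")
  subunits <- strsplit(receptor, "_", fixed = TRUE)
  subunits <- lapply(subunits, function(s) {
    s <- trimws(s)
    if (any(s == "")) stop("receptor unit with an empty subunit symbol")
    s
  })
  db <- data.frame(ligand = ligand, receptor = receptor, pathway = pathway,
                   stringsAsFactors = FALSE)
  db$subunits <- subunits
  structure(db,
            ligands = unique(ligand),
            subunit_genes = unique(unlist(subunits)),
            class = c("lr_db", "data.frame"))
}

#' Ligand gene list of a ligand-receptor database
#' @param db an `lr_db`.
#' @return Character vector of unique ligand genes, first-occurrence order.
#' @export
ligands <- function(db) {
  stopifnot(inherits(db, "lr_db"))
  attr(db, "ligands")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Lines with fewer than three fields are skipped with a
#' warning; repeated genes within a set are stored once.
#'
#' @param path GMT file path.
#' @param source tag recorded on the collection (e.g. `"KEGG"`, `"GO"`).
#' @return An object of class `gene_sets`: a named list of character vectors
#'   with attribute `source`.
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_sets(list(), source = source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) {
    warning(sprintf("skipping %d malformed GMT line(s) with < 3 fields", sum(bad)))
    fields <- fields[!bad]
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- vapply(fields, function(f) trimws(f[1]), "")
  gene_sets(sets, source = source)
}

#' Construct a gene-set collection in memory
#' @param sets named list of character vectors; names unique, sets non-empty.
#' @param source tag recorded on the collection.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, source = "custom") {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("gene set names must be present and unique")
    if (any(!vapply(sets, length, 1L)))
      stop("gene sets must be non-empty")
    sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  }
  structure(sets, source = source, class = "gene_sets")
}

#' Write a gene-set collection in GMT format
#' @param sets a `gene_sets` collection.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], attr(sets, "source"), sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
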