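# Downstream-gene selection, over-representation tests and the panoramic
# ligand -> receptor -> pathway (Sankey) graph for a directed type pair.

#' Select downstream target genes of a ligand
#'
#' Genes whose association with the ligand accumulates strictly more than
#' `frac * N` counts over the `N` cell pairs of a directed type combination.
#'
#' @param networks an `igan_networks` for one directed type combination.
#' @param ligand_gene source (ligand) gene symbol.
#' @param frac count threshold as a fraction of the pair count (default 0.01,
#'   i.e. the `> 0.01 N` rule).
#' @return Character vector of selected target genes (empty when `N = 0`).
#' @export
select_downstream_genes <- function(networks, ligand_gene, frac = 0.01) {
  stopifnot(inherits(networks, "igan_networks"))
  N <- networks$n
  if (N == 0L) return(character())
  e <- networks$edges
  e <- e[e$gene_i == ligand_gene, , drop = FALSE]
  if (!nrow(e)) return(character())
  cnt <- table(e$gene_j)
  names(cnt)[cnt > frac * N]
}

#' Hypergeometric over-representation test of a gene list
#'
#' One-sided hypergeometric enrichment of `query` in each set of a
#' collection, with Benjamini-Hochberg correction across the collection.
#' Sets are intersected with the `universe` first.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param collection a [gene_sets()] collection.
#' @param universe background gene vector.
#' @param q_cut significance threshold on the BH q-value (default 0.05).
#' @return Data frame `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, `significant`; empty for an empty query.
#' @export
enrich_sets <- function(query, collection, universe, q_cut = 0.05) {
  stopifnot(inherits(collection, "gene_sets"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  if (!length(query) || !length(collection))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  Nu <- length(universe); nq <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    ov <- length(intersect(query, s))
    # P(X >= ov), X ~ Hyper(drawn nq from Nu with |s| successes)
    p <- stats::phyper(ov - 1, length(s), Nu - length(s), nq, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               query_size = nq, universe_size = Nu, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < q_cut
  rownames(out) <- NULL
  out
}

#' Panoramic cell-interaction-pathway (Sankey) graph
#'
#' Four node tiers for a directed cell-type pair `A -> B`:
#' \enumerate{
#'   \item ontology terms enriched in the high-activity ligand list;
#'   \item high-activity ligands of the source type;
#'   \item the receptor units of those ligands (from the ligand-receptor
#'     database);
#'   \item pathways that are both enriched in a ligand's downstream gene set
#'     and contain at least one subunit of a cognate receptor unit.
#' }
#' The receptor-to-pathway link weight is the number of the ligand's
#' downstream target genes inside the pathway (drawn identically for every
#' receptor unit of that ligand, since the association networks carry no
#' receptor resolution).
#'
#' @param activity an [compute_activity()] result for the whole slide.
#' @param networks the `igan_networks` of the `A -> B` combination.
#' @param lr an [lr_db()].
#' @param pathway_sets pathway [gene_sets()] (KEGG-like).
#' @param ontology_sets optional ontology [gene_sets()] (GO-like) for tier 1.
#' @param cell_type per-cell labels aligned with `activity`.
#' @param A,B source and target cell types (defaults from `networks`).
#' @param n_top number of high-activity ligands to consider.
#' @param frac downstream selection threshold fraction (default 0.01).
#' @param q_cut enrichment significance threshold.
#' @return An object of class `sankey_graph`: list with `nodes` (data frame
#'   `id`, `tier`, `label`) and `links` (data frame `from`, `to`, `tier_from`,
#'   `weight`, `ligand`), plus `downstream` (per-ligand gene sets).
#' @export
build_sankey <- function(activity, networks, lr, pathway_sets,
                         ontology_sets = NULL, cell_type = NULL,
                         A = networks$A, B = networks$B,
                         n_top = 10L, frac = 0.01, q_cut = 0.05) {
  stopifnot(inherits(networks, "igan_networks"), inherits(lr, "lr_db"),
            inherits(pathway_sets, "gene_sets"))
  cells <- if (is.null(cell_type)) NULL else which(cell_type == A)
  ligs <- top_ligands(activity, cells = cells, direction = "send", n_top = n_top)
  ligs <- intersect(ligs, unique(lr$ligand))
  empty <- function() {
    warning("no ligand passes high-activity selection; empty graph")
    structure(list(nodes = data.frame(id = character(), tier = integer(),
                                      label = character(), stringsAsFactors = FALSE),
                   links = data.frame(from = character(), to = character(),
                                      tier_from = integer(), weight = numeric(),
                                      ligand = character(), stringsAsFactors = FALSE),
                   downstream = list()),
              class = "sankey_graph")
  }
  if (!length(ligs)) return(empty())

  universe <- networks$target_genes
  downstream <- lapply(ligs, function(lg)
    select_downstream_genes(networks, lg, frac = frac))
  names(downstream) <- ligs
  keep <- lengths(downstream) > 0
  ligs <- ligs[keep]; downstream <- downstream[keep]
  if (!length(ligs)) return(empty())

  nodes <- list(); links <- list()
  add_node <- function(id, tier, label = id)
    nodes[[id]] <<- data.frame(id = id, tier = tier, label = label,
                               stringsAsFactors = FALSE)
  add_link <- function(from, to, tier_from, weight, ligand)
    links[[length(links) + 1L]] <<- data.frame(
      from = from, to = to, tier_from = tier_from, weight = weight,
      ligand = ligand, stringsAsFactors = FALSE)

  # tier 1: ontology enrichment of the ligand list (universe: DB ligands)
  if (!is.null(ontology_sets) && length(ontology_sets)) {
    lig_universe <- unique(c(attr(lr, "ligands"), ligs))
    ont <- enrich_sets(ligs, ontology_sets, lig_universe, q_cut = q_cut)
    ont <- ont[ont$significant & ont$overlap > 0, , drop = FALSE]
    for (r in seq_len(nrow(ont))) {
      term <- ont$set[r]
      add_node(term, 1L)
      members <- intersect(ontology_sets[[term]], ligs)
      for (lg in members) add_link(term, lg, 1L, 1, lg)
    }
  }

  for (lg in ligs) {
    add_node(lg, 2L)
    units <- lr[lr$ligand == lg, , drop = FALSE]
    dn <- downstream[[lg]]
    enr <- enrich_sets(intersect(dn, universe), pathway_sets, universe,
                       q_cut = q_cut)
    enr <- enr[enr$significant, , drop = FALSE]
    for (u in seq_len(nrow(units))) {
      rec <- units$receptor[u]
      subunits <- units$subunits[[u]]
      add_node(rec, 3L)
      add_link(lg, rec, 2L, 1, lg)
      for (pw in enr$set) {
        pw_genes <- pathway_sets[[pw]]
        if (!length(intersect(subunits, pw_genes))) next # receptor filter
        wgt <- length(intersect(dn, pw_genes))
        if (wgt < 1) next
        add_node(pw, 4L)
        add_link(rec, pw, 3L, wgt, lg)
      }
    }
  }
  nodes_df <- do.call(rbind, unname(nodes))
  links_df <- if (length(links)) do.call(rbind, links) else
    data.frame(from = character(), to = character(), tier_from = integer(),
               weight = numeric(), ligand = character(), stringsAsFactors = FALSE)
  rownames(nodes_df) <- rownames(links_df) <- NULL
  structure(list(nodes = nodes_df[order(nodes_df$tier, nodes_df$id), ],
                 links = links_df, downstream = downstream,
                 A = A, B = B),
            class = "sankey_graph")
}

#' @export
print.sankey_graph <- function(x, ...) {
  tiers <- table(factor(x$nodes$tier, levels = 1:4))
  cat(sprintf("sankey_graph%s: %d ontology / %d ligand / %d receptor / %d pathway nodes, %d links\n",
              if (!is.null(x$A)) sprintf(" (%s -> %s)", x$A, x$B) else "",
              tiers[1], tiers[2], tiers[3], tiers[4], nrow(x$links)))
  invisible(x)
}

#' Export a Sankey graph as JSON and CSV
#'
#' @param graph a [build_sankey()] result.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return Invisibly, the graph.
#' @export
write_sankey <- function(graph, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(graph, "sankey_graph"))
  if (!is.null(json_path))
    jsonlite::write_json(list(nodes = graph$nodes, links = graph$links),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(graph$links, csv_path, row.names = FALSE)
  invisible(graph)
}

#' Basic static rendering of a Sankey graph
#'
#' Draws the four node tiers as columns with link segments whose widths scale
#' with weight. Intended as a quick-look; export the JSON for full-featured
#' renderers.
#'
#' @param x a [build_sankey()] result.
#' @param ... unused.
#' @export
plot.sankey_graph <- function(x, ...) {
  nd <- x$nodes
  if (!nrow(nd)) {
    graphics::plot.new(); graphics::title("empty sankey graph")
    return(invisible(x))
  }
  nd$yy <- stats::ave(seq_len(nrow(nd)), nd$tier, FUN = function(i)
    seq(0, 1, length.out = length(i) + 2L)[-c(1L, length(i) + 2L)])
  graphics::plot(NA, xlim = c(0.5, 4.5), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s -> %s", x$A %||% "?", x$B %||% "?"))
  graphics::axis(1, at = 1:4, labels = c("ontology", "ligand", "receptor", "pathway"))
  for (r in seq_len(nrow(x$links))) {
    lk <- x$links[r, ]
    from <- nd[nd$id == lk$from, ]; to <- nd[nd$id == lk$to, ]
    graphics::segments(from$tier, from$yy, to$tier, to$yy,
                       lwd = 0.5 + 2 * log1p(lk$weight), col = "grey50")
  }
  graphics::points(nd$tier, nd$yy, pch = 16)
  graphics::text(nd$tier, nd$yy, nd$label, pos = 3, cex = 0.7)
  invisible(x)
}
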