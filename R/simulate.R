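# Synthetic spatial datasets with planted intercellular couplings.
#
# Cells sit on a unit grid; baseline expression is zero-inflated negative
# binomial, generated through per-gene latent gaussian variables so that
# couplings can be planted on the latent scale and transformed to counts
# monotonically (marginals preserved, rank association controlled). The
# planting mechanism depends on the layout: isolated pairs use an exact
# per-pair gaussian copula; contiguous layouts use a spatially smooth
# communication field both sides load on (see simulate_spatial).

#' Simulation configuration
#'
#' @param preset spatial layout: `"checkerboard"` (two interleaved types:
#'   every lattice edge joins the two types), `"boundary"` (two half-slide
#'   blocks meeting at a vertical interface), `"blocks"` (three vertical
#'   zones with overlapping type pairs T1+T2 / T2+T3 / T3+T4, the zone label
#'   serving as ground-truth microenvironment), or `"pairs"` (isolated,
#'   mutually independent A-B cell pairs — the calibration layout: every
#'   cell has exactly one neighbor, so each adjacent pair realizes a planted
#'   copula at exactly its nominal correlation).
#' @param nx,ny grid dimensions (defaults per preset).
#' @param n_pairs number of isolated pairs for the `"pairs"` preset.
#' @param n_genes total gene count.
#' @param n_ligands number of ligand genes (the first `n_ligands` genes); a
#'   matching ligand-receptor table and pathway sets are emitted.
#' @param couplings data frame with columns `source_type`, `target_type`,
#'   `source_gene`, `target_gene`, `r`; `NULL` for the preset default
#'   (checkerboard/boundary: a single coupling from the first ligand;
#'   blocks: one ligand per zone-sharing type pair, both directions).
#' @param mu_range range of per-gene negative-binomial means.
#' @param nb_size negative-binomial dispersion (size).
#' @param zero_inflation extra structural-zero probability.
#' @param coupling_r copula correlation used by preset default couplings.
#' @param local_coupling if `TRUE`, only cells adjacent to the opposite type
#'   load on a coupling's communication field, confining the planted signal
#'   to type interfaces (paracrine locality); if `FALSE`, every cell of the
#'   participating types loads (a zone-wide communication program). Defaults
#'   to `TRUE` for the `"boundary"` preset, `FALSE` otherwise.
#' @param seed RNG seed; the generator is byte-deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("checkerboard", "boundary", "blocks", "pairs"),
                       nx = NULL, ny = NULL, n_pairs = 200L, n_genes = NULL,
                       n_ligands = 3L, couplings = NULL, mu_range = c(1.5, 5),
                       nb_size = 0.5, zero_inflation = 0.1, coupling_r = 0.9,
                       local_coupling = NULL, seed = 1L) {
  preset <- match.arg(preset)
  local_coupling <- isTRUE(local_coupling %||% (preset == "boundary"))
  dims <- switch(preset,
                 checkerboard = c(12L, 12L),
                 boundary = c(4L, 150L),
                 blocks = c(30L, 18L),
                 pairs = c(2L, 2L)) # unused; geometry comes from n_pairs
  # blocks plants 18 coupled target genes; a deep baseline keeps their share
  # of the library size small (normalization would otherwise spread a smooth
  # spatial factor into every gene)
  n_genes <- as.integer(n_genes %||% if (preset == "blocks") 60L else 30L)
  nx <- as.integer(nx %||% dims[1]); ny <- as.integer(ny %||% dims[2])
  n_pairs <- as.integer(n_pairs)
  stopifnot(nx >= 2L, ny >= 2L, n_pairs >= 1L, n_genes >= n_ligands, n_ligands >= 1L,
            zero_inflation >= 0, zero_inflation < 1,
            coupling_r > -1, coupling_r < 1)
  genes <- sprintf("g%02d", seq_len(n_genes))
  lig <- genes[seq_len(n_ligands)]
  if (is.null(couplings)) {
    couplings <- switch(preset,
      pairs = data.frame(
        source_type = "A", target_type = "B",
        source_gene = lig[1], target_gene = genes[n_ligands + 1L],
        r = coupling_r, stringsAsFactors = FALSE),
      checkerboard = data.frame(
        source_type = "A", target_type = "B",
        source_gene = lig[1], target_gene = genes[n_ligands + 1L],
        r = coupling_r, stringsAsFactors = FALSE),
      boundary = data.frame( # three targets across the A|B interface
        source_type = "A", target_type = "B",
        source_gene = lig[1],
        target_gene = genes[n_ligands + seq_len(min(3L, n_genes - n_ligands))],
        r = coupling_r, stringsAsFactors = FALSE),
      blocks = {
        # zone-structured communication: the two types sharing a zone talk
        # through that zone's ligand, each direction driving 3 target genes
        # (several targets per ligand keep the planted signal above the
        # alpha-level background that a ligand accumulates over all tested
        # target genes)
        if (n_ligands < 3L || n_genes < n_ligands + 18L)
          stop("blocks preset needs >= 3 ligands and 18 spare target genes")
        st <- c("T1", "T2", "T2", "T3", "T3", "T4")
        tt <- c("T2", "T1", "T3", "T2", "T4", "T3")
        lg <- lig[c(1, 1, 2, 2, 3, 3)]
        tg <- genes[n_ligands + seq_len(18L)]
        data.frame(
          source_type = rep(st, each = 3L),
          target_type = rep(tt, each = 3L),
          source_gene = rep(lg, each = 3L),
          target_gene = tg,
          r = coupling_r, stringsAsFactors = FALSE)
      })
  }
  stopifnot(all(c("source_type", "target_type", "source_gene",
                  "target_gene", "r") %in% names(couplings)))
  if (!all(couplings$source_gene %in% genes) ||
      !all(couplings$target_gene %in% genes))
    stop("coupling genes must exist in the gene universe")
  if (any(abs(couplings$r) >= 1)) stop("coupling r must lie in (-1, 1)")
  structure(list(preset = preset, nx = nx, ny = ny, n_pairs = n_pairs,
                 n_genes = n_genes,
                 n_ligands = n_ligands, genes = genes, ligands = lig,
                 couplings = couplings, mu_range = mu_range,
                 nb_size = nb_size, zero_inflation = zero_inflation,
                 local_coupling = local_coupling, seed = as.integer(seed)),
            class = "sim_config")
}

# spatially smooth latent field (gaussian-kernel-smoothed noise),
# standardized over the cells that will load on it so the planted loading
# keeps unit variance there
smooth_field <- function(coords, bw = 2, cells = seq_len(nrow(coords))) {
  D2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-D2 / (2 * bw^2))
  S <- as.vector(K %*% stats::rnorm(nrow(coords)))
  (S - mean(S[cells])) / stats::sd(S[cells])
}

# per-cell euclidean distance from each of `from` to the nearest of `to`
type_distance <- function(coords, from, to) {
  apply(coords[from, , drop = FALSE], 1L, function(p)
    sqrt(min((coords[to, 1] - p[1])^2 + (coords[to, 2] - p[2])^2)))
}

# zone/type layout for a config; returns list(type, env)
sim_layout <- function(config) {
  if (config$preset == "pairs") {
    np <- config$n_pairs
    return(list(type = rep(c("A", "B"), np),
                env = rep("slide", 2L * np)))
  }
  ix <- rep(seq_len(config$nx), times = config$ny)
  iy <- rep(seq_len(config$ny), each = config$nx)
  switch(config$preset,
    checkerboard = list(type = ifelse((ix + iy) %% 2L == 0L, "A", "B"),
                        env = rep("slide", length(ix))),
    boundary = list(type = ifelse(ix <= config$nx / 2, "A", "B"),
                    env = ifelse(ix <= config$nx / 2, "left", "right")),
    blocks = {
      # random 50/50 mixing of the zone's two types: every cell's radius-1
      # neighborhood then reflects the zone composition (a parity layout
      # would instead alternate compositions cell by cell), and balanced
      # mixing maximizes the inter-type pair count of every zone. The
      # zone/type chain is invariant under full reversal up to pattern
      # relabeling; negative controls must exclude that automorphism.
      zone <- cut(ix, breaks = 3L, labels = FALSE)
      pick <- stats::runif(length(ix)) < 0.5
      type <- character(length(ix))
      type[zone == 1L] <- ifelse(pick[zone == 1L], "T1", "T2")
      type[zone == 2L] <- ifelse(pick[zone == 2L], "T2", "T3")
      type[zone == 3L] <- ifelse(pick[zone == 3L], "T3", "T4")
      list(type = type, env = paste0("zone", zone))
    })
}

#' Simulate a spatial dataset with planted intercellular couplings
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{a [spatial_dataset()] of counts (platform `"bead"`).}
#'     \item{truth}{list: `couplings` (the planted table), `env` (per-cell
#'       ground-truth microenvironment label), `type` (per-cell type).}
#'     \item{lr}{an [lr_db()] with one receptor unit per ligand (receptor
#'       subunit symbols `rec_<ligand>`, not part of the expression matrix).}
#'     \item{gene_sets}{a [gene_sets()] collection: per ligand one pathway
#'       containing its receptor subunit and its coupled target genes, plus a
#'       receptor-free decoy set; and one ontology-style set per ligand.}
#'   }
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- sim_layout(config)
  if (config$preset == "pairs") {
    np <- config$n_pairs
    n_cells <- 2L * np
    per_row <- 25L
    px <- 3 * ((seq_len(np) - 1L) %% per_row)
    py <- 3 * ((seq_len(np) - 1L) %/% per_row)
    coords <- cbind(x = as.numeric(rbind(px, px + 1)),
                    y = as.numeric(rbind(py, py)))
  } else {
    nx <- config$nx; ny <- config$ny
    n_cells <- nx * ny
    coords <- cbind(x = as.numeric(rep(seq_len(nx), times = ny)),
                    y = as.numeric(rep(seq_len(ny), each = nx)))
  }
  cell_ids <- sprintf("c%04d", seq_len(n_cells))

  m <- config$n_genes
  mu <- stats::runif(m, config$mu_range[1], config$mu_range[2])
  # ligands under study are well expressed by selection: draw their means
  # from the upper half of the range
  li <- seq_len(config$n_ligands)
  mu[li] <- stats::runif(config$n_ligands, mean(config$mu_range),
                         config$mu_range[2])
  Z <- matrix(stats::rnorm(m * n_cells), m, n_cells,
              dimnames = list(config$genes, cell_ids))

  # adjacency on the unit grid (4-neighborhood)
  graph <- build_neighbor_graph(coords, threshold = 1.0)

  # Two planting mechanisms. In the isolated-pairs layout each target cell
  # has exactly one neighbor, so the target-gene latent can be re-drawn
  # against that partner's source-gene latent at exactly correlation r. In
  # contiguous layouts a cell has one expression value but several partners,
  # so a per-pair copula can only reach a 1/t_a fraction of the pairs;
  # instead, both sides load on a spatially smooth communication field:
  # source gene in source-type cells and target gene in target-type cells
  # follow sqrt(r) * field + sqrt(1 - r) * noise, giving every adjacent pair
  # correlation r times the field's (near-1) adjacent autocorrelation.
  pair_mode <- config$preset == "pairs"
  cps <- config$couplings
  grp <- interaction(cps$source_type, cps$source_gene, drop = TRUE)
  for (gi in levels(grp)) {
    rows <- which(grp == gi)
    st <- cps$source_type[rows[1]]; sg <- cps$source_gene[rows[1]]
    src_cells <- which(lay$type == st)
    S <- NULL
    for (ci in rows) {
      cp <- cps[ci, ]
      tg <- cp$target_gene; r <- cp$r
      tgt_cells <- which(lay$type == cp$target_type)
      touched <- any(vapply(tgt_cells, function(v)
        any(lay$type[graph$adjacency[[v]]] == st), TRUE))
      if (!touched) {
        warning(sprintf("coupling %s->%s (%s->%s) is inert: types never adjacent",
                        st, cp$target_type, sg, tg))
        next
      }
      if (pair_mode) {
        for (v in tgt_cells) {
          nb <- graph$adjacency[[v]]
          nb <- nb[lay$type[nb] == st]
          if (!length(nb)) next
          Z[tg, v] <- r * Z[sg, nb[1L]] + sqrt(1 - r^2) * Z[tg, v]
        }
      } else {
        if (is.null(S)) { # one field per (source type, source gene)
          # standardize the field over the cells whose pairs are actually
          # tested: the source cells and their adjacent target-type cells
          tgt_types <- unique(cps$target_type[rows])
          iface <- which(lay$type %in% tgt_types &
                           vapply(graph$adjacency, function(nb)
                             any(lay$type[nb] == st), TRUE))
          grp_cells <- union(src_cells, iface)
          S <- smooth_field(coords, bw = 2, cells = grp_cells)
          # optional paracrine locality: only cells adjacent to the opposite
          # type load on the field, so planted communication structure lives
          # at type interfaces and pairs deep inside a homogeneous region
          # stay at baseline (per-cell variance stays 1 either way)
          a_src <- sqrt(abs(r)) * (if (config$local_coupling)
            as.numeric(type_distance(coords, src_cells,
                                     which(lay$type %in% tgt_types)) <= graph$threshold)
            else 1)
          Z[sg, src_cells] <- a_src * S[src_cells] +
            sqrt(1 - a_src^2) * Z[sg, src_cells]
        }
        a_tgt <- sign(r) * sqrt(abs(r)) * (if (config$local_coupling)
          as.numeric(type_distance(coords, tgt_cells, src_cells) <= graph$threshold)
          else 1)
        Z[tg, tgt_cells] <- a_tgt * S[tgt_cells] +
          sqrt(1 - a_tgt^2) * Z[tg, tgt_cells]
      }
    }
  }

  # monotone transform to zero-inflated NB counts (copula-preserving)
  pi0 <- config$zero_inflation
  counts <- matrix(0L, m, n_cells, dimnames = dimnames(Z))
  for (g in seq_len(m)) {
    u <- stats::pnorm(Z[g, ])
    cnt <- integer(n_cells)
    pos <- u >= pi0
    cnt[pos] <- stats::qnbinom((u[pos] - pi0) / (1 - pi0),
                               size = config$nb_size, mu = mu[g])
    counts[g, ] <- cnt
  }

  dataset <- spatial_dataset(counts, coords, gene_ids = config$genes,
                             cell_ids = cell_ids, cell_type = lay$type,
                             platform = "bead")

  lig <- config$ligands
  rec <- paste0("rec_", lig)
  lr <- lr_db(ligand = lig, receptor = rec,
              pathway = paste0("PW_", lig))

  sets <- list()
  for (i in seq_along(lig)) {
    tgt <- config$couplings$target_gene[config$couplings$source_gene == lig[i]]
    extra <- config$genes[min(config$n_ligands + 7L, config$n_genes)]
    sets[[paste0("PW_", lig[i])]] <- unique(c(rec[i], tgt, extra))
    sets[[paste0("GO_", lig[i])]] <- unique(c(lig[i], "dummy_gene"))
  }
  sets[["DECOY"]] <- utils::tail(config$genes, 3L) # no receptor subunit
  gs <- gene_sets(sets, source = "synthetic")

  list(dataset = dataset,
       truth = list(couplings = config$couplings, env = lay$env,
                    type = lay$type),
       lr = lr, gene_sets = gs)
}
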