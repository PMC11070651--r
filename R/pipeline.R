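# End-to-end pipeline: simulate/read -> neighbors -> networks -> activity ->
# sankey / clustering / patterns, with a parameter manifest JSON beside every
# run. Outputs are plain CSV/JSON and byte-stable under a fixed seed.

#' Default pipeline configuration
#'
#' @param seed master seed (mandatory in the manifest; all stochastic stages
#'   derive from it).
#' @param preset synthetic preset used when no input paths are given.
#' @param b,alpha,min_pairs association-test parameters.
#' @param n_top high-activity ligand count for the Sankey stage.
#' @param n_env microenvironments for the pattern stage.
#' @param k pattern count (NMF rank).
#' @param resolution clustering resolution.
#' @param expr_path,coords_path,labels_path,platform,genes_path,cells_path
#'   input files (see [read_spatial_dataset()]); when `expr_path` is `NULL`
#'   the synthetic preset is generated instead.
#' @return A named list of class `igan_config`.
#' @export
igan_config <- function(seed = 1L, preset = "checkerboard", b = 0.1,
                        alpha = 0.01, min_pairs = 10L, n_top = 10L,
                        n_env = 3L, k = 2L, resolution = 1.0,
                        expr_path = NULL, coords_path = NULL,
                        labels_path = NULL, platform = "bead",
                        genes_path = NULL, cells_path = NULL) {
  structure(as.list(environment()), class = "igan_config")
}

#' Run the full pipeline into an output directory
#'
#' Stages: data (synthetic preset or files) -> neighbor graph -> association
#' networks -> activity/strength map -> CCC clustering -> Sankey graph (when
#' a ligand-receptor table and pathway sets are available) -> microenvironment
#' pattern consistency. Every stage writes plain CSV/JSON; `manifest.json`
#' records all parameters and seeds. Inputs are never mutated and reruns with
#' the same configuration produce identical bytes.
#'
#' @param config an [igan_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fitted objects.
#' @export
run_igan <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "igan_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  # --- data stage -----------------------------------------------------------
  if (is.null(config$expr_path)) {
    say("stage data: synthetic preset '", config$preset, "'")
    sim <- simulate_spatial(sim_config(config$preset, seed = config$seed))
    dataset <- sim$dataset; lr <- sim$lr; sets <- sim$gene_sets
    truth_env <- sim$truth$env
  } else {
    say("stage data: reading files")
    dataset <- read_spatial_dataset(config$expr_path, config$coords_path,
                                    config$labels_path, config$platform,
                                    config$genes_path, config$cells_path)
    lr <- NULL; sets <- NULL; truth_env <- NULL
  }

  # --- fit ------------------------------------------------------------------
  say("stage network: association networks")
  fit <- igan(dataset, lr = lr, b = config$b, alpha = config$alpha,
              min_pairs = config$min_pairs, verbose = verbose)

  edges <- do.call(rbind, lapply(names(fit$networks), function(key) {
    e <- fit$networks[[key]]$edges
    if (!nrow(e)) return(NULL)
    data.frame(combination = key,
               cell_a = dataset$cell_ids[e$cell_a],
               cell_b = dataset$cell_ids[e$cell_b],
               gene_i = e$gene_i, gene_j = e$gene_j,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(combination = character(), cell_a = character(),
                        cell_b = character(), gene_i = character(),
                        gene_j = character())
  utils::write.csv(edges, file.path(out_dir, "edges.csv"), row.names = FALSE)

  graph_df <- data.frame(cell_a = dataset$cell_ids[fit$graph$edges[, "a"]],
                         cell_b = dataset$cell_ids[fit$graph$edges[, "b"]],
                         distance = fit$graph$edges[, "dist"])
  utils::write.csv(graph_df, file.path(out_dir, "neighbors.csv"), row.names = FALSE)

  # --- activity -------------------------------------------------------------
  say("stage activity")
  act <- fit$activity
  act_df <- data.frame(cell_id = act$cell_ids, t = act$t,
                       strength = unname(act$strength))
  utils::write.csv(cbind(act_df, act$send, act$recv),
                   file.path(out_dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(strength_map(act, dataset$coords),
                   file.path(out_dir, "strength_map.csv"), row.names = FALSE)

  # --- clustering -----------------------------------------------------------
  say("stage cluster")
  FF <- build_feature_matrix(act, fit$ligands)
  cl <- cluster_cells(FF, mode = "ccc_only", resolution = config$resolution,
                      n_pcs = min(20L, ncol(FF)), seed = config$seed)
  utils::write.csv(data.frame(cell_id = dataset$cell_ids, ccc_cluster = cl),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)

  # --- sankey ---------------------------------------------------------------
  sankey <- NULL
  if (!is.null(lr) && !is.null(sets) && length(fit$networks)) {
    say("stage sankey")
    key <- names(fit$networks)[which.max(vapply(fit$networks,
                                                function(nw) nrow(nw$edges), 1L))]
    pw <- gene_sets(sets[startsWith(names(sets), "PW_") | names(sets) == "DECOY"],
                    source = "synthetic")
    go <- gene_sets(sets[startsWith(names(sets), "GO_")], source = "synthetic")
    sankey <- suppressWarnings(
      build_sankey(act, fit$networks[[key]], lr, pw, go,
                   cell_type = fit$cell_type, n_top = config$n_top))
    write_sankey(sankey, file.path(out_dir, "sankey.json"),
                 file.path(out_dir, "sankey_links.csv"))
  }

  # --- patterns -------------------------------------------------------------
  patterns <- NULL
  if (length(unique(fit$cell_type)) >= 2L) {
    say("stage patterns")
    me <- simple_microenvironments(fit$graph, fit$cell_type,
                                   n_env = min(config$n_env, length(unique(truth_env %||% fit$cell_type))),
                                   seed = config$seed)
    kk <- min(config$k, dim(me$E))
    counts <- as.numeric(table(fit$cell_type)[rownames(me$E)])
    Cs <- build_comm_matrix(fit$networks, rownames(me$E), fit$ligands, "sending")
    Cr <- build_comm_matrix(fit$networks, rownames(me$E), fit$ligands, "receiving")
    patterns <- tryCatch({
      dE <- nmf_patterns(me$E, kk, seed = config$seed)
      scores <- data.frame(
        direction = c("sending", "receiving"),
        kl = c(weighted_kl(dE, nmf_patterns(Cs, kk, seed = config$seed), counts)$kl,
               weighted_kl(dE, nmf_patterns(Cr, kk, seed = config$seed), counts)$kl))
      utils::write.csv(scores, file.path(out_dir, "pattern_scores.csv"),
                       row.names = FALSE)
      scores
    }, error = function(e) {
      say("pattern stage skipped: ", conditionMessage(e))
      NULL
    })
  }

  write_manifest(list(
    seed = config$seed, preset = config$preset, b = config$b,
    alpha = config$alpha, min_pairs = config$min_pairs, n_top = config$n_top,
    n_env = config$n_env, k = config$k, resolution = config$resolution,
    method = fit$params$method, tie_break = fit$params$tie_break,
    threshold = fit$params$threshold,
    high_activity_rule = sprintf("top-%d ligands by mean sending activity, mean > 0", config$n_top),
    statistic = "focal-excluded hypergeometric window test"
  ), file.path(out_dir, "manifest.json"))

  invisible(list(fit = fit, clusters = cl, sankey = sankey,
                 patterns = patterns, out_dir = out_dir))
}
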