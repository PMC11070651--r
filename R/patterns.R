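# Microenvironment-consistency benchmark: cell-type x ligand communication
# matrices, paired NMF decompositions, and the weighted KL consistency score.

#' Cell-type x ligand communication matrix
#'
#' Sending entry `(i, j)`: sum over other cell types `i'` of the mean, over
#' the ordered `(i, i')` cell pairs, of ligand `j`'s association row sum;
#' receiving uses the reversed networks `(i', i)`. Skipped type combinations
#' contribute zero; a type with no inter-type pairs yields a zero row with a
#' warning.
#'
#' @param networks list of `igan_networks` (e.g. `fit$networks`), named or
#'   not; combination types are read from the objects.
#' @param cell_types character vector of all cell types (row universe).
#' @param ligands ligand vector (column universe).
#' @param direction `"sending"` or `"receiving"`.
#' @return Numeric matrix, cell types x ligands.
#' @export
build_comm_matrix <- function(networks, cell_types, ligands,
                              direction = c("sending", "receiving")) {
  direction <- match.arg(direction)
  if (inherits(networks, "igan_networks")) networks <- list(networks)
  cell_types <- unique(as.character(cell_types))
  ligands <- unique(as.character(ligands))
  C <- matrix(0, length(cell_types), length(ligands),
              dimnames = list(cell_types, ligands))
  touched <- setNames(logical(length(cell_types)), cell_types)
  for (nw in networks) {
    if (nw$A == nw$B) next # inter-type sums only (i' != i)
    e <- nw$edges
    e <- e[e$gene_i %in% ligands, , drop = FALSE]
    cnt <- table(factor(e$gene_i, levels = ligands))
    if (direction == "sending") {
      # pairs (a in A, b in B): A sends
      C[nw$A, ] <- C[nw$A, ] + as.numeric(cnt) / nw$n
      touched[nw$A] <- TRUE
    } else {
      # receiving for type B uses H^(ab) with the roles reversed: the
      # (A, B) networks carry the ligand signal B receives from A
      C[nw$B, ] <- C[nw$B, ] + as.numeric(cnt) / nw$n
      touched[nw$B] <- TRUE
    }
  }
  silent <- cell_types[!touched]
  if (length(silent))
    warning("cell type(s) without inter-type pairs: ",
            paste(silent, collapse = ", "))
  C
}

#' Composition-based spatial microenvironments
#'
#' A light-weight stand-in for dedicated microenvironment callers: each
#' cell's neighborhood cell-type composition vector (neighbors plus itself)
#' is clustered with k-means into `n_env` microenvironment types, and the
#' cell-type x environment count matrix `E` is tabulated.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param cell_type per-cell labels.
#' @param n_env number of microenvironment types.
#' @param seed k-means seed.
#' @return List with `E` (cell types x environments count matrix, integer)
#'   and `env` (per-cell environment label).
#' @export
simple_microenvironments <- function(graph, cell_type, n_env, seed = 0L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cell_type <- as.character(cell_type)
  n <- length(graph$t)
  if (n_env > n) stop("n_env exceeds the number of cells")
  types <- sort(unique(cell_type))
  comp <- matrix(0, n, length(types), dimnames = list(NULL, types))
  for (i in seq_len(n)) {
    nb <- c(i, graph$adjacency[[i]])
    tt <- table(factor(cell_type[nb], levels = types))
    comp[i, ] <- as.numeric(tt) / length(nb)
  }
  distinct <- nrow(unique(comp))
  k <- min(n_env, distinct)
  if (k < n_env)
    warning(sprintf("only %d distinct compositions; using %d environments", distinct, k))
  env <- if (k == 1L) rep(1L, n) else
    with_private_seed(seed, stats::kmeans(comp, centers = k, nstart = 10)$cluster)
  E <- as.matrix(table(factor(cell_type, levels = types),
                       factor(env, levels = seq_len(k))))
  dimnames(E) <- list(types, paste0("env", seq_len(k)))
  list(E = E, env = env)
}

#' Non-negative matrix factorization into communication patterns
#'
#' Columns are scaled to maximum 1, then the matrix is factorized as
#' `W (m x k) %*% Hb (k x n)` by multiplicative updates under the Frobenius
#' objective with seed-controlled uniform initialization.
#'
#' @param mat non-negative matrix.
#' @param k rank (number of patterns), `k <= min(dim(mat))`.
#' @param seed RNG seed for the initialization.
#' @param n_starts random restarts; the factorization with the lowest
#'   reconstruction error is kept (multiplicative updates only find local
#'   minima).
#' @param n_iter,tol update iterations and relative-change stop tolerance.
#' @return An object of class `pattern_decomposition`: list with `loadings`
#'   (`W`, rows = input rows, columns = patterns), `basis` (`Hb`), `k`,
#'   `seed`, `error` (final relative Frobenius error), `scaled` (the
#'   column-scaled input).
#' @export
nmf_patterns <- function(mat, k, seed = 0L, n_starts = 5L, n_iter = 2000L,
                         tol = 1e-9) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be non-negative")
  if (all(mat == 0)) stop("all-zero matrix cannot be factorized")
  if (k > min(dim(mat))) stop("k exceeds min(dim(mat))")
  cmax <- apply(mat, 2L, max)
  scl <- ifelse(cmax > 0, cmax, 1)
  V <- sweep(mat, 2L, scl, "/")
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-10
  nV <- max(norm(V, "F"), eps)
  res <- with_private_seed(seed, {
    best <- NULL
    for (st in seq_len(n_starts)) {
      W <- matrix(stats::runif(m * k), m, k)
      Hb <- matrix(stats::runif(k * n), k, n)
      err_prev <- Inf
      for (it in seq_len(n_iter)) {
        Hb <- Hb * (t(W) %*% V) / (t(W) %*% W %*% Hb + eps)
        W <- W * (V %*% t(Hb)) / (W %*% Hb %*% t(Hb) + eps)
        if (it %% 25L == 0L) {
          err <- norm(V - W %*% Hb, "F") / nV
          if (abs(err_prev - err) < tol) break
          err_prev <- err
        }
      }
      err <- norm(V - W %*% Hb, "F") / nV
      if (is.null(best) || err < best$err)
        best <- list(W = W, Hb = Hb, err = err)
    }
    best
  })
  err <- res$err
  dimnames(res$W) <- list(rownames(mat), paste0("pattern", seq_len(k)))
  dimnames(res$Hb) <- list(paste0("pattern", seq_len(k)), colnames(mat))
  structure(list(loadings = res$W, basis = res$Hb, k = k, seed = seed,
                 error = err, scaled = V),
            class = "pattern_decomposition")
}

#' Reconstruction-error scan over candidate pattern counts
#'
#' @param mat non-negative matrix.
#' @param ks candidate ranks.
#' @param seed seed passed to each factorization.
#' @return Data frame `k`, `error` — the rank choice (elbow) is the user's.
#' @export
nmf_rank_scan <- function(mat, ks = seq_len(min(dim(mat))), seed = 0L) {
  data.frame(k = ks,
             error = vapply(ks, function(kk)
               nmf_patterns(mat, kk, seed = seed)$error, 1.0))
}

#' Weighted KL consistency between microenvironment and CCC patterns
#'
#' Compares the cell-type loading matrices of two rank-`k` decompositions
#' (microenvironment `E^a` vs communication `C^a`). Cell-type weights are
#' the cell-count proportions; pattern weights are the row sums of the
#' microenvironment basis `E^b`. Each loading row is normalized to unit mass
#' under the pattern-weight measure (with floor `eps`), which makes the
#' weighted sum a proper KL divergence: non-negative, zero iff the aligned
#' rows agree. Because NMF pattern order is arbitrary, the communication
#' patterns are first aligned to the microenvironment patterns by the
#' permutation minimizing the total score (exhaustive for `k <= 8`, greedy
#' otherwise).
#'
#' @param decompE microenvironment [nmf_patterns()] decomposition.
#' @param decompC communication [nmf_patterns()] decomposition (same `m`, `k`).
#' @param cell_counts per-cell-type cell counts `N_i`, aligned with the rows.
#' @param eps probability floor (default 1e-12).
#' @return An object of class `kl_consistency`: list with `kl` (the score),
#'   `alignment` (permutation applied to the C patterns), `contributions`
#'   (m x k term matrix), `w_celltype`, `w_pattern`.
#' @export
weighted_kl <- function(decompE, decompC, cell_counts, eps = 1e-12) {
  stopifnot(inherits(decompE, "pattern_decomposition"),
            inherits(decompC, "pattern_decomposition"))
  if (decompE$k != decompC$k) stop("pattern counts k differ")
  Ea <- decompE$loadings; Ca <- decompC$loadings
  if (nrow(Ea) != nrow(Ca)) stop("cell-type dimensions differ")
  m <- nrow(Ea); k <- decompE$k
  if (length(cell_counts) != m) stop("cell_counts must match the rows")
  w_ct <- cell_counts / sum(cell_counts)
  w_p <- pmax(rowSums(decompE$basis), eps)

  norm_rows <- function(M, perm = seq_len(k)) {
    M <- pmax(M[, perm, drop = FALSE], eps)
    sweep(M, 1L, as.vector(M %*% w_p), "/") # unit mass under the w_p measure
  }
  En <- norm_rows(Ea)
  score_for <- function(perm) {
    Cn <- norm_rows(Ca, perm)
    contrib <- sweep(En * log(En / Cn), 2L, w_p, "*") * w_ct
    list(kl = sum(contrib), contributions = contrib)
  }
  perms <- if (k <= 8L) all_permutations(k) else list(greedy_alignment(En, Ca, w_ct, w_p, norm_rows))
  best <- NULL; best_perm <- NULL
  for (p in perms) {
    s <- score_for(p)
    if (is.null(best) || s$kl < best$kl) { best <- s; best_perm <- p }
  }
  structure(list(kl = best$kl, alignment = best_perm,
                 contributions = best$contributions,
                 w_celltype = w_ct, w_pattern = w_p),
            class = "kl_consistency")
}

# greedy pattern matching for large k: repeatedly pair the E pattern with the
# C pattern of smallest column-wise weighted divergence
greedy_alignment <- function(En, Ca, w_ct, w_p, norm_rows) {
  k <- ncol(En)
  Cn <- norm_rows(Ca)
  cost <- matrix(Inf, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cost[i, j] <- sum(w_ct * En[, i] * log(En[, i] / Cn[, j]) * w_p[i])
  perm <- integer(k); used <- logical(k)
  for (i in order(apply(cost, 1L, min))) {
    j <- which.min(ifelse(used, Inf, cost[i, ]))
    perm[i] <- j; used[j] <- TRUE
  }
  perm
}

#' @export
print.kl_consistency <- function(x, ...) {
  cat(sprintf("weighted KL consistency: %.6g (alignment: %s)\n",
              x$kl, paste(x$alignment, collapse = " ")))
  invisible(x)
}

#' Benchmark communication methods against microenvironment patterns
#'
#' For each dataset entry, decomposes the microenvironment matrix `E` and
#' every method's communication matrices at the same rank `k`, computes the
#' weighted KL consistency per direction, and compares methods with a paired
#' Wilcoxon signed-rank test over the (dataset, direction) score pairs.
#'
#' @param datasets list of entries, each a list with `E` (cell types x
#'   environments), `cell_counts` (named per-type counts), and `comm`
#'   (named list of methods, each a list with matrices `sending` and/or
#'   `receiving`, cell types x ligands).
#' @param k shared pattern count.
#' @param seed NMF seed.
#' @return List with `scores` (data frame `dataset`, `method`, `direction`,
#'   `kl`) and `tests` (data frame of pairwise paired Wilcoxon results;
#'   `p = NA` when fewer than 5 paired scores or identical score vectors).
#' @export
benchmark_patterns <- function(datasets, k, seed = 0L) {
  rows <- list()
  for (di in seq_along(datasets)) {
    d <- datasets[[di]]
    dn <- names(datasets)[di] %||% paste0("dataset", di)
    if (is.null(dn) || dn == "") dn <- paste0("dataset", di)
    dE <- nmf_patterns(d$E, k, seed = seed)
    for (mn in names(d$comm)) {
      for (dir in intersect(c("sending", "receiving"), names(d$comm[[mn]]))) {
        Cmat <- d$comm[[mn]][[dir]]
        dC <- nmf_patterns(Cmat, k, seed = seed)
        kl <- weighted_kl(dE, dC, d$cell_counts)$kl
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = dn, method = mn, direction = dir, kl = kl,
          stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, rows)
  methods <- unique(scores$method)
  tests <- list()
  if (length(methods) >= 2L) {
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (i >= j) next
      a <- scores[scores$method == methods[i], ]
      b <- scores[scores$method == methods[j], ]
      key <- paste(a$dataset, a$direction)
      b <- b[match(key, paste(b$dataset, b$direction)), ]
      ok <- stats::complete.cases(a$kl, b$kl)
      pv <- if (sum(ok) < 5L || all(a$kl[ok] == b$kl[ok])) NA_real_ else
        suppressWarnings(stats::wilcox.test(a$kl[ok], b$kl[ok], paired = TRUE)$p.value)
      tests[[length(tests) + 1L]] <- data.frame(
        method1 = methods[i], method2 = methods[j],
        n = sum(ok), median_diff = stats::median(a$kl[ok] - b$kl[ok]),
        p = pv, stringsAsFactors = FALSE)
    }
  }
  list(scores = scores,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(method1 = character(), method2 = character(),
                    n = integer(), median_diff = numeric(), p = numeric()))
}
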