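# The cell-pair association test. For a directed cell-type combination the n
# adjacent pairs (a_k, b_k) define a scatter: x = expression of a source gene
# in a_1..a_n, y = expression of a target gene in b_1..b_n. Around each focal
# pair k a local window is drawn on each axis (the ceil(b*n) pairs nearest in
# value); the joint window occupancy n_xy measures the local joint density
# against the product of marginals. Because the focal pair sits in both
# windows by construction it carries no evidence: the decision rule is based
# on the focal-excluded counts, whose null law is exactly
# n_xy - 1 ~ Hypergeometric(n - 1, w - 1, w - 1) under independence.

#' Window occupancy counts around a focal cell pair
#'
#' The x-window holds the `ceiling(b * n)` pairs whose x-values are nearest to
#' the focal pair's value (the focal pair always included, remaining ties
#' broken by `tie_order`); the y-window analogously; `n_xy` is the size of
#' their intersection.
#'
#' @param x,y numeric vectors of length `n`: expression of the source gene in
#'   the source cells and of the target gene in the paired target cells.
#' @param k focal pair index.
#' @param b window fraction in (0, 1).
#' @param tie_order permutation of `1:n` used to break distance ties;
#'   defaults to pair index order.
#' @return A list with `n_x`, `n_y`, `n_xy`, `k`, `n` (all counts include the
#'   focal pair).
#' @export
window_counts <- function(x, y, k, b, tie_order = seq_along(x)) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop_typed("igan_too_few_pairs", "need at least 3 cell pairs")
  if (b <= 0 || b > 1) stop("window fraction b must be in (0, 1]")
  w <- ceiling(b * n)
  wx <- window_members(x, k, w, tie_order)
  wy <- window_members(y, k, w, tie_order)
  list(n_x = w, n_y = w, n_xy = length(intersect(wx, wy)), k = k, n = n)
}

# Indices of the w pairs nearest in value to x[k]; focal forced in.
window_members <- function(x, k, w, tie_order) {
  d <- abs(x - x[k])
  d[k] <- -1
  order(d, tie_order)[seq_len(w)]
}

# Window membership for every focal pair at once: n x n logical, row k marks
# the members of pair k's window.
#
# Tie handling. Counts (and monotone transforms of counts) are heavily tied;
# any fixed tie resolution shared across focal pairs couples the windows of
# different focals: one lucky overlap between the two genes' resolved tie
# classes then fires many focal pairs simultaneously (and index order
# additionally couples the x- and y-axis resolutions). Under
# tie_break = "scramble", ties are therefore resolved independently per focal
# pair, by a deterministic random stream seeded from the gene's own values —
# a pure function of the values, so the standalone-test and batch-network
# call paths agree exactly. Tie-free vectors take the plain path (the order
# never matters there).
window_membership <- function(x, w, tie_break = c("scramble", "index")) {
  tie_break <- match.arg(tie_break)
  n <- length(x)
  W <- matrix(FALSE, n, n)
  if (tie_break == "index" || !anyDuplicated(x)) {
    idx <- seq_len(n)
    for (k in idx) {
      d <- abs(x - x[k])
      d[k] <- -1
      W[k, order(d, idx)[seq_len(w)]] <- TRUE
    }
  } else {
    with_private_seed(hash_values(x), {
      for (k in seq_len(n)) {
        d <- abs(x - x[k])
        d[k] <- -1
        W[k, order(d, sample.int(n))[seq_len(w)]] <- TRUE
      }
    })
  }
  W
}

#' Association statistic for window occupancy counts
#'
#' Standardized excess of the joint window occupancy over the product of the
#' marginal occupancies:
#' \deqn{\hat\rho = \frac{n_{xy}/n - (n_x/n)(n_y/n)}
#'   {\sqrt{n_x n_y (n-n_x)(n-n_y) / (n^4 (n-1))}}}
#' Under independence of the two genes across cell pairs, \eqn{\hat\rho} is
#' approximately standard normal. With `n_x` or `n_y` equal to 0 or `n` the
#' statistic is undefined and `NA` is returned (treated downstream as no
#' association).
#'
#' @param counts a list with `n_x`, `n_y`, `n_xy` (as from [window_counts()]),
#'   or a numeric vector/data frame with those elements; vectorized.
#' @param n number of cell pairs.
#' @return Numeric statistic value(s); `NA_real_` where degenerate.
#' @export
association_statistic <- function(counts, n) {
  nx <- as.numeric(counts[["n_x"]]); ny <- as.numeric(counts[["n_y"]])
  nxy <- as.numeric(counts[["n_xy"]])
  num <- nxy / n - (nx / n) * (ny / n)
  den <- sqrt(nx * ny * (n - nx) * (n - ny) / (n^4 * (n - 1)))
  out <- num / den
  out[nx <= 0 | ny <= 0 | nx >= n | ny >= n] <- NA_real_
  out
}

# Critical focal-excluded joint count: smallest c such that the decision rule
# rejects when n_xy - 1 >= c, for n pairs and window size w at level alpha.
# method "exact" uses the hypergeometric tail; "normal" applies the
# association statistic's gaussian threshold to the focal-excluded counts.
critical_joint_count <- function(n, w, alpha, method = c("exact", "normal")) {
  method <- match.arg(method)
  K <- w - 1; N <- n - 1
  if (K < 1L || K >= N) return(Inf) # no usable evidence
  if (method == "exact") {
    cc <- stats::qhyper(1 - alpha, K, N - K, K)
    while (stats::phyper(cc - 1, K, N - K, K, lower.tail = FALSE) > alpha)
      cc <- cc + 1
    cc
  } else {
    mu <- K^2 / N
    sdv <- sqrt(K^2 * (N - K)^2 / (N^2 * (N - 1)))
    floor(mu + stats::qnorm(1 - alpha) * sdv) + 1
  }
}

#' Test one gene pair across a set of cell pairs
#'
#' Computes, for every focal pair `k`, the joint window occupancy of the two
#' genes and flags a positive local association at level `alpha`. The focal
#' pair itself (present in both windows by construction) is excluded from the
#' evidence; with `method = "exact"` (default) the cut-off comes from the
#' exact hypergeometric null of the focal-excluded joint count, with
#' `method = "normal"` from the gaussian threshold
#' \eqn{\hat\rho > \Phi^{-1}(1-\alpha)} applied to the focal-excluded counts.
#'
#' A gene with zero variance across the pairs yields all-zero results
#' (degenerate marginal).
#'
#' @param x,y numeric vectors of length `n` (source-side and target-side
#'   expression over the cell pairs).
#' @param b window fraction (default 0.1).
#' @param alpha significance level (default 0.01).
#' @param method `"exact"` or `"normal"`.
#' @param tie_break `"scramble"` (default; deterministic per-gene scrambled
#'   tie resolution) or `"index"`.
#' @return Integer vector `h` of length `n` (1 = associated at pair k), with
#'   attributes `n_xy` (inclusive joint counts) and `statistic` (the
#'   association statistic of the focal-excluded counts).
#' @export
test_gene_pair <- function(x, y, b = 0.1, alpha = 0.01,
                           method = c("exact", "normal"),
                           tie_break = c("scramble", "index")) {
  method <- match.arg(method)
  tie_break <- match.arg(tie_break)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop_typed("igan_too_few_pairs", "need at least 3 cell pairs")
  stopifnot(b > 0, b <= 1, alpha > 0, alpha < 1)
  w <- ceiling(b * n)
  zeros <- function() {
    h <- integer(n)
    attr(h, "n_xy") <- rep(NA_integer_, n)
    attr(h, "statistic") <- rep(NA_real_, n)
    h
  }
  if (stats::var(x) == 0 || stats::var(y) == 0 || w >= n || w < 2L)
    return(zeros())
  Wx <- window_membership(x, w, tie_break)
  Wy <- window_membership(y, w, tie_break)
  nxy <- as.integer(rowSums(Wx & Wy))
  cc <- critical_joint_count(n, w, alpha, method)
  h <- as.integer((nxy - 1L) >= cc)
  attr(h, "n_xy") <- nxy
  attr(h, "statistic") <- association_statistic(
    list(n_x = w - 1, n_y = w - 1, n_xy = nxy - 1L), n - 1)
  h
}

#' Build per-pair association networks for one cell-type combination
#'
#' Runs [test_gene_pair()] for every (source gene, target gene) combination on
#' the scatter defined by a [collect_cell_pairs()] set and scatters the
#' per-pair indicators into sparse directional networks
#' \eqn{H^{(a_k b_k)}}: entry `(i, j)` of pair `k`'s network is 1 iff source
#' gene `i` in cell `a_k` is associated with target gene `j` in cell `b_k`.
#'
#' @param dataset a [spatial_dataset()].
#' @param pairs a `cell_pair_set`.
#' @param source_genes,target_genes non-empty subsets of the dataset's genes.
#' @param b window fraction.
#' @param alpha significance level.
#' @param method,tie_break see [test_gene_pair()].
#' @param min_pairs minimum pair count; below it a condition of class
#'   `igan_too_few_pairs` is signalled.
#' @param norm optional pre-computed [normalize_dataset()] matrix (windows are
#'   drawn on normalized expression).
#' @return An object of class `igan_networks`: list with `edges` (data frame
#'   `k`, `cell_a`, `cell_b`, `gene_i`, `gene_j`; one row per H entry equal
#'   to 1), `pairs`, `n`, `A`, `B`, `source_genes`, `target_genes`, `params`.
#' @export
build_networks <- function(dataset, pairs, source_genes, target_genes,
                           b = 0.1, alpha = 0.01,
                           method = c("exact", "normal"),
                           tie_break = c("scramble", "index"),
                           min_pairs = 10L, norm = NULL) {
  method <- match.arg(method)
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(dataset, "spatial_dataset"), inherits(pairs, "cell_pair_set"))
  if (!length(source_genes) || !length(target_genes))
    stop("source and target gene lists must be non-empty")
  if (!all(source_genes %in% dataset$gene_ids) ||
      !all(target_genes %in% dataset$gene_ids))
    stop("source/target genes must be subsets of the dataset's genes")
  n <- attr(pairs, "n")
  if (n < min_pairs)
    stop_typed("igan_too_few_pairs",
               sprintf("only %d cell pairs for (%s -> %s); min_pairs = %d",
                       n, attr(pairs, "A"), attr(pairs, "B"), min_pairs))
  if (is.null(norm)) norm <- normalize_dataset(dataset)
  w <- ceiling(b * n)
  cc <- critical_joint_count(n, w, alpha, method)

  X <- norm[source_genes, pairs$a, drop = FALSE] # gene x pair
  Y <- norm[target_genes, pairs$b, drop = FALSE]
  varx <- apply(X, 1L, stats::var)
  vary <- apply(Y, 1L, stats::var)

  usable <- is.finite(cc) && w >= 2L && w < n
  src_idx <- if (usable) which(varx > 0) else integer()
  tgt_idx <- if (usable) which(vary > 0) else integer()
  Wx <- lapply(src_idx, function(i) window_membership(X[i, ], w, tie_break))
  Wy <- lapply(tgt_idx, function(j) window_membership(Y[j, ], w, tie_break))

  edge_list <- vector("list", length(src_idx) * length(tgt_idx))
  m <- 0L
  for (ii in seq_along(src_idx)) {
    Wxi <- Wx[[ii]]
    for (jj in seq_along(tgt_idx)) {
      nxy <- rowSums(Wxi & Wy[[jj]])
      ks <- which((nxy - 1) >= cc)
      if (length(ks)) {
        m <- m + 1L
        edge_list[[m]] <- data.frame(
          k = ks,
          gene_i = source_genes[src_idx[ii]],
          gene_j = target_genes[tgt_idx[jj]],
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (m) do.call(rbind, edge_list[seq_len(m)]) else
    data.frame(k = integer(), gene_i = character(), gene_j = character(),
               stringsAsFactors = FALSE)
  edges$cell_a <- pairs$a[edges$k]
  edges$cell_b <- pairs$b[edges$k]
  edges <- edges[, c("k", "cell_a", "cell_b", "gene_i", "gene_j")]
  rownames(edges) <- NULL
  structure(
    list(edges = edges, pairs = pairs, n = n,
         A = attr(pairs, "A"), B = attr(pairs, "B"),
         source_genes = source_genes, target_genes = target_genes,
         params = list(b = b, alpha = alpha, method = method,
                       tie_break = tie_break, w = w,
                       critical_joint_count = unname(cc))),
    class = "igan_networks"
  )
}

#' @export
print.igan_networks <- function(x, ...) {
  cat(sprintf("igan_networks (%s -> %s): %d cell pairs, %d x %d genes, %d associations\n",
              x$A, x$B, x$n, length(x$source_genes), length(x$target_genes),
              nrow(x$edges)))
  invisible(x)
}
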