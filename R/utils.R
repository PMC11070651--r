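# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed condition
#'
#' Used for the typed "no-pairs" / "too-few-pairs" signals so that callers can
#' catch a specific condition class and skip a cell-type combination instead of
#' aborting a whole run.
#' @noRd
stop_typed <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "igan_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

#' Run code with a private RNG stream, restoring the caller's stream
#'
#' Tie-break permutations and other internal randomization must not consume
#' the user's RNG stream, otherwise pipeline reproducibility would depend on
#' the order in which genes are visited.
#' @noRd
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Deterministic integer hash of a numeric vector
#'
#' Pure function of the values (not of external state), used to derive a
#' per-gene tie-break permutation: identical vectors map to identical
#' permutations, so the two call paths (standalone gene-pair test and batch
#' network construction) agree exactly.
#' @noRd
hash_values <- function(x) {
  x <- as.numeric(x)
  s <- sum((abs(x) + 1) * (seq_along(x) %% 9973 + 1)) + length(x)
  as.integer(floor(s * 1e4) %% 2147483629L) + 1L
}

#' Deterministic scrambled tie-break order for a value vector
#' @noRd
scrambled_tie_order <- function(x) {
  with_private_seed(hash_values(x), sample.int(length(x)))
}

#' Write a parameter manifest JSON next to pipeline outputs
#'
#' The manifest is byte-stable across reruns with the same configuration:
#' it records parameters, seeds and the package version, never wall-clock
#' state.
#' @noRd
write_manifest <- function(params, path) {
  params$package <- "igan"
  params$package_version <- as.character(utils::packageVersion("igan"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' All permutations of 1..k (k small)
#' @noRd
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
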