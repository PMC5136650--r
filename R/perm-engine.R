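# Chunked, reproducibly seeded permutation execution.
#
# Every permutation index owns its own random stream, derived from
# (master_seed, perm_index) alone. Chunking and the worker pool are pure
# scheduling: they decide *where* an index runs, never *what* it draws, so
# results are identical for any worker count and chunk layout.

.LEHMER_M <- 2147483647 # 2^31 - 1 (prime)
.LEHMER_A <- 48271

# One multiplicative-congruential step. Products stay below 2^53, so plain
# double arithmetic is exact and platform-stable.
lehmer_step <- function(s) (s * .LEHMER_A) %% .LEHMER_M

#' Reproducible per-permutation random stream
#'
#' Returns an independent random stream determined solely by
#' `(master_seed, perm_index)`. The stream is a Lehmer
#' (multiplicative-congruential) generator whose state is derived by mixing
#' the master seed and the permutation index through Lehmer steps and an
#' integer XOR, so streams for distinct indices start at scattered,
#' effectively independent points of the generator cycle. R's global random
#' number generator is never consulted or modified.
#'
#' @param master_seed Integer master seed for the whole run.
#' @param perm_index Non-negative integer identifying one permutation.
#' @return A list with functions:
#'   * `unif(k)`: `k` uniform draws on (0, 1);
#'   * `shuffle(n)`: a uniformly random permutation of `1:n`;
#'   * `sample_subset(n, m)`: `m` distinct indices from `1:n` (unordered).
#' @examples
#' rng <- perm_rng(42, 7)
#' rng$shuffle(5)
#' @export
perm_rng <- function(master_seed, perm_index = 0) {
  if (perm_index < 0) {
    rlang::abort("`perm_index` must be non-negative.")
  }
  s <- (as.double(master_seed) %% (.LEHMER_M - 1)) + 1
  s <- lehmer_step(s)
  s <- bitwXor(as.integer(s), as.integer(as.double(perm_index) %% .LEHMER_M))
  s <- (as.double(s) %% (.LEHMER_M - 1)) + 1
  s <- lehmer_step(lehmer_step(s))

  state <- s
  unif <- function(k) {
    out <- numeric(k)
    s <- state
    for (i in seq_len(k)) {
      s <- lehmer_step(s)
      out[i] <- s / .LEHMER_M
    }
    state <<- s
    out
  }
  shuffle <- function(n) order(unif(n))
  sample_subset <- function(n, m) {
    # Floyd's algorithm: m draws regardless of n.
    if (m > n) rlang::abort("cannot sample more indices than available")
    chosen <- integer(0)
    in_set <- new.env(hash = TRUE, parent = emptyenv())
    for (j in (n - m + 1):n) {
      t <- floor(unif(1) * j) + 1
      key <- as.character(t)
      if (is.null(in_set[[key]])) {
        assign(key, TRUE, envir = in_set)
        chosen <- c(chosen, t)
      } else {
        assign(as.character(j), TRUE, envir = in_set)
        chosen <- c(chosen, j)
      }
    }
    chosen
  }
  list(unif = unif, shuffle = shuffle, sample_subset = sample_subset)
}

#' Partition a permutation budget into deterministic chunks
#'
#' @param nperm Total number of permutations (>= 0).
#' @param chunk_size Permutations per chunk; defaults to
#'   `min(nperm, 1000)`.
#' @param master_seed Integer master seed recorded in the plan.
#' @return A `chunk_plan` object: list with `master_seed`, `nperm`,
#'   `chunk_size` and `chunks`, a list of half-open 0-based index ranges
#'   `c(from, to)` covering `[0, nperm)` exactly.
#' @export
chunk_plan <- function(nperm, chunk_size = NULL, master_seed = 1) {
  if (is.na(nperm) || nperm < 0) {
    rlang::abort("`nperm` must be a non-negative integer.")
  }
  nperm <- as.double(nperm)
  if (is.null(chunk_size)) chunk_size <- max(1, min(nperm, 1000))
  if (chunk_size < 1) rlang::abort("`chunk_size` must be >= 1.")
  starts <- seq(0, nperm, by = chunk_size)
  if (length(starts) == 0 || starts[length(starts)] < nperm) {
    starts <- c(starts, nperm)
  }
  starts <- unique(c(starts[starts < nperm], nperm))
  chunks <- if (nperm == 0) list() else
    lapply(seq_len(length(starts) - 1),
           function(i) c(starts[i], starts[i + 1]))
  structure(
    list(master_seed = as.double(master_seed), nperm = nperm,
         chunk_size = chunk_size, chunks = chunks),
    class = "chunk_plan"
  )
}

#' Run a permutation test over a chunk plan
#'
#' Computes the exceedance count of permuted statistics against the observed
#' one(s). The statistic callback receives the per-permutation random stream
#' and must be a pure function of it, so chunk layout and the worker pool
#' cannot change the result. Ties (`permuted == observed`) count as
#' exceedances and the p-value uses the `(1 + exceed) / (1 + nperm)`
#' convention, so it is never zero.
#'
#' @param observed Numeric vector (length >= 1) of observed statistic(s).
#' @param stat_fn `function(rng, perm_index)` returning a numeric vector of
#'   the same length as `observed` for one permutation. `rng` is the
#'   [perm_rng()] stream owned by `perm_index`.
#' @param plan A [chunk_plan()].
#' @param workers Number of parallel workers (forked processes; 1 = serial).
#' @return A `perm_test` object: `observed`, `nperm`, `exceed` (integer
#'   vector), `p_value`, `master_seed`.
#' @export
run_permutations <- function(observed, stat_fn, plan, workers = 1) {
  stopifnot(inherits(plan, "chunk_plan"), length(observed) >= 1)
  p <- length(observed)
  run_chunk <- function(range) {
    exceed <- numeric(p)
    for (idx in seq(range[1], length.out = range[2] - range[1])) {
      stat <- tryCatch(
        stat_fn(perm_rng(plan$master_seed, idx), idx),
        error = function(e) rlang::abort(
          sprintf("permutation %d (chunk [%d,%d)) failed: %s",
                  idx, range[1], range[2], conditionMessage(e)))
      )
      hit <- stat >= observed
      hit[is.na(hit)] <- FALSE
      exceed <- exceed + hit
    }
    exceed
  }
  chunk_results <-
    if (workers > 1 && length(plan$chunks) > 1 &&
        .Platform$OS.type == "unix") {
      parallel::mclapply(plan$chunks, run_chunk, mc.cores = workers)
    } else {
      lapply(plan$chunks, run_chunk)
    }
  for (res in chunk_results) {
    if (inherits(res, "try-error")) rlang::abort(as.character(res))
  }
  exceed <- Reduce(`+`, chunk_results, numeric(p))
  structure(
    list(observed = observed, nperm = plan$nperm, exceed = exceed,
         p_value = (1 + exceed) / (1 + plan$nperm),
         master_seed = plan$master_seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", x$nperm, "permutations, seed",
      format(x$master_seed), "\n")
  cat("  observed:", format(x$observed, digits = 6), "\n")
  cat("  p-value: ", format(x$p_value, digits = 6), "\n")
  invisible(x)
}

#' Outer product computed in row blocks
#'
#' Streams the outer product `x %o% y` as a list of row blocks whose
#' concatenation equals the dense result; the dense matrix is never
#' allocated in one piece.
#'
#' @param x,y Non-empty numeric vectors.
#' @param block_rows Rows of `x` per block (>= 1).
#' @return List of matrices; `do.call(rbind, .)` equals `outer(x, y)`.
#' @export
chunked_outer <- function(x, y, block_rows) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("`x` and `y` must be non-empty.")
  }
  if (block_rows < 1) rlang::abort("`block_rows` must be >= 1.")
  starts <- seq(1, length(x), by = block_rows)
  lapply(starts, function(s) {
    rows <- s:min(s + block_rows - 1, length(x))
    outer(x[rows], y)
  })
}
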