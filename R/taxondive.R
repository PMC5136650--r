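# Taxonomic diversity and distinctness indices per sample.
#
# For a sample with abundances x over species with pairwise taxonomic
# distances omega (pairs i < j):
#   Delta   = sum omega_ij x_i x_j / (N(N-1)/2),  N = total individuals
#   Delta*  = sum omega_ij x_i x_j / sum x_i x_j
#   Delta+  = sum_(present pairs) omega_ij / (S_s(S_s-1)/2)   (presence/absence)
#   Lambda+ = mean squared deviation of omega from Delta+ over present pairs
#   sDelta+ = S_s * Delta+
#   EDelta+ = mean omega over all pairs of the full species pool
# Indices whose denominator vanishes are NaN (with a warning), not errors.

taxondive_result <- function(samples, edelta_plus, S, accounting = NULL) {
  n_nan <- sum(is.nan(as.matrix(samples[c("Delta", "DeltaStar",
                                          "DeltaPlus", "LambdaPlus")])))
  if (n_nan > 0) {
    rlang::warn(sprintf(
      "%d undefined index value(s) (too few individuals or species); NaN",
      n_nan))
  }
  structure(
    list(samples = samples, EDeltaPlus = edelta_plus, S = S,
         accounting = accounting),
    class = "taxondive_result"
  )
}

#' @export
print.taxondive_result <- function(x, ...) {
  cat(sprintf(
    "Taxonomic diversity/distinctness: %d samples, pool of %d species\n",
    nrow(x$samples), x$S))
  cat(sprintf("Expected Delta+ of the pool: %.4f\n", x$EDeltaPlus))
  print(x$samples)
  invisible(x)
}

# Shared tail: turn per-sample accumulated pair sums into indices.
finish_taxondive <- function(x, sum_wxx, sum_w_pres, sum_w2_pres,
                             total_w, S, accounting = NULL) {
  n_tot <- rowSums(x)
  sum_xx <- (n_tot^2 - rowSums(x^2)) / 2
  pres <- x > 0
  s_rich <- rowSums(pres)
  npairs <- s_rich * (s_rich - 1) / 2
  suppressWarnings({
    delta <- sum_wxx / (n_tot * (n_tot - 1) / 2)
    delta_star <- sum_wxx / sum_xx
    delta_plus <- sum_w_pres / npairs
    lambda_plus <- sum_w2_pres / npairs - delta_plus^2
  })
  delta[n_tot < 2] <- NaN
  delta_star[sum_xx == 0] <- NaN
  delta_plus[npairs == 0] <- NaN
  lambda_plus[npairs == 0] <- NaN
  samples <- tibble::tibble(
    sample = rownames(x) %||% as.character(seq_len(nrow(x))),
    richness = as.double(unname(s_rich)),
    N = unname(n_tot),
    Delta = unname(delta),
    DeltaStar = unname(delta_star),
    DeltaPlus = unname(delta_plus),
    sDeltaPlus = unname(s_rich * delta_plus),
    LambdaPlus = unname(lambda_plus)
  )
  taxondive_result(samples, edelta_plus = total_w / (S * (S - 1)), S = S,
                   accounting = accounting)
}

#' Taxonomic diversity indices from a dense distance matrix
#'
#' Reference implementation against a fully materialised omega; suits small
#' species pools. For large pools use [taxondive_stream()], which gives the
#' same numbers without ever holding the full matrix.
#'
#' @param comm Community tibble or matrix (samples x species).
#' @param omega Square symmetric taxonomic distance matrix whose labels
#'   match `comm`'s species columns, in the same order (e.g. from
#'   [taxa2dist_full()]).
#' @return A `taxondive_result`: per-sample tibble of `Delta`, `DeltaStar`,
#'   `DeltaPlus`, `sDeltaPlus`, `LambdaPlus` plus the pool expectation
#'   `EDeltaPlus`.
#' @export
taxondive_dense <- function(comm, omega) {
  x <- comm_matrix(comm)
  w <- as.matrix(omega)
  if (!identical(colnames(x), rownames(w))) {
    rlang::abort("species labels of `comm` and `omega` must match exactly")
  }
  pres <- (x > 0) * 1
  sum_wxx <- rowSums((x %*% w) * x) / 2
  sum_w_pres <- rowSums((pres %*% w) * pres) / 2
  sum_w2_pres <- rowSums((pres %*% w^2) * pres) / 2
  finish_taxondive(x, sum_wxx, sum_w_pres, sum_w2_pres,
                   total_w = sum(w), S = ncol(x))
}

#' Streaming taxonomic diversity indices (any pool size)
#'
#' Fuses the distance computation with the index accumulation: omega is
#' produced one row block at a time, consumed immediately for all
#' per-sample accumulators, and discarded (or spilled to a block store),
#' so peak additional memory is one block plus a handful of per-sample
#' sums. Numerically the result equals [taxondive_dense()] applied to
#' [taxa2dist_full()] to within accumulation round-off; the output is
#' independent of `block_rows`.
#'
#' @param comm Community tibble or matrix (samples x species). Species must
#'   exactly match the aggregation table's species (by name).
#' @param agg Aggregation tibble (see [read_aggregation_csv()]).
#' @inheritParams compute_steps
#' @param block_rows Rows of omega per block; default sizes blocks to about
#'   64 MiB.
#' @param store Optional [block_store()]; when given, every omega block is
#'   also persisted under keys `omega_000001, ...`.
#' @return A `taxondive_result`; its `accounting` field reports
#'   `block_rows`, `n_blocks`, `max_block_bytes` and `full_matrix_bytes`
#'   (what the dense matrix would have needed).
#' @export
taxondive_stream <- function(comm, agg, varstep = FALSE, check = TRUE,
                             block_rows = NULL, store = NULL) {
  x <- comm_matrix(comm)
  agg <- validate_aggregation(agg)
  sp_agg <- as.character(agg[[1]])
  if (!setequal(colnames(x), sp_agg) || ncol(x) != length(sp_agg)) {
    rlang::abort(paste0(
      "species sets of `comm` and `agg` must be identical; ",
      "missing from agg: ", toString(utils::head(setdiff(colnames(x), sp_agg), 5)),
      "; missing from comm: ", toString(utils::head(setdiff(sp_agg, colnames(x)), 5))))
  }
  x <- x[, sp_agg, drop = FALSE] # align to aggregation order
  steps <- compute_steps(agg, varstep = varstep, check = check)
  S <- steps$S
  if (is.null(block_rows)) block_rows <- default_block_rows(S)
  block_rows <- max(1L, min(as.integer(block_rows), S))

  tx <- t(x)
  pres <- (x > 0) * 1
  tp <- t(pres)
  n <- nrow(x)
  sum_wxx <- numeric(n)
  sum_w_pres <- numeric(n)
  sum_w2_pres <- numeric(n)
  total_w <- 0
  n_blocks <- 0L
  max_block_bytes <- 0

  start <- 1L
  while (start <= S) {
    rows <- start:min(start + block_rows - 1L, S)
    W <- taxa2dist_block(steps, rows)
    n_blocks <- n_blocks + 1L
    max_block_bytes <- max(max_block_bytes, 8 * length(W))
    if (!is.null(store)) {
      bs_put(store, sprintf("omega_%06d", n_blocks), W)
    }
    # Sums over ordered pairs (i in block, j anywhere); the diagonal is 0.
    sum_wxx <- sum_wxx + rowSums(x[, rows, drop = FALSE] * t(W %*% tx))
    sum_w_pres <- sum_w_pres +
      rowSums(pres[, rows, drop = FALSE] * t(W %*% tp))
    W2 <- W * W
    sum_w2_pres <- sum_w2_pres +
      rowSums(pres[, rows, drop = FALSE] * t(W2 %*% tp))
    total_w <- total_w + sum(W)
    start <- start + block_rows
  }
  accounting <- list(
    block_rows = block_rows, n_blocks = n_blocks,
    max_block_bytes = max_block_bytes,
    full_matrix_bytes = 8 * S^2,
    store = if (!is.null(store)) bs_stats(store)
  )
  # Ordered-pair sums count each unordered pair twice.
  finish_taxondive(x, sum_wxx / 2, sum_w_pres / 2, sum_w2_pres / 2,
                   total_w = total_w, S = S, accounting = accounting)
}

#' Funnel expectations for Delta+
#'
#' Monte-Carlo funnel: for each subsample size `m`, draws random `m`-species
#' subsets of the pool, computes Delta+ of each and reports the mean and
#' empirical quantile bounds. Observed samples plotted against the funnel
#' show whether their distinctness is compatible with random draws from the
#' pool.
#'
#' @inheritParams compute_steps
#' @param sizes Integer vector of subsample sizes (each between 2 and S).
#' @param n_draws Random subsets per size (ignored when `exhaustive`).
#' @param master_seed Integer seed; draws use the package's own stream, not
#'   R's global RNG.
#' @param exhaustive Enumerate all subsets instead of sampling (only
#'   sensible for tiny pools).
#' @param probs Lower/upper quantile bounds (default central 95%).
#' @return A `funnel_table` tibble: `m`, `mean`, `lower`, `upper`,
#'   `n_draws`; attribute `EDeltaPlus` carries the pool expectation.
#' @export
funnel <- function(agg, sizes, n_draws = 999, master_seed = 1,
                   varstep = FALSE, check = TRUE, exhaustive = FALSE,
                   probs = c(0.025, 0.975)) {
  steps <- compute_steps(agg, varstep = varstep, check = check)
  S <- steps$S
  if (any(sizes < 2) || any(sizes > S)) {
    rlang::abort("subsample sizes must lie in [2, S]")
  }
  inc <- steps$increments
  codes <- steps$codes
  dplus_of <- function(idx) {
    m <- length(idx)
    W <- matrix(inc[1], m, m)
    for (k in seq_len(ncol(codes))) {
      W <- W + inc[k + 1] * outer(codes[idx, k], codes[idx, k], "!=")
    }
    diag(W) <- 0
    sum(W) / (m * (m - 1))
  }
  total_w <- 0
  start <- 1L
  bw <- default_block_rows(S)
  while (start <= S) {
    rows <- start:min(start + bw - 1L, S)
    total_w <- total_w + sum(taxa2dist_block(steps, rows))
    start <- start + bw
  }
  edelta <- total_w / (S * (S - 1))
  rows <- dplyr::bind_rows(purrr::map2(sizes, seq_along(sizes), function(m, mi) {
    draws <- if (exhaustive) {
      apply(utils::combn(S, m), 2, dplus_of)
    } else {
      vapply(seq_len(n_draws), function(d) {
        rng <- perm_rng(master_seed, (mi - 1) * n_draws + (d - 1))
        dplus_of(rng$sample_subset(S, m))
      }, numeric(1))
    }
    q <- stats::quantile(draws, probs = probs, names = FALSE)
    tibble::tibble(m = m, mean = mean(draws), lower = q[1], upper = q[2],
                   n_draws = length(draws))
  }))
  structure(rows, EDeltaPlus = edelta, probs = probs,
            class = c("funnel_table", class(rows)))
}
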