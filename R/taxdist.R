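# Taxonomic distances omega between species, from a classification
# aggregation table. omega(i, j) is the cumulative path length to the lowest
# taxonomic level at which species i and j agree, scaled so the maximum
# attainable distance (agreement only at the implicit root) is 100. The
# matrix is available either dense (small pools) or as a stream of row
# blocks (pools of any size); both come from the same block kernel.

#' Step lengths through the taxonomic hierarchy
#'
#' Derives the per-level path increments used to turn a classification into
#' distances. With `check = TRUE`, ranks at which all species are distinct
#' or all identical carry no information and are dropped; remaining ranks
#' are ordered by decreasing category count (ties keep their input, lowest
#' -first, order). The species level itself is the first step, so two
#' species sharing the lowest kept rank are one increment apart and
#' `omega = 0` only on the diagonal. With equal steps every increment is the
#' same; with `varstep = TRUE` each increment is proportional to the
#' relative drop in category richness, `(r_k - r_(k+1)) / r_k` (with `r_0 =
#' S`, the species count, and richness 1 at the root). Cumulative distances
#' are always rescaled so the final (root) level sits at 100.
#'
#' @param agg Aggregation tibble (`species` column then rank columns, lowest
#'   rank first) or anything accepted by [validate_aggregation()].
#' @param varstep Use variable step lengths proportional to richness drops.
#' @param check Drop uninformative ranks (all-distinct or all-identical).
#' @return A `tax_steps` object: kept rank names (plus `"root"`),
#'   increments, cumulative distances (last = 100), species ids, and the
#'   integer label codes used by the block kernel.
#' @export
compute_steps <- function(agg, varstep = FALSE, check = TRUE) {
  lab <- agg_matrix(agg)
  S <- nrow(lab)
  codes <- apply(lab, 2, function(col) match(col, unique(col)))
  if (S == 1) codes <- matrix(codes, nrow = 1, dimnames = list(NULL, colnames(lab)))
  rich <- apply(codes, 2, max)
  keep <- if (check) rich > 1 & rich < S else rep(TRUE, length(rich))
  if (!any(keep)) {
    rlang::abort("no informative taxonomic levels (all ranks dropped by check)")
  }
  codes <- codes[, keep, drop = FALSE]
  rich <- rich[keep]
  ord <- order(-rich) # stable: equal counts keep input (low -> high) order
  codes <- codes[, ord, drop = FALSE]
  rich <- rich[ord]
  K <- length(rich)
  raw <- if (varstep) {
    -diff(c(S, rich, 1)) / c(S, rich)
  } else {
    rep(1, K + 1)
  }
  if (any(raw < 0)) {
    rlang::abort("category richness must not increase towards the root")
  }
  if (any(raw == 0)) {
    rlang::warn("zero-length taxonomic steps (degenerate ranks kept)")
  }
  cum <- cumsum(raw)
  scale <- 100 / cum[K + 1]
  structure(
    list(kept_rank_names = c(colnames(codes), "root"),
         increments = unname(raw * scale),
         cumulative = unname(cum * scale),
         scale_max = 100,
         richness = rich,
         S = S,
         varstep = varstep,
         check = check,
         species_ids = rownames(lab),
         codes = codes),
    class = "tax_steps"
  )
}

#' @export
print.tax_steps <- function(x, ...) {
  cat(sprintf("Taxonomic step lengths (%s): S = %d species\n",
              if (x$varstep) "variable" else "equal", x$S))
  print(tibble::tibble(level = x$kept_rank_names,
                       increment = x$increments,
                       cumulative = x$cumulative))
  invisible(x)
}

#' One row block of the taxonomic distance matrix
#'
#' Computes rows `rows` of the S-by-S matrix omega directly from the label
#' codes; memory use is one block, never the full matrix. Concatenating
#' blocks of any size reproduces the dense matrix exactly.
#'
#' @param steps A [compute_steps()] result.
#' @param rows Integer species (row) indices, 1-based.
#' @return A `length(rows)` x S numeric matrix; diagonal cells inside the
#'   block are 0.
#' @export
taxa2dist_block <- function(steps, rows) {
  stopifnot(inherits(steps, "tax_steps"))
  if (length(rows) == 0) rlang::abort("empty row range")
  S <- steps$S
  if (any(rows < 1) || any(rows > S)) rlang::abort("row index out of range")
  inc <- steps$increments
  codes <- steps$codes
  W <- matrix(inc[1], length(rows), S)
  for (k in seq_len(ncol(codes))) {
    W <- W + inc[k + 1] * outer(codes[rows, k], codes[, k], "!=")
  }
  W[cbind(seq_along(rows), rows)] <- 0
  rownames(W) <- steps$species_ids[rows]
  colnames(W) <- steps$species_ids
  W
}

# Rows per block so one block of an S-column double matrix stays near
# `target_bytes` (default 64 MiB).
default_block_rows <- function(S, target_bytes = 64 * 2^20) {
  max(1L, min(S, as.integer(floor(target_bytes / (8 * S)))))
}

#' Dense taxonomic distance matrix
#'
#' Assembles the full symmetric matrix from row blocks. Guarded by a memory
#' budget: above it, the matrix would not fit and the streaming index
#' pipeline ([taxondive_stream()]), which works for species pools of any
#' size, should be used instead.
#'
#' @inheritParams compute_steps
#' @param block_rows Rows per block during assembly (default ~64 MiB
#'   blocks).
#' @param max_bytes Memory budget for the dense matrix (default 2 GiB).
#' @return S x S symmetric numeric matrix with species dimnames and a
#'   `"steps"` attribute.
#' @export
taxa2dist_full <- function(agg, varstep = FALSE, check = TRUE,
                           block_rows = NULL, max_bytes = 2^31) {
  lab <- agg_matrix(agg)
  if (nrow(lab) == 1) { # a single species: no pairs, trivially zero
    return(matrix(0, 1, 1, dimnames = list(rownames(lab), rownames(lab))))
  }
  steps <- compute_steps(agg, varstep = varstep, check = check)
  S <- steps$S
  if (8 * S^2 > max_bytes) {
    rlang::abort(sprintf(
      paste0("dense omega needs %.1f GiB (> budget %.1f GiB); use the ",
             "streaming pipeline taxondive_stream(), which handles input ",
             "data of any size"),
      8 * S^2 / 2^30, max_bytes / 2^30))
  }
  if (is.null(block_rows)) block_rows <- default_block_rows(S)
  out <- matrix(0, S, S, dimnames = list(steps$species_ids, steps$species_ids))
  start <- 1L
  while (start <= S) {
    rows <- start:min(start + block_rows - 1L, S)
    out[rows, ] <- taxa2dist_block(steps, rows)
    start <- start + block_rows
  }
  attr(out, "steps") <- steps
  out
}
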