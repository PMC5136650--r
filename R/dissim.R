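# Dissimilarity kernels and the condensed-form contract shared by all tests.
#
# Pairwise dissimilarities live in condensed form: the n(n-1)/2 vector of
# upper-triangle values with pair (i, j), i < j (1-based), at index
# (i-1)(2n-i)/2 + (j-i). This is the same lexicographic order used by
# stats::dist, so condensed objects subclass "dist" and interoperate with
# the rest of the ecosystem; square matrices exist only at I/O boundaries.

new_cond_dist <- function(values, labels, metric) {
  n <- length(labels)
  if (length(values) != n * (n - 1) / 2) {
    rlang::abort("condensed vector length must be n(n-1)/2")
  }
  structure(as.double(values), Size = n, Labels = labels, Diag = FALSE,
            Upper = FALSE, method = metric,
            class = c("cond_dist", "dist"))
}

cond_labels <- function(d) attr(d, "Labels")
cond_size <- function(d) attr(d, "Size")

#' Condensed index of a sample pair
#'
#' Maps a 1-based pair `i < j` of `n` items to its index in the condensed
#' dissimilarity vector (lexicographic upper-triangle order, the
#' `stats::dist` convention), and back.
#'
#' @param i,j 1-based item indices with `i < j` (vectorised).
#' @param n Number of items.
#' @return `pair_index()`: integer condensed index in `1:(n(n-1)/2)`.
#' @examples
#' pair_index(1, 2, 4) # 1
#' pair_of(6, 4)       # pair (3, 4)
#' @export
pair_index <- function(i, j, n) {
  if (any(i >= j) || any(i < 1) || any(j > n)) {
    rlang::abort("need 1 <= i < j <= n")
  }
  as.integer((i - 1) * (2 * n - i) / 2 + (j - i))
}

#' @rdname pair_index
#' @param k Condensed index in `1:(n(n-1)/2)` (vectorised).
#' @return `pair_of()`: a two-column matrix of pairs `(i, j)`.
#' @export
pair_of <- function(k, n) {
  npairs <- n * (n - 1) / 2
  if (any(k < 1) || any(k > npairs)) rlang::abort("index out of range")
  cum <- cumsum(n - seq_len(n - 1)) # pairs with first index <= i
  i <- findInterval(k - 0.5, c(0, cum))
  j <- k - c(0, cum)[i] + i
  cbind(i = as.integer(i), j = as.integer(j))
}

# First/second member of every condensed pair, in condensed order.
condensed_pairs <- function(n) {
  first <- rep.int(seq_len(n - 1), (n - 1):1)
  second <- sequence((n - 1):1) + first
  list(i = first, j = second)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_k - v_k| / sum (u_k + v_k)` over species `k`, in
#' `[0, 1]`. Undefined (and an error) when a pair of samples is jointly
#' all-zero.
#'
#' @param comm Community data: a tibble whose first column holds sample ids
#'   and remaining numeric columns species abundances, or a numeric matrix
#'   with sample rownames.
#' @return A condensed dissimilarity (`cond_dist`, subclassing `dist`).
#' @examples
#' comm <- tibble::tibble(sample = c("s1", "s2"), spA = c(3, 1), spB = c(1, 1))
#' bray_curtis(comm)
#' @export
bray_curtis <- function(comm) {
  x <- comm_matrix(comm)
  if (nrow(x) < 2) rlang::abort("need at least 2 samples")
  totals <- rowSums(x)
  pr <- condensed_pairs(nrow(x))
  den <- totals[pr$i] + totals[pr$j]
  if (any(den == 0)) {
    rlang::abort("Bray-Curtis undefined: a pair of samples is jointly all-zero")
  }
  num <- as.vector(stats::dist(x, method = "manhattan"))
  new_cond_dist(num / den, rownames(x), "bray-curtis")
}

#' Euclidean distance on scaled environmental variables
#'
#' Each selected column is centred and divided by its sample standard
#' deviation (n - 1 denominator) before pairwise Euclidean distances are
#' taken.
#'
#' @param env Environmental data: tibble with a sample-id first column and
#'   numeric variable columns, or a numeric matrix with rownames.
#' @param columns Variable names to use (default: all).
#' @return A condensed dissimilarity (`cond_dist`).
#' @export
euclidean_scaled <- function(env, columns = NULL) {
  z <- env_matrix(env)
  if (!is.null(columns)) {
    missing <- setdiff(columns, colnames(z))
    if (length(missing)) {
      rlang::abort(paste0("unknown variables: ", toString(missing)))
    }
    z <- z[, columns, drop = FALSE]
  }
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(z)[which(sds == 0 | is.na(sds))]
    rlang::abort(paste0("zero-variance variable(s): ", toString(bad)))
  }
  zs <- scale(z, center = TRUE, scale = sds)
  new_cond_dist(as.vector(stats::dist(zs)), rownames(z), "euclidean")
}

#' Midranks
#'
#' Average (mid-) ranks for ties; ranks always sum to `m(m+1)/2`. The single
#' tie convention used throughout (ANOSIM ranks, Spearman correlation).
#'
#' @param values Non-empty numeric vector.
#' @return Numeric rank vector.
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0) rlang::abort("`values` must be non-empty")
  rank(values, ties.method = "average")
}

#' @export
print.cond_dist <- function(x, ...) {
  cat(sprintf("Condensed %s dissimilarity: %d samples, %d pairs\n",
              attr(x, "method"), cond_size(x), length(x)))
  NextMethod()
}

#' Tidy a condensed dissimilarity into pair rows
#'
#' @param x A `cond_dist`.
#' @param ... Unused.
#' @return Tibble with `item1`, `item2`, `value` in condensed order.
#' @importFrom tibble as_tibble
#' @method as_tibble cond_dist
#' @export
as_tibble.cond_dist <- function(x, ...) {
  pr <- condensed_pairs(cond_size(x))
  labs <- cond_labels(x)
  tibble::tibble(item1 = labs[pr$i], item2 = labs[pr$j],
                 value = as.double(x))
}
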