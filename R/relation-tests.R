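# Matrix-correlation tests (Mantel, partial Mantel) and the BioEnv best
# -subset search for environmental variables.

check_same_samples <- function(dx, dy, what = "dissimilarity matrices") {
  if (attr(dx, "Size") != attr(dy, "Size")) {
    rlang::abort(sprintf("%s must cover the same samples", what))
  }
  lx <- attr(dx, "Labels")
  ly <- attr(dy, "Labels")
  if (!is.null(lx) && !is.null(ly) && !identical(lx, ly)) {
    rlang::abort(sprintf("%s must share the same label order", what))
  }
}

# Condensed index map: entry [i, j] is the condensed index of pair {i, j}.
cond_index_matrix <- function(n) {
  m <- matrix(0L, n, n)
  pr <- condensed_pairs(n)
  k <- seq_along(pr$i)
  m[cbind(pr$i, pr$j)] <- k
  m[cbind(pr$j, pr$i)] <- k
  m
}

mantel_cor <- function(wx, wy) {
  if (stats::sd(wx) == 0 || stats::sd(wy) == 0) {
    rlang::abort("zero variance in a dissimilarity vector")
  }
  stats::cor(wx, wy)
}

#' Mantel test between two dissimilarity matrices
#'
#' The Mantel statistic `r` is the (Pearson, or Spearman via midranks)
#' correlation between corresponding entries of two condensed
#' dissimilarities. The null distribution permutes the samples (rows and
#' columns, simultaneously) of the first matrix.
#'
#' @param dx,dy Condensed dissimilarities over the same samples in the same
#'   order.
#' @param method `"pearson"` (default) or `"spearman"` (midranks).
#' @inheritParams anosim_test
#' @return An `eco_mantel` object.
#' @export
mantel_test <- function(dx, dy, method = c("pearson", "spearman"),
                        nperm = 999, seed = 1, workers = 1,
                        chunk_size = NULL) {
  method <- match.arg(method)
  check_same_samples(dx, dy)
  n <- attr(dx, "Size")
  wx <- if (method == "spearman") rank_with_ties(as.double(dx)) else as.double(dx)
  wy <- if (method == "spearman") rank_with_ties(as.double(dy)) else as.double(dy)
  r_obs <- mantel_cor(wx, wy)
  kmat <- cond_index_matrix(n)
  lt <- which(lower.tri(kmat))
  stat <- function(p) {
    # permuting samples of dx permutes its condensed entries; midranks
    # travel with the values, so the working vector permutes directly
    kp <- kmat[p, p][lt]
    mantel_cor(wx[kp], wy)
  }
  plan <- chunk_plan(nperm, chunk_size, seed)
  perm <- run_permutations(r_obs,
                           function(rng, idx) stat(rng$shuffle(n)),
                           plan, workers)
  structure(
    list(statistic = r_obs, method = method, partial = FALSE,
         perm = perm, n = n, nperm = nperm, seed = seed),
    class = "eco_mantel"
  )
}

#' Partial Mantel test
#'
#' Correlation between `dx` and `dy` controlling for a third matrix `dz`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. The
#' permutation permutes the samples of `dx` only, recomputing `r_xy` and
#' `r_xz` while `r_yz` stays fixed.
#'
#' @inheritParams mantel_test
#' @param dz Condensed dissimilarity to partial out.
#' @return An `eco_mantel` object with `partial = TRUE`.
#' @export
mantel_partial <- function(dx, dy, dz, method = c("pearson", "spearman"),
                           nperm = 999, seed = 1, workers = 1,
                           chunk_size = NULL) {
  method <- match.arg(method)
  check_same_samples(dx, dy)
  check_same_samples(dx, dz)
  n <- attr(dx, "Size")
  rk <- function(v) if (method == "spearman") rank_with_ties(v) else v
  wx <- rk(as.double(dx)); wy <- rk(as.double(dy)); wz <- rk(as.double(dz))
  partial_r <- function(vx) {
    r_xy <- mantel_cor(vx, wy)
    r_xz <- mantel_cor(vx, wz)
    r_yz <- mantel_cor(wy, wz)
    num <- r_xy - r_xz * r_yz
    den2 <- (1 - r_xz^2) * (1 - r_yz^2)
    if (den2 <= 0) {
      # dy == dz makes the numerator vanish too: the partial is 0, not
      # undefined; any other perfect controlling correlation is an error
      if (abs(num) <= 1e-12) return(0)
      rlang::abort("partial Mantel undefined: a controlling correlation is +/-1")
    }
    num / sqrt(den2)
  }
  r_obs <- partial_r(wx)
  kmat <- cond_index_matrix(n)
  lt <- which(lower.tri(kmat))
  plan <- chunk_plan(nperm, chunk_size, seed)
  perm <- run_permutations(
    r_obs,
    function(rng, idx) {
      p <- rng$shuffle(n)
      partial_r(wx[kmat[p, p][lt]])
    },
    plan, workers
  )
  structure(
    list(statistic = r_obs, method = method, partial = TRUE,
         perm = perm, n = n, nperm = nperm, seed = seed),
    class = "eco_mantel"
  )
}

#' @export
print.eco_mantel <- function(x, ...) {
  cat(sprintf("%sMantel (%s): r = %.4f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial " else "", x$method, x$statistic,
              x$perm$p_value, x$perm$nperm))
  invisible(x)
}

#' BioEnv: best environmental-variable subset
#'
#' Exhaustive search over all non-empty variable subsets up to `max_size`:
#' for each subset, Euclidean distances of the scaled variables are
#' rank-correlated (Spearman) with the community dissimilarities; the
#' subset with maximum correlation wins. Subset evaluation is split into
#' chunks (optionally across workers); the result is identical for any
#' chunk layout. More workers than variables brings no benefit, so that
#' configuration only triggers a warning.
#'
#' @param comm_dist Condensed community dissimilarity (e.g.
#'   [bray_curtis()]), or a community tibble (Bray-Curtis is computed).
#' @param env Environmental tibble (`sample` column + numeric variables).
#' @param max_size Largest subset size (default: all variables).
#' @param workers Parallel workers over subset chunks.
#' @param chunk_size Subsets per chunk (default 64).
#' @param max_vars Hard cap on the number of variables for exhaustive
#'   search (default 15); raise deliberately for bigger searches.
#' @return An `eco_bioenv` object: per-size best subsets, the overall best,
#'   and the per-subset correlation table.
#' @export
bioenv_search <- function(comm_dist, env, max_size = NULL, workers = 1,
                          chunk_size = NULL, max_vars = 15) {
  if (is.data.frame(comm_dist)) comm_dist <- bray_curtis(comm_dist)
  env <- validate_env(env)
  env <- align_by_sample(
    tibble::tibble(sample = attr(comm_dist, "Labels")), env)
  z <- env_matrix(env)
  p <- ncol(z)
  if (p > max_vars) {
    rlang::abort(sprintf(
      "%d variables exceed the exhaustive-search cap (%d); raise `max_vars`",
      p, max_vars))
  }
  if (is.null(max_size)) max_size <- p
  if (max_size < 1 || max_size > p) {
    rlang::abort("`max_size` must lie in [1, number of variables]")
  }
  if (workers > p) {
    rlang::warn(sprintf(
      "using %d workers for %d variables: extra workers are not useful",
      workers, p))
  }
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    rlang::abort(paste0("zero-variance variable(s): ",
                        toString(colnames(z)[sds == 0 | is.na(sds)])))
  }
  zs <- scale(z, center = TRUE, scale = sds)
  pr <- condensed_pairs(nrow(zs))
  # per-variable squared condensed distances; subset distances are sums
  d2 <- (zs[pr$i, , drop = FALSE] - zs[pr$j, , drop = FALSE])^2
  ry <- rank_with_ties(as.double(comm_dist))
  subsets <- unlist(
    lapply(seq_len(max_size),
           function(k) utils::combn(p, k, simplify = FALSE)),
    recursive = FALSE
  )
  rho_of <- function(cols) {
    d <- sqrt(rowSums(d2[, cols, drop = FALSE]))
    stats::cor(rank_with_ties(d), ry)
  }
  if (is.null(chunk_size)) chunk_size <- 64
  chunk_id <- ceiling(seq_along(subsets) / chunk_size)
  chunks <- split(subsets, chunk_id)
  eval_chunk <- function(ch) vapply(ch, rho_of, numeric(1))
  rhos <- if (workers > 1 && length(chunks) > 1 &&
              .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(chunks, eval_chunk, mc.cores = workers),
           use.names = FALSE)
  } else {
    unlist(lapply(chunks, eval_chunk), use.names = FALSE)
  }
  all_tab <- tibble::tibble(
    size = vapply(subsets, length, integer(1)),
    variables = vapply(subsets, function(s) {
      paste(colnames(z)[s], collapse = "+")
    }, character(1)),
    rho = rhos
  )
  by_size <- all_tab |>
    dplyr::group_by(.data$size) |>
    dplyr::slice_max(.data$rho, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best <- by_size[which.max(by_size$rho), ]
  structure(
    list(by_size = by_size, best = best, all = all_tab,
         n_evaluated = length(subsets), n_vars = p, max_size = max_size),
    class = "eco_bioenv"
  )
}

#' @export
print.eco_bioenv <- function(x, ...) {
  cat(sprintf("BioEnv: %d subsets of %d variables evaluated\n",
              x$n_evaluated, x$n_vars))
  print(x$by_size)
  cat(sprintf("Best: {%s}, rho = %.4f\n", x$best$variables, x$best$rho))
  invisible(x)
}
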