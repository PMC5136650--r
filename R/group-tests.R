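# Grouped community tests with permutation significance: ANOSIM, one-way
# PERMANOVA (pseudo-F on a distance matrix) and SIMPER. All of them permute
# sample labels through the chunked engine, so p-values are reproducible
# and invariant to workers and chunk layout.

# Accept groups as a tibble (sample column + level column) or a plain
# vector, aligned against the dissimilarity labels.
resolve_groups <- function(groups, labels, column = NULL) {
  if (is.data.frame(groups)) {
    ref <- tibble::tibble(sample = labels)
    groups <- align_by_sample(ref, groups)
    col <- column %||% names(groups)[2]
    g <- groups[[col]]
    if (is.null(g)) rlang::abort(sprintf("no factor column '%s'", col))
  } else {
    if (!is.null(names(groups)) && all(labels %in% names(groups))) {
      g <- groups[labels]
    } else {
      if (length(groups) != length(labels)) {
        rlang::abort("`groups` length must match the number of samples")
      }
      g <- groups
    }
  }
  factor(as.character(g))
}

check_grouping <- function(g, need_within = TRUE) {
  sizes <- table(g)
  if (length(sizes) < 2) {
    rlang::abort("need at least 2 groups")
  }
  if (need_within && all(sizes < 2)) {
    rlang::abort("no within-group pair: every group has a single sample")
  }
  sizes
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities are larger than
#' within-group ones. With midranks `r` of all `M = n(n-1)/2`
#' dissimilarities, `R = (mean between-group rank - mean within-group rank)
#' / (M/2)`, in `[-1, 1]`. Significance comes from permuting the group
#' labels.
#'
#' @param dist A condensed dissimilarity (`cond_dist` or `dist`).
#' @param groups Grouping: a factor tibble (`sample`, level) or a vector
#'   aligned with the dissimilarity labels.
#' @param nperm Number of label permutations.
#' @param seed Master seed for the permutation streams.
#' @param workers Parallel workers for the permutation chunks.
#' @param chunk_size Permutations per chunk (layout does not affect
#'   results).
#' @param column Factor column name when `groups` is a tibble.
#' @return An `eco_anosim` object; see [tidy()] / [glance()].
#' @export
anosim_test <- function(dist, groups, nperm = 999, seed = 1, workers = 1,
                        chunk_size = NULL, column = NULL) {
  n <- attr(dist, "Size")
  if (is.null(n) || n < 4) rlang::abort("need a dissimilarity over >= 4 samples")
  g <- resolve_groups(groups, attr(dist, "Labels") %||% as.character(seq_len(n)),
                      column)
  check_grouping(g)
  pr <- condensed_pairs(n)
  r <- rank_with_ties(as.double(dist))
  half_m <- length(r) / 2
  gi <- as.integer(g)
  stat <- function(gg) {
    same <- gg[pr$i] == gg[pr$j]
    (mean(r[!same]) - mean(r[same])) / half_m
  }
  observed <- stat(gi)
  plan <- chunk_plan(nperm, chunk_size, seed)
  perm <- run_permutations(observed,
                           function(rng, idx) stat(gi[rng$shuffle(n)]),
                           plan, workers)
  structure(
    list(statistic = observed, perm = perm, n = n,
         group_sizes = table(g), nperm = nperm, seed = seed),
    class = "eco_anosim"
  )
}

#' @export
print.eco_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$perm$p_value, x$perm$nperm))
  invisible(x)
}

#' One-way PERMANOVA (pseudo-F on a distance matrix)
#'
#' Partitions the total sum of squared dissimilarities,
#' `SS_total = sum d_ij^2 / n`, into a between-group part and
#' `SS_within = sum_g (1/n_g) sum_(i<j in g) d_ij^2`;
#' `F = (SS_between/(a-1)) / (SS_within/(n-a))`. When every within-group
#' distance is zero the pseudo-F is reported as `Inf` and permuted
#' statistics that are also infinite count as exceedances.
#'
#' @inheritParams anosim_test
#' @return An `eco_permanova` object with a term table (`df`, `SS`, `MS`,
#'   pseudo-F, `R2`) and the permutation result.
#' @export
permanova_oneway <- function(dist, groups, nperm = 999, seed = 1,
                             workers = 1, chunk_size = NULL, column = NULL) {
  n <- attr(dist, "Size")
  if (is.null(n) || n < 3) rlang::abort("need a dissimilarity over >= 3 samples")
  g <- resolve_groups(groups, attr(dist, "Labels") %||% as.character(seq_len(n)),
                      column)
  check_grouping(g, need_within = FALSE)
  a <- nlevels(g)
  if (n == a) rlang::abort("no residual degrees of freedom (n == number of groups)")
  pr <- condensed_pairs(n)
  d2 <- as.double(dist)^2
  ss_total <- sum(d2) / n
  gi <- as.integer(g)
  sizes <- tabulate(gi, nbins = a)
  f_of <- function(gg) {
    same <- gg[pr$i] == gg[pr$j]
    ss_within <- sum(d2[same] / sizes[gg[pr$i[same]]])
    ss_between <- ss_total - ss_within
    f <- (ss_between / (a - 1)) / (ss_within / (n - a))
    if (is.nan(f)) f <- Inf
    f
  }
  same <- gi[pr$i] == gi[pr$j]
  ss_within <- sum(d2[same] / sizes[gi[pr$i[same]]])
  ss_between <- ss_total - ss_within
  f_obs <- f_of(gi)
  plan <- chunk_plan(nperm, chunk_size, seed)
  perm <- run_permutations(f_obs,
                           function(rng, idx) f_of(gi[rng$shuffle(n)]),
                           plan, workers)
  table <- tibble::tibble(
    term = c("factor", "residual", "total"),
    df = c(a - 1, n - a, n - 1),
    SS = c(ss_between, ss_within, ss_total),
    MS = c(ss_between / (a - 1), ss_within / (n - a), NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    R2 = c(ss_between / ss_total, ss_within / ss_total, 1)
  )
  structure(
    list(table = table, statistic = f_obs, perm = perm, n = n,
         nperm = nperm, seed = seed),
    class = "eco_permanova"
  )
}

#' @export
print.eco_permanova <- function(x, ...) {
  cat(sprintf("One-way PERMANOVA: pseudo-F = %s, p = %.4g (%d permutations)\n",
              format(x$statistic, digits = 6), x$perm$p_value, x$perm$nperm))
  print(x$table)
  invisible(x)
}

# Average per-species contribution to between-group Bray-Curtis
# dissimilarity for one pair of groups. Returns a list with the per-pair
# contribution matrix only when `keep_pairs`.
simper_pair_avg <- function(x, ia, ib, keep_pairs = FALSE) {
  nb <- length(ib)
  totals <- rowSums(x)
  avg <- numeric(ncol(x))
  pairs <- if (keep_pairs) {
    matrix(0, length(ia) * nb, ncol(x),
           dimnames = list(NULL, colnames(x)))
  }
  row <- 0L
  for (u in ia) {
    contrib <- abs(x[ib, , drop = FALSE] -
                     matrix(x[u, ], nb, ncol(x), byrow = TRUE))
    contrib <- contrib / (totals[ib] + totals[u])
    avg <- avg + colSums(contrib)
    if (keep_pairs) {
      pairs[row + seq_len(nb), ] <- contrib
      row <- row + nb
    }
  }
  list(avg = unname(avg) / (length(ia) * nb), pairs = pairs)
}

#' SIMPER: species contributions to between-group dissimilarity
#'
#' For every between-group sample pair `(u, v)`, species `k` contributes
#' `|u_k - v_k| / sum_l (u_l + v_l)` to their Bray-Curtis dissimilarity;
#' contributions are averaged over pairs, so per group pair they sum to the
#' average between-group dissimilarity. Contributions are reported on the
#' 0-1 dissimilarity scale. Per-species permutation p-values are the
#' fraction of label permutations whose average contribution is at least
#' the observed one.
#'
#' @param comm Community tibble or matrix (samples x species).
#' @inheritParams anosim_test
#' @return An `eco_simper` object: one contribution table per group pair
#'   (`species`, `average`, `sd`, `ratio`, `cumulative`, `p_value`) plus
#'   the overall average between-group dissimilarity.
#' @export
simper_contrib <- function(comm, groups, nperm = 999, seed = 1, workers = 1,
                           chunk_size = NULL, column = NULL) {
  x <- comm_matrix(comm)
  g <- resolve_groups(groups, rownames(x), column)
  check_grouping(g, need_within = FALSE)
  if (any(rowSums(x) == 0)) {
    rlang::abort("Bray-Curtis undefined: a sample is all-zero")
  }
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  gi <- as.integer(g)
  observed_tabs <- lapply(pairs, function(pp) {
    res <- simper_pair_avg(x, which(g == pp[1]), which(g == pp[2]),
                           keep_pairs = TRUE)
    sds <- apply(res$pairs, 2, stats::sd)
    if (nrow(res$pairs) == 1) sds <- rep(NA_real_, ncol(x))
    list(avg = res$avg, sd = sds)
  })
  observed_vec <- unlist(lapply(observed_tabs, `[[`, "avg"))
  stat <- function(gg) {
    unlist(lapply(pairs, function(pp) {
      simper_pair_avg(x, which(gg == match(pp[1], lev)),
                      which(gg == match(pp[2], lev)))$avg
    }))
  }
  plan <- chunk_plan(nperm, chunk_size, seed)
  perm <- run_permutations(observed_vec,
                           function(rng, idx) stat(gi[rng$shuffle(length(gi))]),
                           plan, workers)
  p_split <- split(perm$p_value,
                   rep(seq_along(pairs), each = ncol(x)))
  tables <- purrr::map2(observed_tabs, p_split, function(ot, pv) {
    ord <- order(ot$avg, decreasing = TRUE)
    total <- sum(ot$avg)
    tibble::tibble(
      species = colnames(x)[ord],
      average = ot$avg[ord],
      sd = ot$sd[ord],
      ratio = ot$avg[ord] / ot$sd[ord],
      cumulative = cumsum(ot$avg[ord]) / total,
      p_value = pv[ord]
    )
  })
  names(tables) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  overall <- vapply(observed_tabs, function(ot) sum(ot$avg), numeric(1))
  names(overall) <- names(tables)
  structure(
    list(tables = tables, overall = overall, perm = perm,
         nperm = nperm, seed = seed),
    class = "eco_simper"
  )
}

#' @export
print.eco_simper <- function(x, ...) {
  for (nm in names(x$tables)) {
    cat(sprintf("SIMPER %s: average between-group dissimilarity %.4f\n",
                nm, x$overall[[nm]]))
    print(utils::head(x$tables[[nm]], 10))
  }
  invisible(x)
}
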