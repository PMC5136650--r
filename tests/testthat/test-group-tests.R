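test_that("ANOSIM hits its exact extremes", {
  # perfect separation: all within-pair dissimilarities below all between
  d <- cond_from(c(0.1, 0.8, 0.9, 0.85, 0.95, 0.2), 4)
  res <- anosim_test(d, c("g1", "g1", "g2", "g2"), nperm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # all dissimilarities equal: midranks equalize, R = 0
  flat <- cond_from(rep(0.5, 6), 4)
  expect_equal(anosim_test(flat, c("g1", "g1", "g2", "g2"), nperm = 0,
                           seed = 1)$statistic, 0)
  expect_error(anosim_test(d, rep("g1", 4), nperm = 9, seed = 1),
               "2 groups")
})

test_that("ANOSIM p matches exhaustive relabeling on the toy design", {
  d <- cond_from(c(0.1, 0.8, 0.9, 0.85, 0.95, 0.2), 4)
  g <- c("g1", "g1", "g2", "g2")
  pr <- ecostream:::condensed_pairs(4)
  r <- rank_with_ties(as.double(d))
  stat <- function(gg) {
    same <- gg[pr$i] == gg[pr$j]
    (mean(r[!same]) - mean(r[same])) / (length(r) / 2)
  }
  all_orders <- expand.grid(rep(list(1:4), 4))
  all_orders <- all_orders[apply(all_orders, 1, function(p) {
    length(unique(p)) == 4
  }), ]
  stats <- apply(all_orders, 1, function(p) stat(g[unlist(p)]))
  frac <- mean(stats >= 1)
  expect_equal(frac, 1 / 3) # 8 of 24 orderings keep the split
  res <- anosim_test(d, g, nperm = 9999, seed = 11)
  expect_lt(abs(res$perm$p_value - frac), 0.03)
})

test_that("ANOSIM R is invariant to monotone transforms of the dissimilarity", {
  fx <- random_fixture(71, S = 25, n = 10, effect = 0.8)
  d <- bray_curtis(fx$community)
  d2 <- cond_from(exp(3 * as.double(d)) - 1, attr(d, "Size"),
                  attr(d, "Labels"))
  a1 <- anosim_test(d, fx$groups, nperm = 99, seed = 2)
  a2 <- anosim_test(d2, fx$groups, nperm = 99, seed = 2)
  expect_identical(a1$statistic, a2$statistic)
  expect_identical(a1$perm$exceed, a2$perm$exceed)
})

test_that("ANOSIM agrees with vegan on statistic and grouping handling", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(72, S = 30, n = 12, effect = 0.6)
  d <- bray_curtis(fx$community)
  ours <- anosim_test(d, fx$groups, nperm = 0, seed = 1)
  veg <- vegan::anosim(stats::as.dist(d), grouping = fx$groups$group,
                       permutations = 0)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-12)
})

test_that("PERMANOVA reproduces classical one-way ANOVA on univariate data", {
  y <- c(0, 1, 2, 3)
  g <- c("a", "a", "b", "b")
  d <- cond_from(as.double(stats::dist(y)), 4)
  res <- permanova_oneway(d, g, nperm = 99, seed = 1)
  expect_equal(res$statistic, 8)
  expect_equal(res$table$R2[1], 0.8)
  # family of random univariate cases against aov()
  for (seed in 1:4) {
    rng <- perm_rng(1234, seed)
    y <- rng$unif(9)
    g <- rep(c("a", "b", "c"), each = 3)
    d <- cond_from(as.double(stats::dist(y)), 9)
    ours <- permanova_oneway(d, g, nperm = 0, seed = 1)
    classical <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(ours$statistic, classical[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(ours$table$SS[1:2], classical[["Sum Sq"]],
                 tolerance = 1e-10)
  }
})

test_that("PERMANOVA partitions sums of squares and matches a dense oracle", {
  fx <- random_fixture(73, S = 20, n = 12, effect = 0.5)
  env <- gen_env(fx$spec)
  z <- ecostream:::env_matrix(env)
  d <- euclidean_scaled(env)
  g <- factor(rep(c("a", "b", "c"), c(4, 4, 4)))
  res <- permanova_oneway(d, g, nperm = 199, seed = 3)
  tab <- res$table
  expect_equal(tab$SS[1] + tab$SS[2], tab$SS[3], tolerance = 1e-9)
  expect_equal(tab$df[1] + tab$df[2], 11)
  expect_true(tab$R2[1] >= 0 && tab$R2[1] <= 1)
  # McArdle-Anderson hat-matrix oracle on the Gower-centred matrix
  n <- 12
  dm <- as.matrix(d)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  f_oracle <- (sum(diag(H %*% G %*% H)) / 2) /
    (sum(diag((diag(n) - H) %*% G %*% (diag(n) - H))) / 9)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan::adonis2 and flags infinite F", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(74, S = 25, n = 10, effect = 0.7)
  d <- bray_curtis(fx$community)
  ours <- permanova_oneway(d, fx$groups, nperm = 0, seed = 1)
  df <- data.frame(group = fx$groups$group)
  veg <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = 2)
  expect_equal(ours$statistic, veg$F[1], tolerance = 1e-10)
  expect_equal(ours$table$R2[1], veg$R2[1], tolerance = 1e-10)

  # duplicated identical profiles: zero within-group distance, F = Inf
  dup <- tibble::tibble(sample = paste0("s", 1:4),
                        a = c(1, 1, 5, 5), b = c(2, 2, 0, 0))
  ddup <- bray_curtis(dup)
  res <- permanova_oneway(ddup, c("g1", "g1", "g2", "g2"), nperm = 99,
                          seed = 1)
  expect_identical(res$statistic, Inf)
  expect_true(res$perm$p_value > 0 && res$perm$p_value <= 1)
})

test_that("SIMPER contributions match hand arithmetic and sum to the average", {
  comm <- tibble::tibble(sample = c("u", "v"), a = c(3, 1), b = c(1, 1))
  res <- simper_contrib(comm, c("G1", "G2"), nperm = 9, seed = 1)
  tab <- res$tables[[1]]
  expect_equal(tab$average[tab$species == "a"], 1 / 3)
  expect_equal(tab$average[tab$species == "b"], 0)
  expect_equal(unname(res$overall), 1 / 3) # == Bray-Curtis of the pair

  ident <- tibble::tibble(sample = c("u", "v"), a = c(2, 2), b = c(3, 3))
  res2 <- simper_contrib(ident, c("G1", "G2"), nperm = 0, seed = 1)
  expect_equal(res2$tables[[1]]$average, c(0, 0))
})

test_that("SIMPER decomposes mean between-group Bray-Curtis on fixtures", {
  fx <- random_fixture(75, S = 15, n = 8, effect = 0.5)
  res <- simper_contrib(fx$community, fx$groups, nperm = 19, seed = 4)
  d <- bray_curtis(fx$community)
  m <- as.matrix(d)
  g <- fx$groups$group
  between <- m[g == "A", g == "B"]
  expect_equal(unname(res$overall), mean(between), tolerance = 1e-12)
  tab <- res$tables[[1]]
  expect_equal(sum(tab$average), mean(between), tolerance = 1e-12)
  expect_true(all(diff(tab$cumulative) >= -1e-12))
  expect_equal(tab$cumulative[nrow(tab)], 1, tolerance = 1e-12)
  # double-loop oracle for one species
  x <- ecostream:::comm_matrix(fx$community)
  ia <- which(g == "A")
  ib <- which(g == "B")
  sp <- tab$species[1]
  oracle <- mean(vapply(ia, function(u) {
    vapply(ib, function(v) {
      abs(x[u, sp] - x[v, sp]) / sum(x[u, ] + x[v, ])
    }, numeric(1))
  }, numeric(length(ib))))
  expect_equal(tab$average[1], oracle, tolerance = 1e-12)
})

test_that("SIMPER agrees with vegan's average contributions", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(76, S = 12, n = 8, effect = 0.5)
  x <- ecostream:::comm_matrix(fx$community)
  ours <- simper_contrib(fx$community, fx$groups, nperm = 0, seed = 1)
  veg <- summary(vegan::simper(x, fx$groups$group,
                               permutations = 0))[[1]]
  tab <- ours$tables[[1]]
  expect_equal(tab$average, veg[tab$species, "average"], tolerance = 1e-10,
               ignore_attr = TRUE)
})
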