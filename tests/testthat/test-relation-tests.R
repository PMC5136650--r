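test_that("Mantel r matches hand arithmetic and identity", {
  dx <- cond_from(c(1, 2, 4), 3)
  dy <- cond_from(c(1, 3, 4), 3)
  expect_equal(mantel_test(dx, dy, nperm = 0, seed = 1)$statistic, 13 / 14)
  expect_equal(mantel_test(dx, dx, nperm = 0, seed = 1)$statistic, 1)
  expect_error(mantel_test(dx, cond_from(rep(1, 3), 3), nperm = 0, seed = 1),
               "zero variance")
  expect_error(mantel_test(dx, cond_from(c(1, 2, 3, 4, 5, 6), 4),
                           nperm = 0, seed = 1), "same samples")
})

test_that("Mantel r is symmetric, shift-invariant and relabeling-consistent", {
  fx <- random_fixture(81, S = 20, n = 9)
  env <- gen_env(fx$spec)
  dx <- bray_curtis(fx$community)
  dy <- euclidean_scaled(env)
  r_xy <- mantel_test(dx, dy, nperm = 0, seed = 1)$statistic
  r_yx <- mantel_test(dy, dx, nperm = 0, seed = 1)$statistic
  expect_equal(r_xy, r_yx, tolerance = 1e-12)
  shift <- cond_from(as.double(dy) + 5, 9, attr(dx, "Labels"))
  expect_equal(mantel_test(dx, shift, nperm = 0, seed = 1)$statistic, r_xy,
               tolerance = 1e-12)
  # applying one permutation to the samples of both matrices leaves r fixed
  p <- perm_rng(5, 0)$shuffle(9)
  km <- ecostream:::cond_index_matrix(9)
  lt <- which(lower.tri(km))
  permute_both <- function(d) {
    cond_from(as.double(d)[km[p, p][lt]], 9, attr(d, "Labels")[p])
  }
  r_perm <- mantel_test(permute_both(dx), permute_both(dy),
                        nperm = 0, seed = 1)$statistic
  expect_equal(r_perm, r_xy, tolerance = 1e-12)
})

test_that("Spearman Mantel ignores monotone transforms and matches vegan", {
  fx <- random_fixture(82, S = 20, n = 8)
  env <- gen_env(fx$spec)
  dx <- bray_curtis(fx$community)
  dy <- euclidean_scaled(env)
  r1 <- mantel_test(dx, dy, method = "spearman", nperm = 0, seed = 1)$statistic
  warped <- cond_from(log1p(as.double(dy))^3, 8, attr(dy, "Labels"))
  r2 <- mantel_test(dx, warped, method = "spearman", nperm = 0,
                    seed = 1)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  veg_p <- vegan::mantel(stats::as.dist(dx), stats::as.dist(dy),
                         permutations = 0)
  expect_equal(mantel_test(dx, dy, nperm = 0, seed = 1)$statistic,
               unname(veg_p$statistic), tolerance = 1e-12)
  veg_s <- vegan::mantel(stats::as.dist(dx), stats::as.dist(dy),
                         method = "spearman", permutations = 0)
  expect_equal(r1, unname(veg_s$statistic), tolerance = 1e-12)
})

test_that("partial Mantel reduces correctly and matches the residual oracle", {
  fx <- random_fixture(83, S = 18, n = 6)
  env <- gen_env(fx$spec)
  dx <- bray_curtis(fx$community)
  dy <- euclidean_scaled(env, columns = c("env01", "env02"))
  dz <- euclidean_scaled(env, columns = c("env03", "env04"))
  res <- mantel_partial(dx, dy, dz, nperm = 0, seed = 1)
  # residual-regression oracle
  vx <- as.double(dx); vy <- as.double(dy); vz <- as.double(dz)
  rx <- stats::residuals(stats::lm(vx ~ vz))
  ry <- stats::residuals(stats::lm(vy ~ vz))
  expect_equal(res$statistic, stats::cor(rx, ry), tolerance = 1e-12)
  # controlling for dy itself sends the numerator to zero
  self <- mantel_partial(dx, dy, dy, nperm = 0, seed = 1)
  expect_equal(self$statistic, 0, tolerance = 1e-12)
  # controlling for dx itself: r_xz = 1 and r_yz = r_xy, so the numerator
  # vanishes identically and the degenerate partial is 0
  expect_equal(mantel_partial(dx, dy, dx, nperm = 0, seed = 1)$statistic, 0)
})

test_that("BioEnv enumerates subsets exhaustively and finds planted drivers", {
  fx <- random_fixture(84, S = 20, n = 10)
  env <- gen_env(fx$spec)[1:4] # sample + env01..env03
  d <- bray_curtis(fx$community)
  res <- bioenv_search(d, env, max_size = 3)
  expect_equal(res$n_evaluated, 7) # 2^3 - 1
  expect_equal(nrow(res$by_size), 3)
  expect_equal(max(res$by_size$rho), res$best$rho)

  # a variable whose scaled distances share midranks with the community
  # dissimilarity is a perfect singleton
  planted_env <- tibble::tibble(
    sample = attr(d, "Labels"),
    magic = stats::cmdscale(stats::as.dist(d), k = 1)[, 1],
    noise = perm_rng(1, 1)$unif(10)
  )
  res2 <- bioenv_search(d, planted_env, max_size = 1)
  expect_equal(res2$best$variables, "magic")

  env_const <- tibble::tibble(sample = attr(d, "Labels"), c = rep(1, 10))
  expect_error(bioenv_search(d, env_const), "zero-variance.*c")
  expect_error(bioenv_search(d, env, max_size = 9), "max_size")
})

test_that("BioEnv is invariant to chunking and warns about excess workers", {
  fx <- random_fixture(85, S = 25, n = 10)
  env <- gen_env(fx$spec)
  d <- bray_curtis(fx$community)
  base <- bioenv_search(d, env, chunk_size = 1e6)
  expect_equal(base$n_evaluated, 2^6 - 1)
  for (cs in c(1, 5, 17)) {
    got <- bioenv_search(d, env, chunk_size = cs)
    expect_identical(got$all, base$all)
    expect_identical(got$best, base$best)
  }
  got_w <- bioenv_search(d, env, workers = 2, chunk_size = 8)
  expect_identical(got_w$all, base$all)
  expect_warning(bioenv_search(d, env[1:3], workers = 5),
                 "not useful")
})

test_that("BioEnv agrees with vegan on the best subset", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(86, S = 25, n = 12, coupling = 0.9, effect = 1)
  env <- gen_env(fx$spec, gen_community(fx$spec)$community)
  x <- ecostream:::comm_matrix(fx$community)
  ours <- bioenv_search(bray_curtis(fx$community), env)
  z <- as.data.frame(ecostream:::env_matrix(env))
  veg <- vegan::bioenv(x, z, index = "bray")
  veg_best <- veg$models[[which.max(vapply(veg$models, `[[`, numeric(1),
                                           "est"))]]
  expect_equal(ours$best$variables,
               paste(names(z)[veg_best$best], collapse = "+"))
  expect_equal(ours$best$rho, veg_best$est, tolerance = 1e-10)
})
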