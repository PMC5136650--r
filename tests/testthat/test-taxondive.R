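test_that("index values match the hand-worked toy example", {
  w <- taxa2dist_full(toy_agg())
  res <- taxondive_dense(toy_comm(), w)
  row <- res$samples
  expect_equal(row$Delta, 75)
  expect_equal(row$DeltaStar, 90)
  expect_equal(row$DeltaPlus, 250 / 3, tolerance = 1e-9)
  expect_equal(row$sDeltaPlus, 250, tolerance = 1e-9)
  expect_equal(row$LambdaPlus, 5000 / 9, tolerance = 1e-9)
  expect_equal(res$EDeltaPlus, 250 / 3, tolerance = 1e-9)
})

test_that("undefined indices are NaN with a warning, not errors", {
  w <- taxa2dist_full(toy_agg())
  lonely <- tibble::tibble(sample = "s1", A = 2, B = 0, C = 0)
  expect_warning(res <- taxondive_dense(lonely, w), "undefined")
  expect_true(is.nan(res$samples$DeltaPlus))
  expect_true(is.nan(res$samples$LambdaPlus))
  expect_true(is.nan(res$samples$DeltaStar))
  single_ind <- tibble::tibble(sample = "s1", A = 1, B = 0, C = 0)
  expect_warning(res2 <- taxondive_dense(single_ind, w), "undefined")
  expect_true(is.nan(res2$samples$Delta))
})

test_that("constant distances collapse Delta+ to the constant and Lambda+ to 0", {
  w <- matrix(70, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(w) <- 0
  comm <- tibble::tibble(sample = c("s1", "s2"),
                         a = c(1, 3), b = c(2, 1), c = c(1, 0), d = c(0, 2))
  res <- taxondive_dense(comm, w)
  expect_equal(res$samples$DeltaPlus, c(70, 70))
  expect_equal(res$samples$LambdaPlus, c(0, 0), tolerance = 1e-10)
})

test_that("presence/absence abundances make DeltaStar equal DeltaPlus", {
  fx <- random_fixture(51, S = 30, n = 8)
  x <- (ecostream:::comm_matrix(fx$community) > 0) * 1
  w <- taxa2dist_full(fx$agg)
  res <- taxondive_dense(x, w)
  ok <- res$samples$richness >= 2
  expect_equal(res$samples$DeltaStar[ok], res$samples$DeltaPlus[ok],
               tolerance = 1e-12)
  expect_true(all(res$samples$Delta[ok] <= res$samples$DeltaStar[ok] + 1e-12))
})

test_that("streaming equals dense for any block size, including degenerate", {
  fx <- random_fixture(52, S = 30, n = 6)
  dense <- taxondive_dense(fx$community,
                           taxa2dist_full(fx$agg))
  for (b in c(1, 7, 30)) {
    got <- taxondive_stream(fx$community, fx$agg, block_rows = b)
    expect_tabs_equal(got$samples, dense$samples, tolerance = 1e-10)
    expect_equal(got$EDeltaPlus, dense$EDeltaPlus, tolerance = 1e-10)
  }
  # toy, block_rows = 1
  toy_stream <- taxondive_stream(toy_comm(), toy_agg(), block_rows = 1)
  expect_equal(toy_stream$samples$Delta, 75)
  expect_equal(toy_stream$accounting$n_blocks, 3)
})

test_that("streaming matches vegan's indices on a random fixture", {
  skip_if_not_installed("vegan")
  fx <- random_fixture(53, S = 45, n = 9)
  got <- taxondive_stream(fx$community, fx$agg, varstep = TRUE,
                          block_rows = 8)
  x <- ecostream:::comm_matrix(fx$community)
  veg_d <- vegan::taxa2dist(
    as.data.frame(tibble::column_to_rownames(fx$agg, "species")),
    varstep = TRUE)
  veg <- vegan::taxondive(x, veg_d)
  expect_equal(got$samples$Delta, unname(veg$D), tolerance = 1e-10)
  expect_equal(got$samples$DeltaStar, unname(veg$Dstar), tolerance = 1e-10)
  expect_equal(got$samples$DeltaPlus, unname(veg$Dplus), tolerance = 1e-10)
  expect_equal(got$samples$LambdaPlus, unname(veg$Lambda), tolerance = 1e-8)
  expect_equal(got$EDeltaPlus, veg$EDplus, tolerance = 1e-10)
})

test_that("streaming species matching is strict and by name", {
  fx <- random_fixture(54, S = 10, n = 4)
  comm2 <- fx$community
  names(comm2)[2] <- "intruder"
  expect_error(taxondive_stream(comm2, fx$agg), "identical")
  # shuffled community columns are re-aligned by name, same result
  shuffled <- fx$community[, c(1, sample(2:11))]
  a <- taxondive_stream(fx$community, fx$agg)
  b <- taxondive_stream(shuffled, fx$agg)
  expect_tabs_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("omega blocks can be spilled to a store during streaming", {
  fx <- random_fixture(55, S = 20, n = 4)
  dir <- withr::local_tempdir()
  store <- block_store("directory", dir)
  res <- taxondive_stream(fx$community, fx$agg, block_rows = 6,
                          store = store)
  expect_equal(res$accounting$store$n_put, res$accounting$n_blocks)
  # reassembled spilled blocks equal the dense matrix bitwise
  w <- do.call(rbind, lapply(bs_keys(store), function(k) bs_get(store, k)))
  expect_identical(w, bare_matrix(taxa2dist_full(fx$agg)))
})

test_that("funnel means are unbiased and exhaustive draws are exact", {
  # toy pool: subsets of size 2 have Delta+ in {50, 100, 100}
  ft <- funnel(toy_agg(), sizes = 2, exhaustive = TRUE)
  expect_equal(ft$mean, 250 / 3, tolerance = 1e-9)
  expect_equal(ft$n_draws, 3)

  fx <- random_fixture(56, S = 30)
  ft2 <- funnel(fx$agg, sizes = c(5, 10, 30), n_draws = 400,
                master_seed = 9)
  expect_true(all(ft2$lower <= ft2$mean & ft2$mean <= ft2$upper))
  expect_true(all(ft2$mean >= 0 & ft2$mean <= 100))
  ed <- attr(ft2, "EDeltaPlus")
  # whole pool: exact expectation, zero-width bounds
  expect_equal(ft2$mean[3], ed, tolerance = 1e-12)
  expect_equal(ft2$lower[3], ft2$upper[3])
  # random subsets: Delta+ unbiased for EDelta+ (within 3 SE, approximated
  # by the spread of the draws themselves)
  spread <- (ft2$upper - ft2$lower) / (2 * 1.96) / sqrt(ft2$n_draws)
  expect_true(all(abs(ft2$mean - ed) <= pmax(3 * spread, 1e-9)))
  expect_error(funnel(fx$agg, sizes = 1), "\\[2, S\\]")
  # reproducible given the seed
  ft3 <- funnel(fx$agg, sizes = c(5, 10, 30), n_draws = 400,
                master_seed = 9)
  expect_identical(as.data.frame(ft2), as.data.frame(ft3))
})
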