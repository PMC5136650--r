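# Shared toy objects and small generators used across the suite.

# Three species: A and B congeneric, C in another genus of the same family.
# omega = (A,B) 50, (A,C) 100, (B,C) 100.
toy_agg <- function() {
  tibble::tibble(species = c("A", "B", "C"),
                 genus = c("g1", "g1", "g2"),
                 family = c("f1", "f1", "f1"))
}

toy_comm <- function() {
  tibble::tibble(sample = "s1", A = 1, B = 1, C = 2)
}

# Four species exercising variable step lengths: genus richness 3,
# family richness 2.
toy_agg4 <- function() {
  tibble::tibble(species = c("A", "B", "C", "D"),
                 genus = c("g1", "g1", "g2", "g3"),
                 family = c("f1", "f1", "f1", "f2"))
}

# Condensed dissimilarity from explicit values (labels optional).
cond_from <- function(values, n, labels = NULL) {
  labels <- labels %||% paste0("s", seq_len(n))
  structure(as.double(values), Size = as.integer(n), Labels = labels,
            Diag = FALSE, Upper = FALSE, method = "external",
            class = c("cond_dist", "dist"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random community fixture with deterministic content.
random_fixture <- function(seed, S = 40, n = 10, effect = 0, ...) {
  spec <- fixture_spec(S = S, n_samples = n, effect_size = effect,
                       master_seed = seed, ...)
  c(list(spec = spec, agg = gen_aggregation(spec)), gen_community(spec))
}

# Naive double-loop Bray-Curtis oracle.
bray_oracle <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  out
}

# Oracle omega: path-length distance computed pair by pair from the label
# matrix and the step cumulative distances.
omega_oracle <- function(agg, varstep = FALSE, check = TRUE) {
  st <- compute_steps(agg, varstep = varstep, check = check)
  lab <- as.matrix(agg[-1])[, st$kept_rank_names[-length(st$kept_rank_names)],
                            drop = FALSE]
  S <- nrow(lab)
  out <- matrix(0, S, S, dimnames = list(agg[[1]], agg[[1]]))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      level <- which(lab[i, ] == lab[j, ])[1]
      out[i, j] <- if (is.na(level)) 100 else st$cumulative[level]
    }
  }
  out
}

# numeric matrix stripped of every attribute except dim
bare_matrix <- function(m) matrix(as.vector(m), nrow(m))

expect_tabs_equal <- function(a, b, tolerance = 1e-10) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
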