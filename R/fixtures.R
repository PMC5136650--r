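# Synthetic community data generator: the four input file kinds at
# controllable scale with realistic structure (nested taxonomy, zero
# -inflated log-normal abundances, an optional two-group effect and a
# plantable environmental driver). Everything is driven by the package's
# own integer-arithmetic streams, so output is deterministic for a given
# master seed on any platform. Scale names follow the species-pool sizes
# used throughout the package's benchmarks: small 1,700, medium 16,900,
# large 42,300, xl 168,931 (tests default to far smaller pools).

.FIXTURE_SCALES <- c(tiny = 50, small = 1700, medium = 16900,
                     large = 42300, xl = 168931)

# Stream sub-indices reserved per generator role, so the three generators
# draw from disjoint streams of the same master seed.
.STREAM_AGG <- 101
.STREAM_COMM <- 202
.STREAM_ENV <- 303
.STREAM_AFFECTED <- 404

#' Specification of a synthetic dataset
#'
#' @param S Species-pool size.
#' @param n_samples Number of samples (split into two groups A/B).
#' @param rank_richness Category counts per taxonomic rank, lowest rank
#'   first; strictly decreasing and every count `< S` (a rank with `S`
#'   categories would be all-distinct and carry no information).
#' @param meanlog,sdlog Log-normal abundance parameters.
#' @param zero_inflation Probability in `[0, 1)` that a cell is zero.
#' @param effect_size Between-group shift (log scale) applied to the
#'   affected species in group B; 0 makes the two groups exchangeable (the
#'   null fixture).
#' @param affected_frac Fraction of species carrying the group effect.
#' @param n_env Number of environmental variables.
#' @param coupling Strength in `[0, 1]` tying the planted environmental
#'   variable to the community's group axis (1 = deterministic monotone
#'   function of it).
#' @param master_seed Integer master seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(S = 50, n_samples = 10,
                         rank_richness = NULL,
                         meanlog = 1, sdlog = 1, zero_inflation = 0.3,
                         effect_size = 0, affected_frac = 0.3,
                         n_env = 6, coupling = 0, master_seed = 1) {
  if (is.null(rank_richness)) {
    rank_richness <- unique(pmax(2, pmin(S - 1, round(S / c(4, 16, 64)))))
    rank_richness <- rank_richness[rank_richness < S]
  }
  spec <- structure(
    list(S = as.integer(S), n_samples = as.integer(n_samples),
         rank_richness = as.integer(rank_richness),
         meanlog = meanlog, sdlog = sdlog,
         zero_inflation = zero_inflation,
         effect_size = effect_size, affected_frac = affected_frac,
         n_env = as.integer(n_env), coupling = coupling,
         master_seed = as.double(master_seed)),
    class = "fixture_spec"
  )
  rr <- spec$rank_richness
  if (length(rr) < 1) rlang::abort("need at least one taxonomic rank")
  if (any(rr >= S)) {
    rlang::abort("infeasible richness profile: a rank with >= S categories")
  }
  if (any(rr < 1) || any(diff(rr) >= 0)) {
    rlang::abort("rank_richness must be strictly decreasing (lowest rank first)")
  }
  if (zero_inflation < 0 || zero_inflation >= 1) {
    rlang::abort("zero_inflation must lie in [0, 1)")
  }
  if (coupling < 0 || coupling > 1) rlang::abort("coupling must lie in [0, 1]")
  spec
}

.RANK_NAMES <- c("genus", "family", "order", "class", "phylum", "kingdom")

# Standard normals from a stream, via Box-Muller (platform-stable).
stream_normals <- function(rng, k) {
  m <- ceiling(k / 2)
  u1 <- rng$unif(m)
  u2 <- rng$unif(m)
  z <- c(sqrt(-2 * log(u1)) * cos(2 * pi * u2),
         sqrt(-2 * log(u1)) * sin(2 * pi * u2))
  z[seq_len(k)]
}

# The species subset carrying the group effect; shared by the community and
# environment generators so the planted variable tracks the right axis.
affected_species <- function(spec) {
  m <- max(1L, round(spec$affected_frac * spec$S))
  rng <- perm_rng(spec$master_seed, .STREAM_AFFECTED)
  sort(rng$sample_subset(spec$S, m))
}

#' Generate a hierarchical classification table
#'
#' Random nested assignment honouring the requested category counts per
#' rank exactly: each category at a rank is assigned one parent at the next
#' rank (surjectively, so every parent is used), and species are assigned
#' surjectively to the lowest rank.
#'
#' @param spec A [fixture_spec()].
#' @return Aggregation tibble (`species` + one column per rank, lowest
#'   first) that passes [validate_aggregation()].
#' @export
gen_aggregation <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- perm_rng(spec$master_seed, .STREAM_AGG)
  S <- spec$S
  rr <- spec$rank_richness
  K <- length(rr)
  rank_names <- .RANK_NAMES[seq_len(K)]
  if (K > length(.RANK_NAMES)) {
    rank_names <- paste0("rank", seq_len(K))
  }
  # parent category of each category at rank k (k < K)
  parents <- vector("list", K)
  for (k in seq_len(K - 1)) {
    np <- rr[k + 1]
    base <- seq_len(np) # surjective base
    extra <- if (rr[k] > np) floor(rng$unif(rr[k] - np) * np) + 1 else integer(0)
    parents[[k]] <- c(base, extra)[rng$shuffle(rr[k])]
  }
  base <- seq_len(rr[1])
  extra <- if (S > rr[1]) floor(rng$unif(S - rr[1]) * rr[1]) + 1 else integer(0)
  sp_cat <- c(base, extra)[rng$shuffle(S)]
  labels <- matrix("", S, K)
  cat_id <- sp_cat
  for (k in seq_len(K)) {
    labels[, k] <- sprintf("%s%04d", substr(rank_names[k], 1, 2), cat_id)
    if (k < K) cat_id <- parents[[k]][cat_id]
  }
  out <- tibble::tibble(species = sprintf("sp%06d", seq_len(S)))
  for (k in seq_len(K)) out[[rank_names[k]]] <- labels[, k]
  validate_aggregation(out)
}

#' Generate a community matrix and its two-group factor
#'
#' Abundances are zero-inflated log-normal. Group B shifts the log-mean of
#' the affected species by `effect_size`; with `effect_size = 0` the groups
#' are exchangeable.
#'
#' @param spec A [fixture_spec()].
#' @return List with `community` (tibble: `sample` + species columns) and
#'   `groups` (tibble: `sample`, `group`).
#' @export
gen_community <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- perm_rng(spec$master_seed, .STREAM_COMM)
  S <- spec$S
  n <- spec$n_samples
  group <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  affected <- affected_species(spec)
  meanlog <- matrix(spec$meanlog, n, S)
  if (spec$effect_size != 0) {
    meanlog[group == "B", affected] <-
      meanlog[group == "B", affected] + spec$effect_size
  }
  z <- matrix(stream_normals(rng, n * S), n, S)
  u <- matrix(rng$unif(n * S), n, S)
  x <- ifelse(u < spec$zero_inflation, 0,
              exp(meanlog + spec$sdlog * z))
  # keep Bray-Curtis defined: no all-zero samples
  for (i in which(rowSums(x) == 0)) {
    j <- floor(rng$unif(1) * S) + 1
    x[i, j] <- exp(spec$meanlog)
  }
  sample_ids <- sprintf("st%03d", seq_len(n))
  comm <- tibble::as_tibble(as.data.frame(x))
  names(comm) <- sprintf("sp%06d", seq_len(S))
  comm <- dplyr::bind_cols(tibble::tibble(sample = sample_ids), comm)
  list(community = validate_community(comm),
       groups = tibble::tibble(sample = sample_ids, group = group))
}

#' Generate environmental variables, optionally coupled to a community
#'
#' Variables are independent standard normals except the planted one
#' (`env01`), which, when `coupling > 0` and a community is supplied, is a
#' monotone function of the samples' position along the group axis (the
#' standardized total log-abundance of the affected species) mixed with
#' noise; `coupling = 1` makes it a deterministic monotone transform, so a
#' BioEnv search has a known best singleton.
#'
#' @param spec A [fixture_spec()].
#' @param community Optional community tibble from [gen_community()].
#' @return Environmental tibble (`sample` + `env01..`); attribute
#'   `"planted"` names the coupled variable.
#' @export
gen_env <- function(spec, community = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- perm_rng(spec$master_seed, .STREAM_ENV)
  n <- spec$n_samples
  p <- spec$n_env
  vals <- matrix(stream_normals(rng, n * p), n, p)
  if (spec$coupling > 0 && !is.null(community)) {
    x <- comm_matrix(community)
    score <- rowSums(log1p(x[, affected_species(spec), drop = FALSE]))
    score <- as.vector(scale(score))
    vals[, 1] <- spec$coupling * score +
      sqrt(1 - spec$coupling^2) * vals[, 1]
  }
  env <- tibble::as_tibble(as.data.frame(vals))
  names(env) <- sprintf("env%02d", seq_len(p))
  env <- dplyr::bind_cols(
    tibble::tibble(sample = sprintf("st%03d", seq_len(n))), env)
  structure(validate_env(env), planted = "env01")
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the four CSV input files (aggregation, community, factor,
#' environment) for a named scale or a custom spec.
#'
#' @param dir Output directory (created if needed).
#' @param scale One of `"tiny"`, `"small"`, `"medium"`, `"large"`, `"xl"`
#'   (species pools of 50 / 1,700 / 16,900 / 42,300 / 168,931), ignored
#'   when `spec` is given.
#' @param spec Optional [fixture_spec()] overriding `scale`.
#' @param master_seed Seed used when building the spec from `scale`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixtures <- function(dir, scale = "tiny", spec = NULL,
                           master_seed = 1) {
  if (is.null(spec)) {
    if (!scale %in% names(.FIXTURE_SCALES)) {
      rlang::abort(paste0("unknown scale '", scale, "'"))
    }
    spec <- fixture_spec(S = .FIXTURE_SCALES[[scale]],
                         master_seed = master_seed)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  agg <- gen_aggregation(spec)
  cf <- gen_community(spec)
  env <- gen_env(spec, cf$community)
  paths <- c(
    aggregation = file.path(dir, "aggregation.csv"),
    community = file.path(dir, "community.csv"),
    factors = file.path(dir, "factors.csv"),
    env = file.path(dir, "environment.csv")
  )
  write_table_csv(agg, paths[["aggregation"]])
  write_table_csv(cf$community, paths[["community"]])
  write_table_csv(cf$groups, paths[["factors"]])
  write_table_csv(env, paths[["env"]])
  invisible(paths)
}
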