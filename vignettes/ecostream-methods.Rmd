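---
title: "Methods: streaming taxonomic distinctness and chunk-invariant permutation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streaming taxonomic distinctness and chunk-invariant permutation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecostream)
```

## What the package computes

ecostream implements the community-ecology statistics that dominate routine
multivariate analysis of species-by-sample data — taxonomic
diversity/distinctness indices, ANOSIM, one-way PERMANOVA, Mantel and
partial Mantel tests, SIMPER and the BioEnv subset search — with two
engineering guarantees that matter once datasets stop being small:

1. **Streaming distance computation.** The species-by-species taxonomic
   distance matrix ω is produced and consumed one row block at a time, so
   the indices can be computed for species pools whose dense matrix would
   not fit in memory (an S = 170,000 pool would need ~230 GB of doubles).
2. **Chunk- and worker-invariant permutation testing.** Every permutation
   index owns a private random stream derived from `(master_seed,
   perm_index)`. The chunk layout and the worker pool decide only *where*
   a permutation is evaluated, never *what* it draws, so results are
   bitwise identical for any parallel configuration.

## Taxonomic distances and the Δ family

Given a classification table (species × ranks, lowest rank first), the
distance between two species is the cumulative path length to the lowest
taxonomic level at which they agree, scaled so that species that meet only
at the implicit root are 100 apart. With `check = TRUE` (default), ranks
at which all species are distinct or all identical are dropped: they
cannot separate any pair. The species level itself is the first step, so
ω = 0 only on the diagonal.

Equal step lengths give each level the same increment. With
`varstep = TRUE` the increment of each level is proportional to the
relative drop in category richness, `(r_k − r_{k+1})/r_k` (with `r_0 = S`
and richness 1 at the root), then rescaled to a cumulative maximum of 100.
Ties between ranks with equal category counts keep their input order — a
deterministic choice; note that some other implementations reverse tied
columns, so exact numerical parity with any particular third-party release
is not claimed when ties occur.

Per sample with abundances *x*, total individuals *N* and present-species
richness *S_s*, over species pairs *i < j*:

- Δ (taxonomic diversity) `= Σ ω_ij x_i x_j / (N(N−1)/2)`
- Δ\* (taxonomic distinctness) `= Σ ω_ij x_i x_j / Σ x_i x_j`
- Δ⁺ (average taxonomic distinctness, presence/absence)
  `= Σ_present ω_ij / (S_s(S_s−1)/2)`
- Λ⁺ (variation in taxonomic distinctness)
  `= Σ_present (ω_ij − Δ⁺)² / (S_s(S_s−1)/2)`
- sΔ⁺ `= S_s·Δ⁺`, and EΔ⁺ = mean ω over the full pool.

Samples where a denominator vanishes (fewer than two individuals for Δ,
fewer than two present species for Δ⁺/Λ⁺) get `NaN` with a warning rather
than an error, so batch runs over many samples keep going. The Σ x_i x_j
denominator of Δ\* uses *i < j* pairs only, consistent with the numerator.

### Streaming evaluation

All five indices are sums over species pairs, so they decompose over row
blocks of ω. `taxondive_stream()` walks the blocks once and keeps only

- `Σ ω_ij x_i x_j`, `Σ_present ω_ij`, `Σ_present ω_ij²` per sample, and
- the pool totals for EΔ⁺,

i.e. a handful of numbers per sample next to a single resident block.
`Σ x_i x_j` needs no ω at all (`(N² − Σx²)/2`). Block size defaults to
about 64 MiB of doubles (`block_rows ≈ 64 MiB / 8S`) and is configurable;
the output is block-size independent up to floating-point accumulation
order, which the tests bound at 10⁻¹⁰ relative. Blocks can additionally be
spilled to a `block_store()` (in-memory or one binary file per block with
a JSON shape sidecar) when the distances themselves need to be kept; the
store's accounting (`max_block_bytes`) is how the tests assert that the
dense matrix is never resident.

### Funnel expectations

`funnel()` draws random m-species subsets of the pool and reports the mean
and empirical 2.5 %/97.5 % quantiles of Δ⁺ per subsample size. Monte-Carlo
quantiles were chosen over a closed-form variance because they are
assumption-free and directly testable (the whole-pool draw must equal EΔ⁺
with zero width; subset means must be unbiased); a closed-form funnel is a
possible extension, not implemented. Draw counts default to 999 per size.

## The permutation engine

Permutation indices `0 … nperm−1` are partitioned into chunks
(`chunk_plan()`). Each index derives its own stream: the master seed and
the index are mixed through Lehmer steps (multiplier 48271, modulus
2³¹−1) and an integer XOR, after which the stream is an ordinary Lehmer
generator. All arithmetic stays below 2⁵³ in doubles, so the streams are
exactly reproducible on any platform, and R's global RNG is never touched.
Seeding per permutation (rather than per chunk) is what makes results
independent of the chunk layout and worker count; it is a deliberately
stronger contract than merely summing correct per-chunk counts.

P-values use the `(1 + #{permuted ≥ observed}) / (1 + nperm)` convention:
ties count as exceedances and p is never 0. An infinite observed statistic
(PERMANOVA with zero within-group sum of squares) is kept as `Inf`;
permuted statistics that are also infinite count as exceedances under the
same `≥` rule. Workers are forked processes (`parallel::mclapply`); on
platforms without fork the engine falls back to serial evaluation with
identical results, which is the point of the invariance contract.

Under a true null the estimator is slightly conservative
(super-uniform); the suite checks a rejection rate ≤ 0.07 at α = 0.05
over 500 simulated nulls, and the acceptance script recomputes null
rejection rates for all four tests over 200 replicates with 199
permutations each, so p-values resolve to multiples of 1/200 and the
nominal rejection probability is exactly 0.05.

## The tests themselves

- **ANOSIM**: midranks of all n(n−1)/2 dissimilarities;
  `R = (mean between-group rank − mean within-group rank) / (M/2)`.
  Rank-based, hence invariant to monotone transforms of the
  dissimilarity.
- **One-way PERMANOVA**: `SS_total = Σ d²/n`,
  `SS_within = Σ_g (1/n_g) Σ_{pairs in g} d²`, pseudo-F from the usual
  mean squares. On univariate Euclidean data this reduces exactly to the
  classical ANOVA F (a test pins F = 8, R² = 0.8 on `y = 0,1,2,3` with
  groups 1,1,2,2). Scope is deliberately one-way: single factor, label
  permutation; multi-factor designs with sequential sums of squares are
  out of scope.
- **SIMPER**: for each between-group sample pair, species k contributes
  `|u_k − v_k| / Σ_l (u_l + v_l)`; contributions average over pairs and
  sum, per group pair, to the average between-group Bray-Curtis
  dissimilarity (checked to 10⁻¹²). Contributions are reported on the 0-1
  scale (`--percent` in the CLI rescales the display). The permutation
  keeps sample profiles intact and permutes group labels only. Raw
  abundances are used; no transformation is applied implicitly.
- **Mantel / partial Mantel**: Pearson (default) or Spearman-on-midranks
  correlation of two condensed matrices; the null permutes rows and
  columns of the first matrix simultaneously. The partial statistic is the
  usual first-order formula; the degenerate case dz = dy (or dx), where
  both numerator and denominator vanish, returns 0 rather than erroring,
  since the limit is well-defined there; a genuinely perfect controlling
  correlation with a non-vanishing numerator is an error.
- **BioEnv**: exhaustive search over all non-empty subsets of the scaled
  environmental variables up to `max_size`, Spearman correlation against
  the community dissimilarity (Spearman only, as is conventional for this
  procedure; Mantel offers both). Subset evaluation is chunked over the
  flattened lexicographic subset list — a finer unit than chunking by
  variable, which balances load as subset counts grow combinatorially —
  and a hard cap of 15 variables (overridable) guards the 2^p blow-up.
  More workers than variables triggers a warning, since the extra workers
  cannot help.

## Data contracts

Condensed dissimilarities use the lexicographic upper-triangle order (pair
(i,j), i<j at index `(i−1)(2n−i)/2 + (j−i)`), the same convention as
`stats::dist`, and subclass `dist`, so they flow into the wider ecosystem
unchanged. CSV I/O is strict: one dialect (comma, header row, first column
labels, `.` decimal), duplicate names, negative abundances and missing
cells are errors, species matching between community and classification is
by exact name with no silent intersection, and orientation is fixed
(samples × species) with an explicit `--transpose` flag instead of
guessing. Numeric cells are written with 17 significant digits and parsed
with `strtod`, so write-read cycles are bitwise stable.

## The synthetic data generator

`fixture_spec()` fixes the study conditions; the generators are
deterministic given `master_seed` (they draw from the package's own
integer-arithmetic streams, so output is identical across platforms).

- **Classification**: random nested assignment that honours the requested
  category counts per rank exactly (surjective parent maps), defaulting to
  richness ratios of roughly S/4, S/16, S/64. Scale names follow the pool
  sizes used in the package's benchmarks (small 1,700; medium 16,900;
  large 42,300; xl 168,931); tests run at S ≤ 300 plus one 20,000-species
  scale check, sizes chosen to exercise the machinery while keeping the
  default suite around a minute.
- **Abundances**: zero-inflated log-normal (default 30 % zeros,
  `sdlog = 1`) — the canonical skewed-abundance caricature. Two groups of
  samples; group B shifts the log-mean of a random species subset
  (`affected_frac`, default 30 %) by `effect_size`. `effect_size = 0`
  makes the groups exchangeable, which is the null fixture used for
  calibration runs.
- **Environment**: independent standard normals, except one planted
  variable that, at `coupling = 1`, is a deterministic monotone function
  of the samples' position along the group axis (standardized total
  log-abundance of the affected species), giving BioEnv a known correct
  answer.

What the generator does *not* emulate: real taxonomies' uneven clade
sizes, spatial or temporal autocorrelation between samples, compositional
(relative-abundance) constraints, and detection error. Passing tests
demonstrate algorithmic correctness and calibration under exchangeable
nulls — not robustness to those real-data features.

## Numerical choices and edge cases

- Sample standard deviation (n−1) for scaling environmental variables.
- Midranks for all ties, everywhere a rank is taken.
- Blocked accumulation order is fixed (blocks in row order), so repeated
  runs are bitwise reproducible; streaming vs dense agreement is bounded
  at 10⁻¹⁰ relative rather than exact because summation order differs.
- `taxa2dist_full()` refuses pools whose dense matrix exceeds a 2 GiB
  budget and points to the streaming path instead.
- A single-species pool has no pairs: its dense matrix is the 1×1 zero
  matrix and the step machinery is bypassed.
- Rank-richness ties keep input order (see above); `check = FALSE` keeps
  all ranks but retains the species-level base step, so increments stay
  positive; degenerate ranks then produce a warning, not an error.
- The CLI requires an explicit `--seed` for every permutation subcommand —
  no silent clock seeding — and always writes a JSON manifest (flags,
  seed, package and R versions, wall time) next to the results.

## Known limitations

One-way designs only for PERMANOVA; Bray-Curtis and scaled Euclidean are
the only built-in dissimilarities (external square CSVs are accepted
everywhere a distance is consumed); BioEnv is exhaustive (no stepwise
heuristics) and capped by default at 15 variables; funnels are
Monte-Carlo, not closed-form; permutations are always sampled, never the
exhaustive set, even for tiny designs where enumeration would be feasible.
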