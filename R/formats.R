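# Strict readers/writers for the four CSV input dialects and the square
# distance-matrix output. One dialect only: comma separator, header row,
# first column = row labels, UTF-8, '.' decimal. Orientation is fixed
# (rows = samples, columns = species); no guessing, no NA cells.

first_col_labels <- function(df, what) {
  labs <- as.character(df[[1]])
  if (anyNA(labs) || any(labs == "")) {
    rlang::abort(sprintf("empty %s label in first column", what))
  }
  if (anyDuplicated(labs)) {
    dup <- labs[duplicated(labs)][1]
    rlang::abort(sprintf("duplicate %s id: '%s'", what, dup))
  }
  labs
}

# Everything is read as character first; numeric columns are converted with
# strtod (correctly rounded), so a file written with 17 significant digits
# reads back to bitwise-identical doubles.
read_label_csv <- function(path, numeric_cells) {
  df <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal",
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(df) < 2) rlang::abort("file needs a label column plus data columns")
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  if (numeric_cells) {
    for (j in 2:ncol(df)) {
      raw <- df[[j]]
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & !is.na(raw) & raw != "")
      if (length(bad)) {
        rlang::abort(sprintf("non-numeric cell '%s' in column '%s'",
                             raw[bad[1]], names(df)[j]))
      }
      df[[j]] <- num
    }
  }
  df
}

#' Read a community (abundance) matrix CSV
#'
#' Header row = species names, first column = sample names, cells =
#' non-negative abundances (counts or biomass). Validation is strict:
#' duplicate names, negative, missing or non-numeric cells are errors.
#'
#' @param path CSV file path.
#' @param transpose If `TRUE` the file is stored species-by-samples and is
#'   transposed after reading.
#' @return Tibble: `sample` column then one numeric column per species.
#' @export
read_community_csv <- function(path, transpose = FALSE) {
  df <- read_label_csv(path, TRUE)
  names(df)[1] <- "sample"
  if (transpose) {
    labs <- first_col_labels(df, "row")
    m <- t(as.matrix(df[-1]))
    colnames(m) <- labs
    df <- tibble::as_tibble(m, rownames = "sample")
  }
  validate_community(df)
}

#' Validate a community tibble
#'
#' @param comm Tibble with `sample` first column and numeric species columns.
#' @return `comm`, invisibly classed as validated (returned visibly).
#' @export
validate_community <- function(comm) {
  stopifnot(is.data.frame(comm))
  first_col_labels(comm, "sample")
  sp <- names(comm)[-1]
  if (anyDuplicated(sp)) {
    rlang::abort(sprintf("duplicate species id: '%s'", sp[duplicated(sp)][1]))
  }
  if (length(sp) < 2) rlang::abort("need at least 2 species")
  if (nrow(comm) < 1) rlang::abort("need at least 1 sample")
  vals <- as.matrix(comm[-1])
  if (!is.numeric(vals) || anyNA(vals)) {
    rlang::abort("community cells must all be numeric and non-missing")
  }
  if (any(vals < 0)) rlang::abort("negative abundance cell")
  tibble::as_tibble(comm)
}

# Tibble (label col first) or matrix -> numeric matrix with rownames.
comm_matrix <- function(comm) {
  if (is.matrix(comm)) {
    storage.mode(comm) <- "double"
    return(comm)
  }
  comm <- validate_community(comm)
  m <- as.matrix(comm[-1])
  rownames(m) <- as.character(comm[[1]])
  m
}

env_matrix <- function(env) {
  if (is.matrix(env)) {
    storage.mode(env) <- "double"
    return(env)
  }
  env <- validate_env(env)
  m <- as.matrix(env[-1])
  rownames(m) <- as.character(env[[1]])
  m
}

#' Read a taxonomic classification aggregation CSV
#'
#' First column = species name; subsequent columns = taxonomic ranks ordered
#' lowest to highest (e.g. genus, family, ...). The classification must be
#' hierarchical: species sharing a category at one rank must share the
#' categories at all higher ranks.
#'
#' @param path CSV file path.
#' @return Tibble: `species` column then one character column per rank.
#' @export
read_aggregation_csv <- function(path) {
  df <- read_label_csv(path, FALSE)
  names(df)[1] <- "species"
  validate_aggregation(df)
}

#' Validate an aggregation tibble
#'
#' @param agg Tibble with `species` first column and character rank columns.
#' @return `agg` as a validated tibble.
#' @export
validate_aggregation <- function(agg) {
  stopifnot(is.data.frame(agg))
  first_col_labels(agg, "species")
  if (ncol(agg) < 2) rlang::abort("need at least one taxonomic rank")
  lab <- as.matrix(agg[-1])
  if (anyNA(lab) || any(lab == "")) {
    rlang::abort("empty classification cell")
  }
  ranks <- names(agg)[-1]
  sp <- as.character(agg[[1]])
  for (k in seq_len(ncol(lab) - 1)) {
    child <- lab[, k]
    parent <- lab[, k + 1]
    nparent <- tapply(parent, child, function(p) length(unique(p)))
    bad <- names(nparent)[nparent > 1][1]
    if (!is.na(bad)) {
      idx <- which(child == bad)
      other <- idx[parent[idx] != parent[idx[1]]][1]
      rlang::abort(sprintf(
        paste0("classification is not hierarchical: species '%s' and '%s' ",
               "share %s '%s' but differ at %s ('%s' vs '%s')"),
        sp[idx[1]], sp[other], ranks[k], bad, ranks[k + 1],
        parent[idx[1]], parent[other]))
    }
  }
  tibble::as_tibble(agg)
}

agg_matrix <- function(agg) {
  agg <- validate_aggregation(agg)
  m <- as.matrix(agg[-1])
  rownames(m) <- as.character(agg[[1]])
  m
}

#' Read a qualitative factor CSV
#'
#' First column = sample names; remaining columns = factor levels per
#' sample.
#'
#' @param path CSV file path.
#' @return Tibble: `sample` column then one character column per factor.
#' @export
read_factor_csv <- function(path) {
  df <- read_label_csv(path, FALSE)
  names(df)[1] <- "sample"
  first_col_labels(df, "sample")
  if (anyNA(as.matrix(df[-1]))) rlang::abort("missing factor level")
  tibble::as_tibble(df)
}

#' Read a quantitative environmental CSV
#'
#' First column = sample names; remaining columns = numeric environmental
#' variables. Missing cells are a load error.
#'
#' @param path CSV file path.
#' @return Tibble: `sample` column then numeric variable columns.
#' @export
read_env_csv <- function(path) {
  df <- read_label_csv(path, TRUE)
  names(df)[1] <- "sample"
  validate_env(df)
}

#' Validate an environmental tibble
#' @param env Tibble with `sample` first column and numeric columns.
#' @return `env` as a validated tibble.
#' @export
validate_env <- function(env) {
  stopifnot(is.data.frame(env))
  first_col_labels(env, "sample")
  if (ncol(env) < 2) rlang::abort("need at least one environmental variable")
  vals <- as.matrix(env[-1])
  if (!is.numeric(vals) || anyNA(vals)) {
    rlang::abort("environmental cells must all be numeric and non-missing")
  }
  tibble::as_tibble(env)
}

# 17 significant digits: enough for any double to round-trip exactly.
fmt_full_precision <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ sprintf("%.17g", .x)))
}

#' Write any label-first tibble back to CSV
#'
#' Numeric cells are written with 17 significant digits, so reading the
#' file back reproduces the doubles exactly.
#'
#' @param x Tibble with a label first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(fmt_full_precision(x), path, progress = FALSE)
  invisible(path)
}

#' Reorder a sample-keyed table to match a community's sample order
#'
#' Pure permutation: the two files must contain exactly the same sample
#' ids; a mismatch is an error listing the missing and extra ids.
#'
#' @param comm Community tibble (or any tibble whose first column is the
#'   reference sample order).
#' @param other Factor or environmental tibble keyed by sample.
#' @return `other`, reordered to `comm`'s sample order.
#' @export
align_by_sample <- function(comm, other) {
  ref <- as.character(comm[[1]])
  got <- as.character(other[[1]])
  if (!setequal(ref, got) || length(ref) != length(got)) {
    missing <- setdiff(ref, got)
    extra <- setdiff(got, ref)
    rlang::abort(paste0(
      "sample ids do not match; ",
      if (length(missing)) paste0("missing: ", toString(missing), "; ") else "",
      if (length(extra)) paste0("extra: ", toString(extra)) else ""))
  }
  other[match(ref, got), , drop = FALSE]
}

#' Write a square, labelled distance matrix CSV
#'
#' @param dist A `cond_dist`, `dist` or square symmetric matrix with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_square_dist_csv <- function(dist, path) {
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m)) rlang::abort("distance matrix must be square")
  labs <- rownames(m) %||% colnames(m)
  if (is.null(labs) || length(labs) != nrow(m)) {
    rlang::abort("distance matrix must carry one label per row")
  }
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- labs
  out <- dplyr::bind_cols(tibble::tibble(sample = labs), df)
  readr::write_csv(fmt_full_precision(out), path, progress = FALSE)
  invisible(path)
}

#' Read a square distance matrix CSV into condensed form
#'
#' @param path CSV path as written by [write_square_dist_csv()].
#' @param metric Metric tag recorded on the result.
#' @return A `cond_dist`.
#' @export
read_square_dist_csv <- function(path, metric = "external") {
  df <- read_label_csv(path, TRUE)
  labs <- first_col_labels(df, "sample")
  m <- as.matrix(df[-1])
  if (nrow(m) != ncol(m) || !identical(colnames(m), labs)) {
    rlang::abort("not a square labelled distance matrix")
  }
  if (!isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-12))) {
    rlang::abort("distance matrix is not symmetric")
  }
  new_cond_dist(m[lower.tri(m)], labs, metric)
}
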