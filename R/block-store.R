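# Keyed persistence for matrix blocks, so intermediates larger than memory
# can be spilled and re-read incrementally. Two backends share one contract:
# get(put(key, block)) is bitwise identical to block, and keys are unique.

#' Create a block store
#'
#' @param backend `"memory"` (an in-session environment) or `"directory"`
#'   (one binary file of doubles per key plus a JSON sidecar with the shape;
#'   survives the R session).
#' @param dir Directory path, required for the directory backend; created if
#'   missing.
#' @return A `block_store` object.
#' @export
block_store <- function(backend = c("memory", "directory"), dir = NULL) {
  backend <- match.arg(backend)
  if (backend == "directory") {
    if (is.null(dir)) rlang::abort("directory backend needs `dir`.")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  structure(
    list(backend = backend, dir = dir,
         blocks = new.env(hash = TRUE, parent = emptyenv()),
         stats = new.env(parent = emptyenv())),
    class = "block_store"
  )
}

store_key_path <- function(store, key) {
  file.path(store$dir, paste0(key, ".bin"))
}

#' Store a numeric block under a key
#'
#' @param store A [block_store()].
#' @param key Unique character key.
#' @param block Numeric matrix.
#' @return The store, invisibly.
#' @export
bs_put <- function(store, key, block) {
  stopifnot(inherits(store, "block_store"), is.matrix(block))
  if (key %in% bs_keys(store)) {
    rlang::abort(sprintf("key '%s' already present in block store", key))
  }
  if (store$backend == "memory") {
    assign(key, block, envir = store$blocks)
  } else {
    path <- store_key_path(store, key)
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(block), con, size = 8, endian = "little")
    jsonlite::write_json(
      list(key = key, nrow = nrow(block), ncol = ncol(block)),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  bytes <- 8 * length(block)
  st <- store$stats
  st$n_put <- (st$n_put %||% 0) + 1
  st$bytes_written <- (st$bytes_written %||% 0) + bytes
  st$max_block_bytes <- max(st$max_block_bytes %||% 0, bytes)
  invisible(store)
}

#' Retrieve a block by key
#'
#' @inheritParams bs_put
#' @return The stored matrix, bitwise identical to what was put.
#' @export
bs_get <- function(store, key) {
  stopifnot(inherits(store, "block_store"))
  if (store$backend == "memory") {
    if (!exists(key, envir = store$blocks, inherits = FALSE)) {
      rlang::abort(sprintf("key '%s' not found in block store", key))
    }
    get(key, envir = store$blocks, inherits = FALSE)
  } else {
    path <- store_key_path(store, key)
    if (!file.exists(path)) {
      rlang::abort(sprintf("key '%s' not found in block store", key))
    }
    meta <- jsonlite::read_json(paste0(path, ".json"))
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    vals <- readBin(con, "double", n = meta$nrow * meta$ncol, size = 8,
                    endian = "little")
    matrix(vals, meta$nrow, meta$ncol)
  }
}

#' List the keys held by a store
#' @inheritParams bs_put
#' @return Character vector of keys.
#' @export
bs_keys <- function(store) {
  if (store$backend == "memory") {
    ls(store$blocks)
  } else {
    sub("\\.bin$", "", basename(list.files(store$dir, pattern = "\\.bin$")))
  }
}

#' Accounting counters of a store
#' @inheritParams bs_put
#' @return List with `n_put`, `bytes_written`, `max_block_bytes`.
#' @export
bs_stats <- function(store) {
  st <- store$stats
  list(n_put = st$n_put %||% 0,
       bytes_written = st$bytes_written %||% 0,
       max_block_bytes = st$max_block_bytes %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
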