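# Minimal Zarr v2 directory-store primitives: hierarchical groups described
# by .zgroup/.zattrs JSON files and chunked N-dimensional arrays described by
# .zarray, stored as uncompressed C-order little-endian chunk files
# ("<i>.<j>" keys). Edge chunks are padded with the fill value, as the format
# requires. Every chunk READ passes through zarr_read_chunk(), which feeds the
# package-level counter used to verify the lazy-loading contract.

.sk_env <- new.env(parent = emptyenv())
.sk_env$chunk_reads <- 0L

#' Raster chunk-read instrumentation
#'
#' Every raster chunk read from a store increments a package-level counter.
#' Used to verify the lazy-loading contract: listing a store and reading its
#' non-raster content must perform zero chunk reads.
#'
#' @param reset if `TRUE`, reset the counter to zero after reading it.
#' @return The number of chunk reads since the last reset.
#' @export
chunk_read_count <- function(reset = FALSE) {
  n <- .sk_env$chunk_reads
  if (reset) .sk_env$chunk_reads <- 0L
  n
}

write_json_file <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

zarr_init_group <- function(path, attrs = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_json_file(list(zarr_format = 2L), file.path(path, ".zgroup"))
  if (!is.null(attrs)) write_json_file(attrs, file.path(path, ".zattrs"))
  invisible(path)
}

zarr_dtype_of <- function(arr) {
  if (is.integer(arr)) "<i4" else "<f8"
}

zarr_dtype_info <- function(dtype) {
  switch(dtype,
         "<i4" = list(what = integer(), size = 4L, fill = 0L),
         "<f8" = list(what = numeric(), size = 8L, fill = 0),
         stop(sprintf("unsupported dtype '%s'", dtype)))
}

default_chunks <- function(shape) {
  # chunk shape must stay >= 1 even for empty (0-extent) arrays
  pmax(1L, pmin(as.integer(shape), 256L))
}

# write an R array as a Zarr v2 array group at `path`
zarr_write_array <- function(path, arr, chunks = default_chunks(dim(arr)),
                             attrs = NULL) {
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  shape <- dim(arr)
  chunks <- as.integer(chunks)
  dtype <- zarr_dtype_of(arr)
  info <- zarr_dtype_info(dtype)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(zarr_format = 2L,
               shape = as.list(as.integer(shape)),
               chunks = as.list(chunks),
               dtype = dtype,
               compressor = NULL,
               fill_value = 0L,
               order = "C",
               filters = NULL,
               dimension_separator = ".")
  write_json_file(meta, file.path(path, ".zarray"))
  if (!is.null(attrs)) write_json_file(attrs, file.path(path, ".zattrs"))
  if (prod(shape) == 0) return(invisible(path))   # empty array: metadata only
  n_chunks <- ceiling(shape / chunks)
  grid <- do.call(expand.grid, lapply(n_chunks, function(n) seq_len(n) - 1L))
  for (r in seq_len(nrow(grid))) {
    ci <- as.integer(grid[r, ])
    idx <- lapply(seq_along(shape), function(k) {
      lo <- ci[k] * chunks[k] + 1L
      seq(lo, min(lo + chunks[k] - 1L, shape[k]))
    })
    block <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    if (any(dim(block) < chunks)) block <- pad_block(block, chunks, info$fill)
    key <- paste(ci, collapse = ".")
    con <- file(file.path(path, key), "wb")
    writeBin(as.vector(aperm(block, rev(seq_along(dim(block))))),
             con, size = info$size, endian = "little")
    close(con)
  }
  invisible(path)
}

pad_block <- function(block, chunks, fill) {
  full <- array(fill, dim = chunks)
  idx <- lapply(dim(block), seq_len)
  do.call(`[<-`, c(list(full), idx, list(block)))
}

# ---------------------------------------------------------------------------
# lazy arrays

new_lazy_array <- function(path, shape, chunks, dtype, counted = FALSE) {
  structure(list(path = path, shape = as.integer(shape),
                 chunks = as.integer(chunks), dtype = dtype,
                 counted = counted),
            class = "sk_lazy_array")
}

#' @export
dim.sk_lazy_array <- function(x) x$shape

#' @export
print.sk_lazy_array <- function(x, ...) {
  cat("<lazy array> ", paste(x$shape, collapse = " x "), " (", x$dtype,
      "), chunks ", paste(x$chunks, collapse = " x "), "\n", sep = "")
  invisible(x)
}

lazy_dim <- function(x) if (inherits(x, "sk_lazy_array")) x$shape else dim(x)

#' Materialize an array
#'
#' Returns a plain in-memory array; for lazy store-backed rasters this is the
#' point at which chunks are actually read.
#'
#' @param x an array or `sk_lazy_array`.
#' @return An R array.
#' @export
materialize <- function(x) UseMethod("materialize")

#' @export
materialize.default <- function(x) x

#' @export
materialize.sk_lazy_array <- function(x) {
  info <- zarr_dtype_info(x$dtype)
  out <- array(info$fill, dim = x$shape)
  n_chunks <- ceiling(x$shape / x$chunks)
  grid <- do.call(expand.grid, lapply(n_chunks, function(n) seq_len(n) - 1L))
  for (r in seq_len(nrow(grid))) {
    ci <- as.integer(grid[r, ])
    block <- zarr_read_chunk(x, ci)
    idx <- lapply(seq_along(x$shape), function(k) {
      lo <- ci[k] * x$chunks[k] + 1L
      seq(lo, min(lo + x$chunks[k] - 1L, x$shape[k]))
    })
    trimmed <- do.call(`[`, c(list(block), lapply(lengths(idx), seq_len),
                              list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx, list(trimmed)))
  }
  out
}

#' @export
as.array.sk_lazy_array <- function(x, ...) materialize(x)

zarr_read_chunk <- function(x, ci) {
  if (isTRUE(x$counted)) .sk_env$chunk_reads <- .sk_env$chunk_reads + 1L
  info <- zarr_dtype_info(x$dtype)
  key <- file.path(x$path, paste(ci, collapse = "."))
  n <- prod(x$chunks)
  if (!file.exists(key)) return(array(info$fill, dim = x$chunks))
  con <- file(key, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = info$what, n = n, size = info$size,
                 endian = "little")
  aperm(array(vec, dim = rev(x$chunks)), rev(seq_along(x$chunks)))
}

# open an array lazily: reads only .zarray metadata. `counted` marks raster
# payloads, whose chunk reads feed the lazy-contract counter.
zarr_open_array <- function(path, counted = FALSE) {
  meta <- read_json_file(file.path(path, ".zarray"))
  new_lazy_array(path,
                 shape = unlist(meta$shape),
                 chunks = unlist(meta$chunks),
                 dtype = meta$dtype,
                 counted = counted)
}
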