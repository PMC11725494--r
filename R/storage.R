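# Persistent store: one hierarchical Zarr-v2 directory per dataset, with
# kind groups images/, labels/, points/, shapes/, tables/ and one child group
# per element. Raster elements are chunked multiscale arrays with
# NGFF-style `multiscales` metadata (axes plus per-level scale/translation);
# the full transformation records -- including affine matrices, which core
# NGFF 0.4 has no standard encoding for -- travel in a `spatialkit` extension
# attribute that strict NGFF readers simply skip. Points and shape/obs/var
# attribute tables are columnar Parquet (categoricals preserved); polygon
# geometry is WKB; circles are typed records (never polygonized on disk).
# Sparse matrices are CSR triplets. Element writes are atomic: each element
# group is staged and renamed into place, so partial failures leave no
# half-written element.

.SK_FORMAT_VERSION <- "0.1"

raster_scale_vec <- function(level_dim, level0_dim, axes) {
  vapply(seq_along(axes), function(k) {
    if (axes[k] %in% .SK_SPATIAL_AXES) level0_dim[k] / level_dim[k] else 1
  }, numeric(1))
}

element_attrs <- function(e, kind) {
  attrs <- list(spatialkit = list(
    kind = kind,
    transformations = lapply(e$transformations, transform_to_list)))
  if (kind %in% c("image", "labels")) {
    attrs$spatialkit$axes <- as.list(e$axes)
    d0 <- lazy_dim(e$pyramid[[1]])
    attrs$multiscales <- list(list(
      version = "0.4",
      name = kind,
      axes = lapply(e$axes, function(ax)
        list(name = ax, type = if (ax == "c") "channel" else "space")),
      datasets = lapply(seq_along(e$pyramid), function(i) {
        sc <- raster_scale_vec(lazy_dim(e$pyramid[[i]]), d0, e$axes)
        list(path = as.character(i - 1L),
             coordinateTransformations = list(list(type = "scale",
                                                   scale = as.list(sc))))
      })))
  }
  attrs
}

write_points_group <- function(e, path) {
  zarr_init_group(path, element_attrs(e, "points"))
  df <- e$data
  df$`__instance_id` <- e$instance_ids
  arrow::write_parquet(df, file.path(path, "points.parquet"))
}

write_shapes_group <- function(e, path) {
  zarr_init_group(path, element_attrs(e, "shapes"))
  n <- length(e$geometries)
  type <- vapply(e$geometries, function(g) g$type, character(1))
  cx <- cy <- cz <- radius <- rep(NA_real_, n)
  wkb <- vector("list", n)
  for (i in seq_len(n)) {
    g <- e$geometries[[i]]
    if (g$type == "circle") {
      cx[i] <- g$center[["x"]]; cy[i] <- g$center[["y"]]
      if ("z" %in% names(g$center)) cz[i] <- g$center[["z"]]
      radius[i] <- g$radius
      wkb[[i]] <- raw(0)
    } else {
      wkb[[i]] <- geometry_to_wkb(g)
    }
  }
  tb <- arrow::arrow_table(
    `__instance_id` = e$instance_ids,
    type = type, cx = cx, cy = cy, cz = cz, radius = radius,
    wkb = arrow::Array$create(wkb, type = arrow::binary()))
  arrow::write_parquet(tb, file.path(path, "geometries.parquet"))
  if (!is.null(e$data) && ncol(e$data) > 0)
    arrow::write_parquet(e$data, file.path(path, "attributes.parquet"))
}

write_raster_group <- function(e, path, kind) {
  zarr_init_group(path, element_attrs(e, kind))
  for (i in seq_along(e$pyramid)) {
    zarr_write_array(file.path(path, as.character(i - 1L)),
                     materialize(e$pyramid[[i]]))
  }
}

write_matrix_node <- function(X, path) {
  if (methods::is(X, "Matrix")) {
    Xr <- as_csr(X)
    zarr_init_group(path, list(encoding = "csr_matrix",
                               shape = as.list(dim(X))))
    zarr_write_array(file.path(path, "data"), array(Xr@x, length(Xr@x)))
    zarr_write_array(file.path(path, "indices"), array(Xr@j, length(Xr@j)))
    zarr_write_array(file.path(path, "indptr"), array(Xr@p, length(Xr@p)))
  } else {
    X <- as.matrix(X)
    colnames(X) <- NULL; rownames(X) <- NULL
    zarr_write_array(path, X, attrs = list(encoding = "dense"))
  }
}

as_csr <- function(X) {
  methods::as(methods::as(methods::as(X, "RsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

read_matrix_node <- function(path) {
  if (file.exists(file.path(path, ".zarray"))) {
    return(zarr_open_array(path))          # dense; caller materializes
  }
  attrs <- read_json_file(file.path(path, ".zattrs"))
  stopifnot(identical(attrs$encoding, "csr_matrix"))
  shape <- unlist(attrs$shape)
  x <- as.numeric(materialize(zarr_open_array(file.path(path, "data"))))
  j <- as.integer(materialize(zarr_open_array(file.path(path, "indices"))))
  p <- as.integer(materialize(zarr_open_array(file.path(path, "indptr"))))
  methods::new("dgRMatrix", x = x, j = j, p = p, Dim = as.integer(shape))
}

write_table_group <- function(tab, path) {
  attrs <- list(spatialkit = list(
    kind = "table",
    region = if (is.null(tab$region)) NULL else as.list(as.character(tab$region)),
    region_key = tab$region_key,
    instance_key = tab$instance_key,
    var_names = as.list(colnames(tab$X))))
  zarr_init_group(path, attrs)
  write_matrix_node(tab$X, file.path(path, "X"))
  arrow::write_parquet(tab$obs, file.path(path, "obs.parquet"))
  arrow::write_parquet(tab$var, file.path(path, "var.parquet"))
  if (length(tab$layers)) {
    zarr_init_group(file.path(path, "layers"))
    for (ln in names(tab$layers))
      write_matrix_node(tab$layers[[ln]], file.path(path, "layers", ln))
  }
}

#' Write a dataset to a store
#'
#' Persists a validated `spatial_dataset` as a hierarchical Zarr-style
#' directory store. Fails (before touching the path) if
#' [validate_dataset()] reports violations, or if the path exists and
#' `overwrite` is unset.
#'
#' @param ds a `spatial_dataset`.
#' @param path store directory to create.
#' @param overwrite replace an existing store?
#' @return `path`, invisibly.
#' @export
write_store <- function(ds, path, overwrite = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  v <- validate_dataset(ds)
  if (length(v))
    stop(paste(c("dataset fails validation:", v), collapse = "\n  "))
  if (file.exists(path)) {
    if (!overwrite) stop(sprintf("path '%s' exists; set overwrite = TRUE", path))
    unlink(path, recursive = TRUE)
  }
  zarr_init_group(path, list(spatialkit = list(
    format = "spatialkit-store", format_version = .SK_FORMAT_VERSION)))
  kinds <- c(images = "image", labels = "labels", points = "points",
             shapes = "shapes", tables = "table")
  for (grp in names(kinds)) {
    if (!length(ds[[grp]])) next
    zarr_init_group(file.path(path, grp))
    for (nm in names(ds[[grp]])) {
      staged <- file.path(path, grp, paste0(".tmp-", nm))
      unlink(staged, recursive = TRUE)
      ok <- FALSE
      tryCatch({
        e <- ds[[grp]][[nm]]
        switch(grp,
               images = write_raster_group(e, staged, "image"),
               labels = write_raster_group(e, staged, "labels"),
               points = write_points_group(e, staged),
               shapes = write_shapes_group(e, staged),
               tables = write_table_group(e, staged))
        ok <- TRUE
      }, finally = if (!ok) unlink(staged, recursive = TRUE))
      file.rename(staged, file.path(path, grp, nm))
    }
  }
  invisible(path)
}

read_raster_group <- function(path, lazy) {
  attrs <- read_json_file(file.path(path, ".zattrs"))
  sk <- attrs$spatialkit
  axes <- unlist(sk$axes)
  levels <- sort(as.integer(list.dirs(path, recursive = FALSE, full.names = FALSE)))
  pyramid <- lapply(levels, function(i) {
    la <- zarr_open_array(file.path(path, as.character(i)), counted = TRUE)
    if (lazy) la else materialize(la)
  })
  tfms <- lapply(sk$transformations, transform_from_list)
  kind <- sk$kind
  structure(list(data = pyramid[[1]], axes = axes, pyramid = pyramid,
                 transformations = tfms),
            class = c(paste0("sk_", kind), "sk_element"))
}

read_points_group <- function(path) {
  attrs <- read_json_file(file.path(path, ".zattrs"))
  df <- as.data.frame(arrow::read_parquet(file.path(path, "points.parquet")))
  ids <- df$`__instance_id`
  df$`__instance_id` <- NULL
  points_element(df, instance_ids = ids,
                 transformations = lapply(attrs$spatialkit$transformations,
                                          transform_from_list))
}

read_shapes_group <- function(path) {
  attrs <- read_json_file(file.path(path, ".zattrs"))
  g <- arrow::read_parquet(file.path(path, "geometries.parquet"))
  n <- nrow(g)
  wkb_col <- g$wkb
  geoms <- vector("list", n)
  for (i in seq_len(n)) {
    if (g$type[i] == "circle") {
      ctr <- c(x = g$cx[i], y = g$cy[i])
      if (!is.na(g$cz[i])) ctr <- c(ctr, z = g$cz[i])
      geoms[[i]] <- circle(ctr, g$radius[i])
    } else {
      geoms[[i]] <- geometry_from_wkb(as.raw(wkb_col[[i]]))
    }
  }
  data <- NULL
  if (file.exists(file.path(path, "attributes.parquet")))
    data <- as.data.frame(arrow::read_parquet(file.path(path, "attributes.parquet")))
  shapes_element(geoms, instance_ids = as.integer(g$`__instance_id`), data = data,
                 transformations = lapply(attrs$spatialkit$transformations,
                                          transform_from_list))
}

read_table_group <- function(path, lazy) {
  attrs <- read_json_file(file.path(path, ".zattrs"))
  sk <- attrs$spatialkit
  X <- read_matrix_node(file.path(path, "X"))
  if (!methods::is(X, "Matrix")) X <- materialize(X)
  vn <- unlist(sk$var_names)
  if (!is.null(vn)) colnames(X) <- vn
  obs <- as.data.frame(arrow::read_parquet(file.path(path, "obs.parquet")))
  var <- as.data.frame(arrow::read_parquet(file.path(path, "var.parquet")))
  layers <- list()
  lay_dir <- file.path(path, "layers")
  if (dir.exists(lay_dir)) {
    for (ln in list.dirs(lay_dir, recursive = FALSE, full.names = FALSE)) {
      l <- read_matrix_node(file.path(lay_dir, ln))
      layers[[ln]] <- if (methods::is(l, "Matrix")) l else materialize(l)
    }
  }
  table_element(X, obs = obs, var = var,
                region = if (is.null(sk$region)) NULL else unlist(sk$region),
                region_key = sk$region_key, instance_key = sk$instance_key,
                layers = layers)
}

check_store_root <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no store at '%s'", path))
  attrs_path <- file.path(path, ".zattrs")
  if (!file.exists(attrs_path))
    stop("not a spatialkit store: missing root attributes")
  attrs <- read_json_file(attrs_path)
  if (is.null(attrs$spatialkit$format_version))
    stop("invalid store: missing required root field 'format_version'")
  attrs
}

#' Read a dataset from a store
#'
#' With `lazy = TRUE` (the default) raster payloads are deferred: listing
#' elements, reading points/shapes/tables and all transformation metadata
#' touches no raster chunks (verified by [chunk_read_count()]); arrays
#' materialize only on [materialize()] or explicit access. Reading back a
#' written dataset reproduces all element content and metadata.
#'
#' @param path store directory written by [write_store()].
#' @param lazy defer raster payloads?
#' @return A `spatial_dataset`.
#' @export
read_store <- function(path, lazy = TRUE) {
  check_store_root(path)
  ds <- spatial_dataset()
  for (grp in c("images", "labels", "points", "shapes", "tables")) {
    gdir <- file.path(path, grp)
    if (!dir.exists(gdir)) next
    for (nm in list.dirs(gdir, recursive = FALSE, full.names = FALSE)) {
      edir <- file.path(gdir, nm)
      kind_attrs <- read_json_file(file.path(edir, ".zattrs"))
      kind <- kind_attrs$spatialkit$kind
      e <- switch(kind,
                  image = , labels = read_raster_group(edir, lazy),
                  points = read_points_group(edir),
                  shapes = read_shapes_group(edir),
                  table = read_table_group(edir, lazy),
                  stop(sprintf("unknown element kind '%s' in store", kind)))
      ds[[grp]][[nm]] <- e
    }
  }
  ds
}

#' Summarize a store without loading raster data
#'
#' @param path store directory.
#' @return A data.frame with one row per element: name, kind, shape or row
#'   count, pyramid levels and coordinate systems. The root format version is
#'   attached as attribute `"format_version"`.
#' @export
describe_store <- function(path) {
  attrs <- check_store_root(path)
  rows <- list()
  for (grp in c("images", "labels", "points", "shapes", "tables")) {
    gdir <- file.path(path, grp)
    if (!dir.exists(gdir)) next
    for (nm in list.dirs(gdir, recursive = FALSE, full.names = FALSE)) {
      edir <- file.path(gdir, nm)
      ea <- read_json_file(file.path(edir, ".zattrs"))
      sk <- ea$spatialkit
      cs <- paste(names(sk$transformations), collapse = ",")
      if (sk$kind %in% c("image", "labels")) {
        levels <- sort(as.integer(list.dirs(edir, recursive = FALSE,
                                            full.names = FALSE)))
        zm <- read_json_file(file.path(edir, "0", ".zarray"))
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = sk$kind,
          shape = paste(unlist(zm$shape), collapse = "x"),
          n = prod(unlist(zm$shape)),
          pyramid_levels = length(levels), coordinate_systems = cs)
      } else if (sk$kind == "points") {
        pf <- arrow::ParquetFileReader$create(file.path(edir, "points.parquet"))
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "points", shape = "", n = pf$ReadTable()$num_rows,
          pyramid_levels = NA_integer_, coordinate_systems = cs)
      } else if (sk$kind == "shapes") {
        gq <- arrow::read_parquet(file.path(edir, "geometries.parquet"),
                                  col_select = "type")
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "shapes", shape = "", n = nrow(gq),
          pyramid_levels = NA_integer_, coordinate_systems = cs)
      } else {
        obs <- arrow::read_parquet(file.path(edir, "obs.parquet"))
        nvar <- length(unlist(sk$var_names))
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "table", shape = paste0(nrow(obs), "x", nvar),
          n = nrow(obs), pyramid_levels = NA_integer_,
          coordinate_systems = "")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), kind = character(), shape = character(),
               n = numeric(), pyramid_levels = integer(),
               coordinate_systems = character())
  attr(out, "format_version") <- attrs$spatialkit$format_version
  out
}

# update an element's transformation metadata in place (write-back path of
# set_transformation)
store_update_transformations <- function(path, name, transformations) {
  check_store_root(path)
  for (grp in c("images", "labels", "points", "shapes")) {
    edir <- file.path(path, grp, name)
    if (dir.exists(edir)) {
      attrs <- read_json_file(file.path(edir, ".zattrs"))
      attrs$spatialkit$transformations <-
        lapply(transformations, transform_to_list)
      write_json_file(attrs, file.path(edir, ".zattrs"))
      return(invisible(path))
    }
  }
  stop(sprintf("no element named '%s' in store '%s'", name, path))
}

#' Add a table element to an existing store
#'
#' @param path store directory.
#' @param tab an `sk_table`.
#' @param name table name.
#' @return `path`, invisibly.
#' @export
store_write_table <- function(path, tab, name) {
  check_store_root(path)
  zarr_init_group(file.path(path, "tables"))
  staged <- file.path(path, "tables", paste0(".tmp-", name))
  unlink(staged, recursive = TRUE)
  write_table_group(tab, staged)
  dest <- file.path(path, "tables", name)
  unlink(dest, recursive = TRUE)
  file.rename(staged, dest)
  invisible(path)
}
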