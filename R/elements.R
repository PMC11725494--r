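# The five primitive element kinds and the dataset container.
#
# Conventions:
#   * Raster arrays are stored with axes in (c, z, y, x) order (subsets
#     thereof). Pixel (row i, col j) of a 2D raster occupies the half-open
#     square [i-1, i) x [j-1, j) in intrinsic (y, x) units under R's 1-based
#     indexing, i.e. its center is (i - 0.5, j - 0.5). This makes scale
#     transforms commute with pyramid levels.
#   * Vector elements store coordinates as columns named x, y (optionally z);
#     the mapping between the raster (z, y, x) axis order and the column
#     convention is resolved by name through the transforms module, never
#     positionally.
#   * Instance ids: label masks use their nonzero pixel values; points and
#     shapes use an explicit integer id vector (defaulting to the row index),
#     preserved verbatim by every operation.

.SK_AXIS_ORDER <- c("c", "z", "y", "x")
.SK_PYRAMID_STOP <- 64L   # add levels while max spatial dim >= this

#' Validate an ordered axis-name set
#'
#' Axis names are drawn from `c, z, y, x`; spatial axes appear in the order
#' `(z, y, x)` and the channel axis `c` precedes them.
#'
#' @param axes character vector of axis names.
#' @return `axes`, invisibly; errors on violation.
#' @export
check_axes <- function(axes) {
  if (!is.character(axes) || anyDuplicated(axes) ||
      !all(axes %in% .SK_AXIS_ORDER))
    stop("axes must be unique names drawn from {c, z, y, x}")
  if (!identical(axes, .SK_AXIS_ORDER[.SK_AXIS_ORDER %in% axes]))
    stop("axes must be ordered as (c, z, y, x)")
  invisible(axes)
}

spatial_axes <- function(axes) setdiff(axes, "c")

new_element <- function(kind, fields, transformations = NULL) {
  if (is.null(transformations)) {
    transformations <- list(global = identity_transform())
  }
  stopifnot(is.list(transformations), !is.null(names(transformations)))
  structure(c(fields, list(transformations = transformations)),
            class = c(paste0("sk_", kind), "sk_element"))
}

element_kind <- function(e) {
  if (inherits(e, "sk_image")) return("image")
  if (inherits(e, "sk_labels")) return("labels")
  if (inherits(e, "sk_points")) return("points")
  if (inherits(e, "sk_shapes")) return("shapes")
  if (inherits(e, "sk_table")) return("table")
  stop("not a spatial element")
}

# ---------------------------------------------------------------------------
# rasters

#' Build a spatial element
#'
#' `build_element()` dispatches on `kind` to the typed constructors
#' `image_element()`, `labels_element()`, `points_element()`,
#' `shapes_element()` and `table_element()`. Every non-table element carries a
#' mapping from coordinate-system names to transformations, defaulting to the
#' identity into the system `"global"`.
#'
#' @param kind one of `"image"`, `"labels"`, `"points"`, `"shapes"`, `"table"`.
#' @param payload the raw data the typed constructor expects.
#' @param ... options forwarded to the typed constructor.
#' @return A validated element.
#' @examples
#' img <- build_element("image", array(0, c(1, 4, 4)))
#' dim(img$data)
#' @export
build_element <- function(kind, payload, ...) {
  switch(match.arg(kind, c("image", "labels", "points", "shapes", "table")),
         image = image_element(payload, ...),
         labels = labels_element(payload, ...),
         points = points_element(payload, ...),
         shapes = shapes_element(payload, ...),
         table = table_element(payload, ...))
}

#' @param data numeric array with axes `(c, y, x)` or `(c, z, y, x)` for
#'   images; non-negative integer array with axes `(y, x)` or `(z, y, x)` for
#'   labels (0 is background).
#' @param axes axis names matching `dim(data)`; inferred from the
#'   dimensionality when omitted.
#' @param pyramid logical: build a factor-2 multiscale pyramid (mean pooling
#'   for images, stride-2 subsampling for labels) with levels added while the
#'   largest spatial dimension is at least 64?
#' @param transformations named list mapping coordinate-system names to
#'   `sk_transform`s; defaults to identity into `"global"`.
#' @rdname build_element
#' @export
image_element <- function(data, axes = NULL, pyramid = FALSE,
                          transformations = NULL) {
  if (is.null(axes)) {
    axes <- switch(as.character(length(dim(data))),
                   "3" = c("c", "y", "x"), "4" = c("c", "z", "y", "x"),
                   stop("image payload must have 3 (c,y,x) or 4 (c,z,y,x) dimensions"))
  }
  check_axes(axes)
  if (!identical(axes[1], "c") || length(dim(data)) != length(axes))
    stop("image axes must be (c, y, x) or (c, z, y, x) matching the payload")
  if (!is.numeric(data)) stop("image payload must be numeric")
  storage.mode(data) <- "double"
  levels <- build_pyramid(data, axes, mode = if (pyramid) "mean" else "none")
  new_element("image", list(data = data, axes = axes, pyramid = levels),
              transformations)
}

#' @rdname build_element
#' @export
labels_element <- function(data, axes = NULL, pyramid = FALSE,
                           transformations = NULL) {
  if (is.matrix(data)) data <- array(data, dim(data))
  if (is.null(axes)) {
    axes <- switch(as.character(length(dim(data))),
                   "2" = c("y", "x"), "3" = c("z", "y", "x"),
                   stop("labels payload must have 2 (y,x) or 3 (z,y,x) dimensions"))
  }
  check_axes(axes)
  if ("c" %in% axes || length(dim(data)) != length(axes))
    stop("labels axes must be (y, x) or (z, y, x) matching the payload")
  if (!is.numeric(data) || any(data != round(data)) || any(data < 0))
    stop("labels payload must be a non-negative integer array")
  storage.mode(data) <- "integer"
  levels <- build_pyramid(data, axes, mode = if (pyramid) "subsample" else "none")
  new_element("labels", list(data = data, axes = axes, pyramid = levels),
              transformations)
}

# Factor-2 pyramid. Level 0 is the full-resolution array; further levels are
# appended while the largest spatial dimension is >= 64. Odd trailing
# rows/cols are dropped exactly.
build_pyramid <- function(data, axes, mode = c("none", "mean", "subsample")) {
  mode <- match.arg(mode)
  levels <- list(data)
  if (mode == "none") return(levels)
  sp <- which(axes %in% .SK_SPATIAL_AXES)
  cur <- data
  while (max(dim(cur)[sp]) >= .SK_PYRAMID_STOP) {
    cur <- downsample_once(cur, sp, mode)
    levels <- c(levels, list(cur))
  }
  levels
}

downsample_once <- function(arr, spatial_dims, mode) {
  d <- dim(arr)
  keep <- lapply(seq_along(d), function(k) {
    if (k %in% spatial_dims) seq_len(d[k] - d[k] %% 2L) else seq_len(d[k])
  })
  arr <- do.call(`[`, c(list(arr), keep, list(drop = FALSE)))
  d <- dim(arr)
  if (mode == "subsample") {
    idx <- lapply(seq_along(d), function(k) {
      if (k %in% spatial_dims) seq(1L, d[k], by = 2L) else seq_len(d[k])
    })
    return(do.call(`[`, c(list(arr), idx, list(drop = FALSE))))
  }
  # mean pooling: average 2^s blocks by successive pairwise means per axis
  out <- arr
  for (k in spatial_dims) {
    d <- dim(out)
    i1 <- lapply(seq_along(d), function(m) if (m == k) seq(1L, d[m], 2L) else seq_len(d[m]))
    i2 <- lapply(seq_along(d), function(m) if (m == k) seq(2L, d[m], 2L) else seq_len(d[m]))
    out <- (do.call(`[`, c(list(out), i1, list(drop = FALSE))) +
            do.call(`[`, c(list(out), i2, list(drop = FALSE)))) / 2
  }
  out
}

raster_spatial_dims <- function(e) {
  sp <- spatial_axes(e$axes)
  d <- dim(e$data)[match(sp, e$axes)]
  names(d) <- sp
  d
}

#' Instance ids of a label mask (distinct nonzero values, sorted)
#' @param e an `sk_labels` element.
#' @return Integer vector of instance ids.
#' @export
label_ids <- function(e) {
  stopifnot(inherits(e, "sk_labels"))
  ids <- sort(unique(as.vector(materialize(e$data))))
  ids[ids != 0L]
}

# ---------------------------------------------------------------------------
# vector elements

#' @param records data.frame with finite numeric columns `x`, `y` (optionally
#'   `z`) plus arbitrary attribute columns, for points.
#' @param instance_ids integer instance ids (default: the row index); must be
#'   unique and are preserved verbatim by all operations.
#' @rdname build_element
#' @export
points_element <- function(records, instance_ids = NULL,
                           transformations = NULL) {
  records <- as.data.frame(records)
  axes <- intersect(c("x", "y", "z"), names(records))
  if (!all(c("x", "y") %in% axes))
    stop("points records must have numeric columns x and y")
  for (ax in axes) {
    if (!is.numeric(records[[ax]]) || any(!is.finite(records[[ax]])))
      stop(sprintf("coordinate column '%s' must be finite numeric", ax))
  }
  if (is.null(instance_ids)) instance_ids <- seq_len(nrow(records))
  instance_ids <- as.integer(instance_ids)
  if (length(instance_ids) != nrow(records) || anyDuplicated(instance_ids))
    stop("instance_ids must be unique, one per row")
  rownames(records) <- NULL
  new_element("points",
              list(data = records, instance_ids = instance_ids,
                   axes = intersect(c("z", "y", "x"), axes)),
              transformations)
}

#' Shape geometries
#'
#' Geometry constructors for [shapes_element()]: a circle (center plus a
#' strictly positive radius), a polygon (one outer ring, optional hole rings,
#' even-odd semantics; outer rings are normalised counter-clockwise and holes
#' clockwise) and a multipolygon (list of polygons).
#'
#' @param center numeric vector named `x`, `y` (optionally `z`).
#' @param radius strictly positive number.
#' @param rings list of ring matrices (columns `x`, `y`), or a single matrix;
#'   first ring is the outer boundary, the rest are holes. Rings are stored
#'   unclosed (last vertex differs from the first) with at least 3 distinct
#'   vertices.
#' @param polygons list of `circle`/`polygon` ring-lists for `multipolygon`.
#' @return A geometry object (class `sk_geometry`).
#' @name geometries
NULL

#' @rdname geometries
#' @export
circle <- function(center, radius) {
  center <- unlist(center)
  if (is.null(names(center))) names(center) <- c("x", "y", "z")[seq_along(center)]
  if (!all(c("x", "y") %in% names(center)) || any(!is.finite(center)))
    stop("circle center must be finite and named x, y")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("circle radius must be strictly positive")
  structure(list(type = "circle", center = center, radius = radius),
            class = "sk_geometry")
}

#' @rdname geometries
#' @export
polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(seq_along(rings), function(i) normalize_ring(rings[[i]], hole = i > 1L))
  structure(list(type = "polygon", rings = rings), class = "sk_geometry")
}

#' @rdname geometries
#' @export
multipolygon <- function(polygons) {
  polys <- lapply(polygons, function(p) {
    if (inherits(p, "sk_geometry")) {
      stopifnot(p$type == "polygon")
      p$rings
    } else polygon(p)$rings
  })
  structure(list(type = "multipolygon", polygons = polys),
            class = "sk_geometry")
}

normalize_ring <- function(ring, hole = FALSE) {
  ring <- as.matrix(ring)
  if (is.null(colnames(ring))) colnames(ring) <- c("x", "y")[seq_len(ncol(ring))]
  ring <- ring[, c("x", "y"), drop = FALSE]
  if (any(!is.finite(ring))) stop("polygon ring coordinates must be finite")
  n <- nrow(ring)
  if (n >= 2L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(unique(ring)) < 3L)
    stop("polygon ring must have at least 3 distinct vertices")
  a <- ring_signed_area(ring)
  if (a == 0) stop("degenerate polygon ring with zero area")
  if ((a < 0) != hole) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

#' @param geometries list of geometry objects (see [circle()], [polygon()],
#'   [multipolygon()]) for shapes.
#' @param data optional data.frame of per-instance attribute columns (e.g. a
#'   category), one row per geometry.
#' @rdname build_element
#' @export
shapes_element <- function(geometries, instance_ids = NULL, data = NULL,
                           transformations = NULL) {
  stopifnot(is.list(geometries), length(geometries) >= 0L)
  for (g in geometries) {
    if (!inherits(g, "sk_geometry")) stop("geometries must be built with circle()/polygon()/multipolygon()")
  }
  if (is.null(instance_ids)) instance_ids <- seq_along(geometries)
  instance_ids <- as.integer(instance_ids)
  if (length(instance_ids) != length(geometries) || anyDuplicated(instance_ids))
    stop("instance_ids must be unique, one per geometry")
  if (!is.null(data)) {
    data <- as.data.frame(data)
    if (nrow(data) != length(geometries))
      stop("attribute data must have one row per geometry")
    rownames(data) <- NULL
  }
  new_element("shapes",
              list(geometries = geometries, instance_ids = instance_ids,
                   data = data, axes = c("y", "x")),
              transformations)
}

# ---------------------------------------------------------------------------
# annotation tables

#' @param X instances x variables matrix, dense or sparse (`Matrix`), for
#'   tables.
#' @param obs per-instance metadata data.frame (may have categorical columns).
#' @param var per-variable metadata data.frame.
#' @param region name(s) of the annotated element(s), or `NULL`.
#' @param region_key name of the obs column holding the element name per row.
#' @param instance_key name of the obs column holding the instance id per row.
#' @param layers named list of extra matrices with the same shape as `X`.
#' @rdname build_element
#' @export
table_element <- function(X, obs = NULL, var = NULL, region = NULL,
                          region_key = NULL, instance_key = NULL,
                          layers = list()) {
  if (!(is.matrix(X) || methods::is(X, "Matrix")))
    stop("X must be a dense matrix or a Matrix sparse matrix")
  if (is.null(obs)) obs <- as.data.frame(matrix(nrow = nrow(X), ncol = 0))
  obs <- as.data.frame(obs)
  if (is.null(var)) {
    vn <- colnames(X)
    if (is.null(vn)) vn <- paste0("V", seq_len(ncol(X)))
    var <- data.frame(var_name = vn, stringsAsFactors = FALSE)
  }
  var <- as.data.frame(var)
  if (nrow(obs) != nrow(X)) stop("obs must have one row per instance (row of X)")
  if (nrow(var) != ncol(X)) stop("var must have one row per variable (column of X)")
  keys <- list(region = region, region_key = region_key, instance_key = instance_key)
  n_set <- sum(!vapply(keys, is.null, logical(1)))
  if (!(n_set %in% c(0L, 3L)))
    stop("region, region_key and instance_key must be all set or all absent")
  for (lay in layers) {
    if (!all(dim(lay) == dim(X))) stop("every layer must have the same shape as X")
  }
  rownames(obs) <- NULL
  structure(list(X = X, obs = obs, var = var, region = region,
                 region_key = region_key, instance_key = instance_key,
                 layers = layers),
            class = c("sk_table", "sk_element"))
}

table_n_obs <- function(tab) nrow(tab$X)

# ---------------------------------------------------------------------------
# the dataset container

#' A named collection of spatial elements
#'
#' The container holds `name -> element` mappings for the five element kinds
#' and is the unit of storage and query. Element names must be unique across
#' all kinds.
#'
#' @param images,labels,points,shapes,tables named lists of elements of the
#'   corresponding kind.
#' @return A `spatial_dataset`.
#' @examples
#' ds <- spatial_dataset(images = list(img = image_element(array(0, c(1, 8, 8)))))
#' validate_dataset(ds)
#' @export
spatial_dataset <- function(images = list(), labels = list(), points = list(),
                            shapes = list(), tables = list()) {
  ds <- structure(list(images = images, labels = labels, points = points,
                       shapes = shapes, tables = tables),
                  class = "spatial_dataset")
  for (k in c("images", "labels", "points", "shapes", "tables")) {
    if (length(ds[[k]]) && (is.null(names(ds[[k]])) || any(!nzchar(names(ds[[k]])))))
      stop(sprintf("every element in '%s' must be named", k))
  }
  if (anyDuplicated(element_names(ds)))
    stop("element names must be unique across all kinds")
  ds
}

element_names <- function(ds) {
  unlist(lapply(c("images", "labels", "points", "shapes", "tables"),
                function(k) names(ds[[k]])), use.names = FALSE)
}

#' Look up an element by name across all kinds
#' @param ds a `spatial_dataset`.
#' @param name element name.
#' @return The element; errors if absent.
#' @export
get_element <- function(ds, name) {
  for (k in c("images", "labels", "points", "shapes", "tables")) {
    if (name %in% names(ds[[k]])) return(ds[[k]][[name]])
  }
  stop(sprintf("no element named '%s' in the dataset", name))
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset>\n")
  for (k in c("images", "labels", "points", "shapes", "tables")) {
    if (!length(x[[k]])) next
    cat("  ", k, ":\n", sep = "")
    for (nm in names(x[[k]])) {
      e <- x[[k]][[nm]]
      desc <- switch(k,
        images = , labels = paste0("(", paste(lazy_dim(e$data), collapse = "x"), "), ",
                                   length(e$pyramid), " pyramid level(s)"),
        points = paste0(nrow(e$data), " points"),
        shapes = paste0(length(e$geometries), " geometries"),
        tables = paste0(nrow(e$X), " x ", ncol(e$X)))
      cat("    ", nm, ": ", desc, "\n", sep = "")
    }
  }
  invisible(x)
}

# instance ids an annotation row can resolve against
element_instance_ids <- function(e) {
  switch(element_kind(e),
         labels = label_ids(e),
         points = e$instance_ids,
         shapes = e$instance_ids,
         stop("element kind has no instances to annotate"))
}

#' Validate a dataset against the element contracts
#'
#' Checks every element invariant plus the table-linkage contract: each
#' table's `(region, region_key, instance_key)` triple must resolve, i.e.
#' every annotated `(element, instance id)` pair must exist (a nonzero label
#' value, or a point/shape instance id). Violations are returned as a
#' character vector of human-readable reports, never raised.
#'
#' @param ds a `spatial_dataset`.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_dataset <- function(ds) {
  v <- character()
  nm <- element_names(ds)
  if (anyDuplicated(nm))
    v <- c(v, sprintf("duplicate element name(s): %s",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  # rasters: pyramid consistency
  for (k in c("images", "labels")) {
    for (en in names(ds[[k]])) {
      e <- ds[[k]][[en]]
      sp <- which(e$axes %in% .SK_SPATIAL_AXES)
      dims <- lapply(e$pyramid, lazy_dim)
      for (i in seq_along(dims)) {
        if (length(dims[[i]]) != length(e$axes))
          v <- c(v, sprintf("element '%s': pyramid level %d has a different axis count", en, i - 1L))
        else if (i > 1L && any(dims[[i]][sp] > dims[[i - 1L]][sp]))
          v <- c(v, sprintf("element '%s': pyramid level %d is larger than level %d", en, i - 1L, i - 2L))
      }
      if (!length(e$transformations))
        v <- c(v, sprintf("element '%s': no coordinate-system transformation", en))
    }
  }
  for (en in names(ds$shapes)) {
    e <- ds$shapes[[en]]
    for (i in seq_along(e$geometries)) {
      g <- e$geometries[[i]]
      if (g$type == "circle" && g$radius <= 0)
        v <- c(v, sprintf("shapes '%s': instance %d has non-positive radius", en, e$instance_ids[i]))
    }
  }
  # coordinate-system names must imply one axis set
  cs_axes <- list()
  for (k in c("images", "labels", "points", "shapes")) {
    for (en in names(ds[[k]])) {
      e <- ds[[k]][[en]]
      sp <- spatial_axes(e$axes)
      for (cs in names(e$transformations)) {
        if (is.null(cs_axes[[cs]])) cs_axes[[cs]] <- sp
        else if (!setequal(cs_axes[[cs]], sp))
          v <- c(v, sprintf("coordinate system '%s' used with conflicting axis sets", cs))
      }
    }
  }
  # table linkage
  for (tn in names(ds$tables)) {
    tab <- ds$tables[[tn]]
    keys <- list(tab$region, tab$region_key, tab$instance_key)
    n_set <- sum(!vapply(keys, is.null, logical(1)))
    if (n_set == 0L) next
    if (n_set != 3L) {
      v <- c(v, sprintf("table '%s': region/region_key/instance_key must be all set or all absent", tn))
      next
    }
    if (!all(c(tab$region_key, tab$instance_key) %in% names(tab$obs))) {
      v <- c(v, sprintf("table '%s': region_key/instance_key column missing from obs", tn))
      next
    }
    regions <- as.character(tab$obs[[tab$region_key]])
    inst <- tab$obs[[tab$instance_key]]
    bad_region <- setdiff(unique(regions), as.character(tab$region))
    if (length(bad_region))
      v <- c(v, sprintf("table '%s': obs names region(s) %s outside the declared region",
                        tn, paste(bad_region, collapse = ", ")))
    for (rn in intersect(unique(regions), as.character(tab$region))) {
      target <- tryCatch(get_element(ds, rn), error = function(e) NULL)
      if (is.null(target)) {
        v <- c(v, sprintf("table '%s': annotated element '%s' does not exist", tn, rn))
        next
      }
      ids <- tryCatch(element_instance_ids(target), error = function(e) NULL)
      if (is.null(ids)) {
        v <- c(v, sprintf("table '%s': element '%s' of kind %s cannot be annotated",
                          tn, rn, element_kind(target)))
        next
      }
      missing <- setdiff(inst[regions == rn], ids)
      for (mid in missing)
        v <- c(v, sprintf("table '%s': instance id %s not found in element '%s'",
                          tn, format(mid), rn))
    }
  }
  v
}

#' Restrict a table to the instances of the element it annotates
#'
#' Returns the table restricted to rows whose `(region_key, instance_key)`
#' pair resolves to an instance of `element_name`, reordered to match the
#' element's instance order. Layers and obs travel with the rows.
#'
#' @param ds a `spatial_dataset`.
#' @param table_name name of a table in `ds`.
#' @param element_name name of the annotated element.
#' @return An `sk_table`.
#' @export
match_table_to_element <- function(ds, table_name, element_name) {
  tab <- ds$tables[[table_name]]
  if (is.null(tab)) stop(sprintf("no table named '%s'", table_name))
  if (is.null(tab$region) || !(element_name %in% as.character(tab$region)))
    stop(sprintf("table '%s' does not annotate element '%s'", table_name, element_name))
  target <- get_element(ds, element_name)
  ids <- element_instance_ids(target)
  rows_region <- as.character(tab$obs[[tab$region_key]]) == element_name
  inst <- tab$obs[[tab$instance_key]]
  pos <- match(ids, ifelse(rows_region, inst, NA))
  pos <- pos[!is.na(pos)]
  subset_table(tab, pos)
}

subset_table <- function(tab, rows) {
  table_element(X = tab$X[rows, , drop = FALSE],
                obs = tab$obs[rows, , drop = FALSE],
                var = tab$var,
                region = tab$region, region_key = tab$region_key,
                instance_key = tab$instance_key,
                layers = lapply(tab$layers, function(l) l[rows, , drop = FALSE]))
}

#' Assign a transformation to an element
#'
#' Adds or overwrites the element's transformation into the named coordinate
#' system. With `store` set, the updated transformation metadata is also
#' persisted to that element's group in a written store.
#'
#' @param e a non-table element.
#' @param system coordinate-system name.
#' @param t an `sk_transform`.
#' @param store optional path to a store written by [write_store()] holding
#'   this element under `name`; metadata is updated in place.
#' @param name element name inside the store (required with `store`).
#' @return The updated element.
#' @export
set_transformation <- function(e, system, t, store = NULL, name = NULL) {
  stopifnot(inherits(e, "sk_element"), inherits(t, "sk_transform"))
  e$transformations[[system]] <- t
  if (!is.null(store)) {
    if (is.null(name)) stop("element 'name' is required to write back to a store")
    store_update_transformations(store, name, e$transformations)
  }
  e
}

#' @rdname set_transformation
#' @export
get_transformation <- function(e, system) {
  t <- e$transformations[[system]]
  if (is.null(t))
    stop(sprintf("element has no transformation into coordinate system '%s'", system))
  t
}
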