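# Spatial queries: subset any element or a whole dataset by a region
# expressed in any coordinate system.
#
# Interval conventions, fixed once and used everywhere: bounding boxes are
# half-open [min, max) for point coordinates and pixel centers; polygon
# membership is boundary-closed (a point on an edge is kept). Shapes survive
# a query when their geometry INTERSECTS the region (an ROI should capture
# cells partially inside it); `mode = "centroid"` switches to
# centroid-containment. Raster crops only adjust the translation component of
# their transformations -- queries never interpolate.

#' Query regions
#'
#' A query region is an axis-aligned box (`box_region`) or a polygon
#' (`polygon_region`), together with the name of the coordinate system it is
#' expressed in.
#'
#' @param min_coord,max_coord named numeric vectors (axes `x`, `y`, optionally
#'   `z`) with `min < max` per axis.
#' @param geometry an `sk_geometry` polygon/multipolygon, or a ring matrix.
#' @param frame coordinate-system name.
#' @return A `query_region`.
#' @export
box_region <- function(min_coord, max_coord, frame = "global") {
  check_named_numeric(min_coord, "min_coord")
  check_named_numeric(max_coord, "max_coord")
  axes <- names(min_coord)
  if (!setequal(axes, names(max_coord)))
    stop("min_coord and max_coord must name the same axes")
  max_coord <- max_coord[axes]
  if (any(max_coord <= min_coord)) stop("box region requires min < max per axis")
  structure(list(variant = "box", min = min_coord, max = max_coord,
                 frame = frame), class = "query_region")
}

#' @rdname box_region
#' @export
polygon_region <- function(geometry, frame = "global") {
  if (is.matrix(geometry)) geometry <- polygon(geometry)
  stopifnot(inherits(geometry, "sk_geometry"),
            geometry$type %in% c("polygon", "multipolygon"))
  structure(list(variant = "polygon", geometry = geometry, frame = frame),
            class = "query_region")
}

region_as_geometry <- function(region) {
  if (region$variant == "polygon") return(region$geometry)
  axes <- names(region$min)
  lo <- region$min; hi <- region$max
  polygon(cbind(x = c(lo[["x"]], hi[["x"]], hi[["x"]], lo[["x"]]),
                y = c(lo[["y"]], lo[["y"]], hi[["y"]], hi[["y"]])))
}

#' Bounding-box query
#'
#' Subsets an element (or every element of a dataset) to the axis-aligned box
#' of the region, evaluated in the region's coordinate system. Points are
#' kept when their transformed coordinates lie in `[min, max)` per axis;
#' shapes when their transformed geometry intersects the closed box; rasters
#' are cropped to the pixels whose centers fall inside the
#' inverse-transformed box's axis-aligned bounds, and the crop's
#' transformations gain the corresponding translation so its position in the
#' query frame is unchanged. Dataset tables are restricted to surviving
#' instances.
#'
#' @param target an element or `spatial_dataset`.
#' @param region a `query_region` built with [box_region()].
#' @param mode shapes survival rule: `"intersects"` (default) or
#'   `"centroid"`.
#' @param ... passed between methods.
#' @return An object of the same type as `target`.
#' @export
bounding_box_query <- function(target, region, ...) {
  stopifnot(inherits(region, "query_region"), region$variant == "box")
  UseMethod("bounding_box_query")
}

#' Polygon query
#'
#' As [bounding_box_query()], with a polygonal region: points are kept when
#' inside or on the polygon boundary (even-odd rule, closed); shapes when
#' intersecting the polygon; rasters are cropped to the polygon's bounding
#' box and pixels whose centers fall outside the polygon are zeroed.
#'
#' @inheritParams bounding_box_query
#' @param region a `query_region` built with [polygon_region()].
#' @export
polygon_query <- function(target, region, ...) {
  stopifnot(inherits(region, "query_region"), region$variant == "polygon")
  UseMethod("polygon_query")
}

# -- points -----------------------------------------------------------------

points_coords_in_frame <- function(e, frame) {
  axes <- intersect(c("x", "y", "z"), names(e$data))
  t <- get_transformation(e, frame)
  apply_transform(t, as.matrix(e$data[, axes, drop = FALSE]))
}

subset_points <- function(e, keep) {
  points_element(e$data[keep, , drop = FALSE],
                 instance_ids = e$instance_ids[keep],
                 transformations = e$transformations)
}

#' @export
bounding_box_query.sk_points <- function(target, region, ...) {
  coords <- points_coords_in_frame(target, region$frame)
  keep <- rep(TRUE, nrow(coords))
  for (ax in names(region$min))
    keep <- keep & coords[, ax] >= region$min[[ax]] & coords[, ax] < region$max[[ax]]
  subset_points(target, keep)
}

#' @export
polygon_query.sk_points <- function(target, region, ...) {
  coords <- points_coords_in_frame(target, region$frame)
  keep <- point_in_geometry(coords[, "x"], coords[, "y"], region$geometry)
  subset_points(target, keep)
}

# -- shapes -----------------------------------------------------------------

shapes_in_frame <- function(e, frame) {
  t <- get_transformation(e, frame)
  lapply(e$geometries, transform_geometry, t = t)
}

subset_shapes <- function(e, keep) {
  shapes_element(e$geometries[keep], instance_ids = e$instance_ids[keep],
                 data = if (is.null(e$data)) NULL else e$data[keep, , drop = FALSE],
                 transformations = e$transformations)
}

geometry_centroid <- function(g) {
  if (g$type == "circle") return(g$center[c("x", "y")])
  v <- do.call(rbind, lapply(geometry_as_rings(g), function(r) do.call(rbind, r)))
  c(x = mean(v[, "x"]), y = mean(v[, "y"]))
}

shape_survives <- function(g, region_geom, mode) {
  if (mode == "centroid") {
    ctr <- geometry_centroid(g)
    return(point_in_geometry(ctr[["x"]], ctr[["y"]], region_geom))
  }
  if (g$type == "circle" && region_geom$type == "polygon" &&
      nrow(region_geom$rings[[1]]) == 4L && length(region_geom$rings) == 1L &&
      ring_is_convex(region_geom$rings[[1]])) {
    # exact circle-box test: clamp the center into the box
    ring <- region_geom$rings[[1]]
    cx <- pmin(pmax(g$center[["x"]], min(ring[, "x"])), max(ring[, "x"]))
    cy <- pmin(pmax(g$center[["y"]], min(ring[, "y"])), max(ring[, "y"]))
    return((cx - g$center[["x"]])^2 + (cy - g$center[["y"]])^2 <= g$radius^2 + 1e-12)
  }
  geometries_intersect(g, region_geom)
}

query_shapes_impl <- function(target, region, mode) {
  geoms <- shapes_in_frame(target, region$frame)
  region_geom <- region_as_geometry(region)
  keep <- vapply(geoms, shape_survives, logical(1),
                 region_geom = region_geom, mode = mode)
  subset_shapes(target, keep)
}

#' @export
bounding_box_query.sk_shapes <- function(target, region,
                                         mode = c("intersects", "centroid"), ...) {
  query_shapes_impl(target, region, match.arg(mode))
}

#' @export
polygon_query.sk_shapes <- function(target, region,
                                    mode = c("intersects", "centroid"), ...) {
  query_shapes_impl(target, region, match.arg(mode))
}

# -- rasters ----------------------------------------------------------------

# crop index range along one axis: pixel centers i - 0.5 kept in [lo, hi)
crop_range <- function(lo, hi, n) {
  i0 <- max(1L, as.integer(ceiling(lo + 0.5)))
  i1 <- min(n, as.integer(ceiling(hi + 0.5)) - 1L)
  c(i0, i1)
}

crop_raster_to_bounds <- function(e, lo, hi) {
  sp <- spatial_axes(e$axes)
  arr <- materialize(e$data)
  d <- dim(arr)
  sp_pos <- match(sp, e$axes)
  ranges <- lapply(seq_along(sp), function(k)
    crop_range(lo[[sp[k]]], hi[[sp[k]]], d[sp_pos[k]]))
  idx <- lapply(seq_along(d), function(k) {
    m <- match(k, sp_pos)
    if (is.na(m)) seq_len(d[k])
    else if (ranges[[m]][1] > ranges[[m]][2]) integer(0)
    else seq(ranges[[m]][1], ranges[[m]][2])
  })
  cropped <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  offs <- vapply(seq_along(sp), function(k) as.numeric(ranges[[k]][1] - 1L), numeric(1))
  names(offs) <- sp
  shift <- translation_transform(offs)
  tfms <- lapply(e$transformations, function(t) compose_transforms(shift, t))
  list(element = rebuild_raster(e, cropped, tfms), offset = offs,
       empty = any(vapply(idx, length, integer(1)) == 0L))
}

query_raster_impl <- function(target, region) {
  t <- get_transformation(target, region$frame)
  sp <- spatial_axes(target$axes)
  t_inv <- invert_transform(t)
  if (region$variant == "box") {
    axes <- names(region$min)
    corners <- as.matrix(do.call(expand.grid,
      lapply(axes, function(ax) c(region$min[[ax]], region$max[[ax]]))))
    colnames(corners) <- axes
  } else {
    bb <- geometry_bbox(region$geometry)
    corners <- as.matrix(expand.grid(x = bb[, "x"], y = bb[, "y"]))
  }
  mapped <- apply_transform(t_inv, corners)
  lo <- lapply(stats::setNames(sp, sp), function(ax) min(mapped[, ax]))
  hi <- lapply(stats::setNames(sp, sp), function(ax) max(mapped[, ax]))
  res <- crop_raster_to_bounds(target, lo, hi)
  if (region$variant == "polygon" && !res$empty) {
    # zero out pixels whose centers fall outside the polygon (in intrinsic
    # coordinates: the region is mapped back through the inverse transform)
    region_i <- transform_geometry(region$geometry, t_inv)
    e <- res$element
    arr <- materialize(e$data)
    d <- dim(arr)
    sp_pos <- match(sp, e$axes)
    centers <- lapply(seq_along(sp), function(k)
      res$offset[[sp[k]]] + seq_len(d[sp_pos[k]]) - 0.5)
    names(centers) <- sp
    grid <- do.call(expand.grid, centers)
    outside <- !point_in_geometry(grid$x, grid$y, region_i)
    mask <- array(outside, dim = d[sp_pos])
    if ("c" %in% e$axes) {
      for (ch in seq_len(d[1])) {
        plane <- array(arr[slice.index(arr, 1) == ch], dim = d[sp_pos])
        plane[mask] <- 0
        arr[slice.index(arr, 1) == ch] <- plane
      }
    } else {
      arr[mask] <- 0
    }
    res$element <- rebuild_raster(e, arr, e$transformations)
  }
  res$element
}

#' @export
bounding_box_query.sk_image <- function(target, region, ...) query_raster_impl(target, region)
#' @export
bounding_box_query.sk_labels <- function(target, region, ...) query_raster_impl(target, region)
#' @export
polygon_query.sk_image <- function(target, region, ...) query_raster_impl(target, region)
#' @export
polygon_query.sk_labels <- function(target, region, ...) query_raster_impl(target, region)

# -- datasets ---------------------------------------------------------------

query_dataset_impl <- function(target, region, query_fun, ...) {
  out <- target
  for (k in c("images", "labels", "points", "shapes")) {
    for (nm in names(target[[k]])) {
      out[[k]][[nm]] <- query_fun(target[[k]][[nm]], region, ...)
    }
  }
  # restrict tables to instances that survived in their annotated elements
  for (tn in names(target$tables)) {
    tab <- target$tables[[tn]]
    if (is.null(tab$region)) next
    regions <- as.character(tab$obs[[tab$region_key]])
    inst <- tab$obs[[tab$instance_key]]
    keep <- logical(nrow(tab$obs))
    for (rn in unique(regions)) {
      ids <- element_instance_ids(get_element(out, rn))
      keep[regions == rn & inst %in% ids] <- TRUE
    }
    out$tables[[tn]] <- subset_table(tab, which(keep))
  }
  out
}

#' @export
bounding_box_query.spatial_dataset <- function(target, region, ...) {
  query_dataset_impl(target, region, bounding_box_query, ...)
}

#' @export
polygon_query.spatial_dataset <- function(target, region, ...) {
  query_dataset_impl(target, region, polygon_query, ...)
}

#' Is an element empty (no instances / zero-extent raster)?
#' @param e an element.
#' @return Logical.
#' @export
is_empty_element <- function(e) {
  switch(element_kind(e),
         image = , labels = any(lazy_dim(e$data) == 0L),
         points = nrow(e$data) == 0L,
         shapes = length(e$geometries) == 0L,
         table = nrow(e$X) == 0L)
}
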