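# Cross-element aggregation: summarize a source element's values over the
# instances of a target shapes (or labels) element, producing an annotation
# table linked to the target via (region, region_key, instance_key).
#
# For shape sources the weight of source i on target j is
#     w_ij = area(source_i  intersect  target_j) / area(source_i),
# i.e. the denominator is the SOURCE area: a cell split across two capture
# locations contributes at most 1 in total and is never double-counted. With
# `fractions = TRUE` each target row is then normalized to sum to 1 over
# categories, which yields the composition fractions of the location. The
# source-area choice is isolated in `shape_overlap_weights()` so the
# alternative normalizations remain switchable.

#' Aggregate points onto shape instances
#'
#' Counts (or sums/averages a numeric column of) the source points falling
#' into each target shape instance, with membership evaluated in `frame`
#' (boundary-closed for both circles and polygons). With a categorical
#' `value_key` the result matrix has one column per category; points in no
#' target contribute nothing and points in overlapping targets contribute to
#' each.
#'
#' @param ds a `spatial_dataset`.
#' @param source name of an `sk_points` element.
#' @param target name of an `sk_shapes` element.
#' @param value_key optional column of the source records: categorical (counts
#'   per category) or numeric (with `agg = "sum"`/`"mean"`).
#' @param agg `"count"`, `"sum"` or `"mean"`.
#' @param frame coordinate system in which membership is computed.
#' @return An `sk_table` annotating the target element.
#' @export
aggregate_points_by_shapes <- function(ds, source, target, value_key = NULL,
                                       agg = c("count", "sum", "mean"),
                                       frame = "global") {
  agg <- match.arg(agg)
  src <- get_element(ds, source); tgt <- get_element(ds, target)
  if (!inherits(src, "sk_points") || !inherits(tgt, "sk_shapes"))
    stop("aggregate_points_by_shapes expects a points source and a shapes target")
  vals <- NULL
  if (!is.null(value_key)) {
    if (!value_key %in% names(src$data))
      stop(sprintf("source has no column '%s'", value_key))
    vals <- src$data[[value_key]]
  }
  categorical <- !is.null(vals) && (is.factor(vals) || is.character(vals))
  if (agg != "count" && (is.null(vals) || categorical))
    stop(sprintf("agg = '%s' requires a numeric value_key", agg))
  if (agg == "count" && !is.null(vals) && !categorical)
    stop("agg = 'count' requires a categorical value_key (or none)")
  coords <- points_coords_in_frame(src, frame)
  geoms <- shapes_in_frame(tgt, frame)
  if (categorical) {
    vals <- as.factor(vals)
    cats <- levels(vals)
    X <- matrix(0, length(geoms), length(cats), dimnames = list(NULL, cats))
  } else {
    X <- matrix(0, length(geoms), 1,
                dimnames = list(NULL, if (is.null(vals)) "count" else
                  paste0(value_key, "_", agg)))
  }
  for (j in seq_along(geoms)) {
    inside <- point_in_geometry(coords[, "x"], coords[, "y"], geoms[[j]])
    if (!any(inside)) next
    if (categorical) {
      tab <- table(vals[inside])
      X[j, names(tab)] <- as.numeric(tab)
    } else if (agg == "count") {
      X[j, 1] <- sum(inside)
    } else if (agg == "sum") {
      X[j, 1] <- sum(vals[inside])
    } else {
      X[j, 1] <- mean(vals[inside])
    }
  }
  aggregation_table(X, target, tgt$instance_ids)
}

# The normalization choice lives here: denominator is the source area.
# Numerator and denominator must share one discretization, or a source fully
# covered by disjoint targets would not spread exactly weight 1: when every
# geometry in the call is a circle the analytic path is used throughout;
# otherwise circles are polygonized (64-gon) for intersections AND areas.
shape_overlap_weights <- function(src_geoms, tgt_geoms) {
  all_circles <- all(vapply(c(src_geoms, tgt_geoms),
                            function(g) g$type == "circle", logical(1)))
  if (!all_circles) {
    polygonize <- function(g) {
      if (g$type == "circle") polygon(circle_ring(g$center, g$radius)) else g
    }
    src_geoms <- lapply(src_geoms, polygonize)
    tgt_geoms <- lapply(tgt_geoms, polygonize)
  }
  W <- matrix(0, length(src_geoms), length(tgt_geoms))
  areas <- vapply(src_geoms, geometry_area, numeric(1))
  if (any(areas <= 0)) stop("zero-area source geometry")
  for (i in seq_along(src_geoms)) {
    bi <- geometry_bbox(src_geoms[[i]])
    for (j in seq_along(tgt_geoms)) {
      bj <- geometry_bbox(tgt_geoms[[j]])
      if (any(bi["min", ] > bj["max", ]) || any(bj["min", ] > bi["max", ])) next
      W[i, j] <- geometry_intersection_area(src_geoms[[i]], tgt_geoms[[j]]) / areas[i]
    }
  }
  W
}

#' Aggregate shapes onto shape instances by overlap area
#'
#' For each source instance i and target instance j the weight is the shared
#' area divided by the source area. With a categorical `value_key`, the raw
#' aggregate for category c at target j is the summed weight of the
#' category-c sources; `fractions = TRUE` additionally normalizes each target
#' row to sum to 1 over categories (rows with no overlap stay all-zero and
#' are flagged in `obs$covered`). Circle-circle overlaps are analytic; other
#' circle overlaps use a 64-gon approximation.
#'
#' @param ds a `spatial_dataset`.
#' @param source,target names of `sk_shapes` elements.
#' @param value_key categorical attribute column of the source (required with
#'   `fractions`); `NULL` gives a single summed-weight column.
#' @param fractions normalize each target row to total 1?
#' @param frame coordinate system in which overlap areas are computed.
#' @return An `sk_table` annotating the target element.
#' @export
aggregate_shapes_by_shapes <- function(ds, source, target, value_key = NULL,
                                       fractions = FALSE, frame = "global") {
  src <- get_element(ds, source); tgt <- get_element(ds, target)
  if (!inherits(src, "sk_shapes") || !inherits(tgt, "sk_shapes"))
    stop("aggregate_shapes_by_shapes expects shapes source and target")
  vals <- NULL
  if (!is.null(value_key)) {
    if (is.null(src$data) || !value_key %in% names(src$data))
      stop(sprintf("source has no attribute column '%s'", value_key))
    vals <- src$data[[value_key]]
    if (!(is.factor(vals) || is.character(vals))) {
      if (fractions) stop("fractions require a categorical value_key")
    }
  } else if (fractions) stop("fractions require a categorical value_key")
  W <- shape_overlap_weights(shapes_in_frame(src, frame),
                             shapes_in_frame(tgt, frame))
  if (is.null(vals) || is.numeric(vals)) {
    w <- if (is.null(vals)) rep(1, nrow(W)) else as.numeric(vals)
    X <- matrix(colSums(W * w), ncol = 1,
                dimnames = list(NULL, if (is.null(vals)) "weight" else value_key))
  } else {
    vals <- as.factor(vals)
    cats <- levels(vals)
    X <- matrix(0, ncol(W), length(cats), dimnames = list(NULL, cats))
    for (c_i in seq_along(cats)) {
      rows <- which(vals == cats[c_i])
      if (length(rows)) X[, c_i] <- colSums(W[rows, , drop = FALSE])
    }
  }
  covered <- rowSums(X) > 0
  if (fractions) {
    X[covered, ] <- X[covered, , drop = FALSE] / rowSums(X[covered, , drop = FALSE])
  }
  tab <- aggregation_table(X, target, tgt$instance_ids)
  tab$obs$covered <- covered
  tab
}

#' Aggregate a label mask onto shape instances by pixel counting
#'
#' Fallback aggregation for raster segmentation masks: the weight of label id
#' i on target j is the fraction of i's pixels whose centers (mapped into
#' `frame`) fall inside target j.
#'
#' @inheritParams aggregate_shapes_by_shapes
#' @param source name of an `sk_labels` element.
#' @export
aggregate_labels_by_shapes <- function(ds, source, target, value_key = NULL,
                                       fractions = FALSE, frame = "global") {
  src <- get_element(ds, source); tgt <- get_element(ds, target)
  if (!inherits(src, "sk_labels") || !inherits(tgt, "sk_shapes"))
    stop("aggregate_labels_by_shapes expects a labels source and a shapes target")
  arr <- materialize(src$data)
  if (length(dim(arr)) != 2L)
    stop("pixel-counting aggregation supports 2D label masks")
  ids <- label_ids(src)
  t <- get_transformation(src, frame)
  nz <- which(arr != 0L, arr.ind = TRUE)
  centers <- cbind(x = nz[, 2] - 0.5, y = nz[, 1] - 0.5)
  mapped <- apply_transform(t, centers)
  pix_id <- arr[nz]
  tgt_geoms <- shapes_in_frame(tgt, frame)
  W <- matrix(0, length(ids), length(tgt_geoms))
  totals <- as.numeric(table(factor(pix_id, levels = ids)))
  for (j in seq_along(tgt_geoms)) {
    inside <- point_in_geometry(mapped[, "x"], mapped[, "y"], tgt_geoms[[j]])
    if (!any(inside)) next
    cnt <- table(factor(pix_id[inside], levels = ids))
    W[, j] <- as.numeric(cnt) / totals
  }
  if (is.null(value_key)) {
    X <- matrix(colSums(W), ncol = 1, dimnames = list(NULL, "weight"))
  } else {
    # value per label id from a table annotating the source is out of scope;
    # a categorical vector named by id may be passed directly
    stop("value_key is not supported for labels sources; aggregate via vectorized shapes instead")
  }
  tab <- aggregation_table(X, target, tgt$instance_ids)
  tab$obs$covered <- rowSums(X) > 0
  tab
}

aggregation_table <- function(X, target_name, instance_ids) {
  obs <- data.frame(region = rep(target_name, nrow(X)),
                    instance_id = instance_ids)
  table_element(X, obs = obs,
                var = data.frame(var_name = colnames(X)),
                region = target_name, region_key = "region",
                instance_key = "instance_id")
}

#' Zero out minor categories and renormalize fraction rows
#'
#' Display rule for composition tables: per row (target instance), categories
#' contributing less than `min_fraction` are set to zero and the row is
#' renormalized to total 1 (rows left with no mass stay zero).
#'
#' @param tab an `sk_table` of per-row fractions.
#' @param min_fraction threshold (default 0.05).
#' @return The filtered `sk_table`.
#' @export
filter_fraction_table <- function(tab, min_fraction = 0.05) {
  X <- as.matrix(tab$X)
  X[X < min_fraction] <- 0
  tot <- rowSums(X)
  nz <- tot > 0
  X[nz, ] <- X[nz, , drop = FALSE] / tot[nz]
  tab$X <- X
  tab
}

#' Store an aggregation result in a dataset
#'
#' Adds the table under `name`, or -- when `layer_of` names an existing table
#' with matching instances -- writes the matrix as a named layer of that
#' table instead.
#'
#' @param ds a `spatial_dataset`.
#' @param tab an `sk_table` (e.g. from [aggregate_points_by_shapes()]).
#' @param name name for the new table, or the layer name with `layer_of`.
#' @param layer_of optional name of an existing table to receive the matrix
#'   as a layer.
#' @return The updated dataset.
#' @export
add_aggregation_table <- function(ds, tab, name, layer_of = NULL) {
  if (is.null(layer_of)) {
    ds$tables[[name]] <- tab
    return(ds)
  }
  host <- ds$tables[[layer_of]]
  if (is.null(host)) stop(sprintf("no table named '%s'", layer_of))
  if (nrow(host$X) != nrow(tab$X))
    stop("layer host table must have matching instances")
  if (!is.null(host$instance_key) && !is.null(tab$instance_key) &&
      !identical(as.vector(host$obs[[host$instance_key]]),
                 as.vector(tab$obs[[tab$instance_key]])))
    stop("layer host table must have matching instances")
  host$layers[[name]] <- as.matrix(tab$X)
  ds$tables[[layer_of]] <- host
  ds
}
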