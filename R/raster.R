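# Raster resampling and vector-element transformation.
#
# Raster transforms use inverse mapping: each output pixel center is mapped
# back through the inverse transformation and the input is sampled there
# (nearest neighbour or n-linear interpolation); samples falling outside the
# input fill with 0. Label masks always use nearest neighbour.

#' Apply a transformation to a points or shapes element
#'
#' Point coordinates and polygon vertices are mapped through `t`; circle
#' centers are mapped and radii are multiplied by the geometric mean of the
#' absolute singular values of the linear part (so the transformed circle
#' conserves the area an ellipse would have: `pi * r'^2 = |det| * pi * r^2`).
#' Instance ids and attribute columns are preserved verbatim.
#'
#' @param e an `sk_points` or `sk_shapes` element.
#' @param t an `sk_transform` defined on the element's spatial axes.
#' @param transformations transformations mapping for the result (default:
#'   identity into `"global"`).
#' @return An element of the same kind.
#' @export
transform_vector_element <- function(e, t, transformations = NULL) {
  if (inherits(e, "sk_points")) {
    axes <- intersect(c("x", "y", "z"), names(e$data))
    coords <- apply_transform(t, as.matrix(e$data[, axes, drop = FALSE]))
    data <- e$data
    data[, axes] <- coords
    return(points_element(data, instance_ids = e$instance_ids,
                          transformations = transformations))
  }
  if (inherits(e, "sk_shapes")) {
    geoms <- lapply(e$geometries, transform_geometry, t = t)
    return(shapes_element(geoms, instance_ids = e$instance_ids, data = e$data,
                          transformations = transformations))
  }
  stop("transform_vector_element expects a points or shapes element")
}

#' Resample a raster element through a transformation
#'
#' Materializes a transformation onto a pixel grid. The output extent is a
#' half-open `[lo, hi)` range per spatial axis in the target coordinates
#' (default: the axis-aligned bounds of the transformed input extent, rounded
#' outward to integers); output pixels have unit size and the pixel at index
#' `i` has center `lo + i - 0.5`. Each output center is mapped through
#' `invert_transform(t)` and sampled from the input; out-of-bounds samples are
#' 0. The result carries a translation by `lo` into `frame`, so its position
#' in that system equals the transformed input's.
#'
#' @param e an `sk_image` or `sk_labels` element.
#' @param t an invertible `sk_transform` on the element's spatial axes.
#' @param output_extent named list of `c(lo, hi)` per spatial axis, or `NULL`.
#' @param interpolation `"nearest"` or `"linear"` (labels force nearest).
#' @param frame coordinate-system name the result is placed in.
#' @return An element of the same kind as `e`.
#' @export
transform_raster <- function(e, t, output_extent = NULL,
                             interpolation = c("nearest", "linear"),
                             frame = "global") {
  stopifnot(inherits(e, "sk_image") || inherits(e, "sk_labels"))
  interpolation <- match.arg(interpolation)
  if (inherits(e, "sk_labels")) interpolation <- "nearest"
  sp <- spatial_axes(e$axes)
  if (!transform_is_invertible(t, sp))
    stop("singular transformation: raster resampling needs an invertible map")
  arr <- materialize(e$data)
  d <- dim(arr)
  sp_dims <- d[match(sp, e$axes)]
  names(sp_dims) <- sp
  if (is.null(output_extent)) {
    corners <- as.matrix(do.call(expand.grid,
      lapply(sp_dims, function(n) c(0, n))))
    colnames(corners) <- sp
    mapped <- apply_transform(t, corners)
    output_extent <- lapply(stats::setNames(sp, sp), function(ax)
      c(floor(min(mapped[, ax])), ceiling(max(mapped[, ax]))))
  }
  lo <- vapply(output_extent[sp], `[`, numeric(1), 1L)
  hi <- vapply(output_extent[sp], `[`, numeric(1), 2L)
  out_dims <- as.integer(round(hi - lo))
  if (any(out_dims <= 0L)) stop("output extent must be positive along every axis")
  centers <- lapply(seq_along(sp), function(k) lo[k] + seq_len(out_dims[k]) - 0.5)
  grid <- as.matrix(do.call(expand.grid, centers))   # first axis varies fastest
  colnames(grid) <- sp
  src <- apply_transform(invert_transform(t), grid)
  sample_one_plane <- function(plane) {
    if (interpolation == "nearest") {
      idx <- floor(src) + 1
      ok <- rep(TRUE, nrow(idx))
      for (k in seq_along(sp)) ok <- ok & idx[, k] >= 1 & idx[, k] <= sp_dims[k]
      vals <- rep(if (is.integer(plane)) 0L else 0, nrow(idx))
      if (any(ok)) vals[ok] <- plane[idx[ok, , drop = FALSE]]
      vals
    } else {
      nlinear_sample(plane, src, sp_dims)
    }
  }
  if ("c" %in% e$axes) {
    n_ch <- d[1]
    out <- array(0, dim = c(n_ch, out_dims))
    for (ch in seq_len(n_ch)) {
      plane <- array(arr[slice.index(arr, 1) == ch], dim = sp_dims)
      out[slice.index(out, 1) == ch] <- sample_one_plane(plane)
    }
  } else {
    out <- array(sample_one_plane(arr), dim = out_dims)
  }
  offs <- stats::setNames(as.numeric(lo), sp)
  tfm <- stats::setNames(list(translation_transform(offs)), frame)
  rebuild_raster(e, out, tfm)
}

# n-linear interpolation at fractional (axis-ordered) coordinates
nlinear_sample <- function(plane, src, sp_dims) {
  d <- length(sp_dims)
  base <- floor(src - 0.5)            # pixel centers sit at i - 0.5
  frac <- (src - 0.5) - base
  vals <- numeric(nrow(src))
  for (corner in seq_len(2^d) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(d)]
    idx <- base + matrix(bits, nrow(src), d, byrow = TRUE) + 1
    w <- rep(1, nrow(src))
    for (k in seq_len(d)) w <- w * ifelse(bits[k] == 1L, frac[, k], 1 - frac[, k])
    ok <- rep(TRUE, nrow(idx))
    for (k in seq_len(d)) ok <- ok & idx[, k] >= 1 & idx[, k] <= sp_dims[k]
    v <- numeric(nrow(idx))
    if (any(ok)) v[ok] <- plane[idx[ok, , drop = FALSE]]
    vals <- vals + w * v
  }
  vals
}

# rebuild an element like `e` around a new full-resolution array, keeping the
# pyramid policy (multi-level iff the original had more than one level)
rebuild_raster <- function(e, arr, transformations) {
  pyr <- length(e$pyramid) > 1L
  if (inherits(e, "sk_image")) {
    image_element(arr, axes = e$axes, pyramid = pyr,
                  transformations = transformations)
  } else {
    labels_element(arr, axes = e$axes, pyramid = pyr,
                   transformations = transformations)
  }
}

#' Rasterize a geometry onto a pixel grid
#'
#' Marks every pixel whose center lies inside (or on the boundary of) the
#' geometry; used for raster/vector consistency checks and pixel-counting
#' aggregation.
#'
#' @param g an `sk_geometry` in intrinsic raster coordinates.
#' @param dims named `c(y = , x = )` grid size.
#' @return An integer `(y, x)` matrix mask of 0/1.
#' @export
rasterize_geometry <- function(g, dims) {
  yc <- seq_len(dims[["y"]]) - 0.5
  xc <- seq_len(dims[["x"]]) - 0.5
  grid <- expand.grid(y = yc, x = xc)
  inside <- point_in_geometry(grid$x, grid$y, g)
  matrix(as.integer(inside), nrow = dims[["y"]], ncol = dims[["x"]])
}
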