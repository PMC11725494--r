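# Generic readers for interchange formats: delimited text -> points,
# GeoJSON -> shapes, TIFF -> image/labels.

#' Read points from delimited text
#'
#' @param path CSV/TSV file.
#' @param x,y,z names of the coordinate columns in the file (z optional).
#' @param id optional column holding instance ids.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param transformations passed to [points_element()].
#' @return An `sk_points` element; non-coordinate columns become attributes.
#' @export
read_points_csv <- function(path, x = "x", y = "y", z = NULL, id = NULL,
                            sep = NULL, transformations = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = TRUE)
  cols <- c(x = x, y = y)
  if (!is.null(z)) cols <- c(cols, z = z)
  if (!all(cols %in% names(df)))
    stop(sprintf("missing coordinate column(s): %s",
                 paste(setdiff(cols, names(df)), collapse = ", ")))
  ids <- NULL
  if (!is.null(id)) {
    ids <- as.integer(df[[id]])
    df[[id]] <- NULL
  }
  names(df)[match(cols, names(df))] <- names(cols)
  points_element(df, instance_ids = ids, transformations = transformations)
}

#' Write points to delimited text
#'
#' CSV interchange is lossy for categoricals (factor levels become plain
#' strings); use the store for lossless round trips.
#'
#' @param e an `sk_points` element.
#' @param path output file.
#' @export
write_points_csv <- function(e, path) {
  df <- e$data
  df$instance_id <- e$instance_ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

geojson_coords <- function(x) {
  do.call(rbind, lapply(x, function(p) unlist(p)[1:2]))
}

#' Read shapes from GeoJSON
#'
#' Supports Polygon and MultiPolygon features; a Point feature with a
#' `radius` property becomes a circle. Feature properties become attribute
#' columns. GeoJSON axis order `(x, y)` is kept.
#'
#' @param path GeoJSON file with a FeatureCollection (or a single feature).
#' @param transformations passed to [shapes_element()].
#' @return An `sk_shapes` element.
#' @export
read_shapes_geojson <- function(path, transformations = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  gj <- read_json_file(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  geoms <- list(); props <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    g <- switch(geom$type,
      Point = {
        r <- f$properties$radius
        if (is.null(r)) stop("a Point feature needs a 'radius' property to define a circle")
        cc <- unlist(geom$coordinates)
        circle(c(x = cc[1], y = cc[2]), as.numeric(r))
      },
      Polygon = polygon(lapply(geom$coordinates, function(ring) {
        m <- geojson_coords(ring); colnames(m) <- c("x", "y"); m
      })),
      MultiPolygon = multipolygon(lapply(geom$coordinates, function(poly)
        lapply(poly, function(ring) {
          m <- geojson_coords(ring); colnames(m) <- c("x", "y"); m
        }))),
      stop(sprintf("unsupported GeoJSON geometry type '%s'", geom$type)))
    geoms[[length(geoms) + 1L]] <- g
    pr <- f$properties
    pr$radius <- NULL
    props[[length(props) + 1L]] <- pr
  }
  data <- NULL
  keys <- unique(unlist(lapply(props, names)))
  if (length(keys)) {
    data <- as.data.frame(lapply(stats::setNames(keys, keys), function(k)
      vapply(props, function(p) {
        v <- p[[k]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))))
  }
  shapes_element(geoms, data = data, transformations = transformations)
}

#' Read a raster from TIFF
#'
#' @param path TIFF file.
#' @param kind `"image"` (axes `(c, y, x)`, channels from the TIFF planes) or
#'   `"labels"` (single plane, values rounded to integers).
#' @param pyramid,transformations passed to the element constructor.
#' @return An `sk_image` or `sk_labels` element.
#' @export
read_raster_tiff <- function(path, kind = c("image", "labels"),
                             pyramid = FALSE, transformations = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (kind == "labels") {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(labels_element(array(as.integer(round(a)), dim(a)),
                          pyramid = pyramid, transformations = transformations))
  }
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a <- aperm(a, c(3, 1, 2))    # (y, x, c) -> (c, y, x)
  image_element(a, pyramid = pyramid, transformations = transformations)
}
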