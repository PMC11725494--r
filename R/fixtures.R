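# Deterministic synthetic datasets ("blobs"): a download-free stand-in with
# the same structure as an imaging-based spatial transcriptomics experiment.
# One modality bundles an intensity image (sum of Gaussian bumps + noise), a
# segmentation label mask (connected components above the 80th intensity
# percentile), categorical points whose categories form blob-centred
# territories (cell-type analog), a hexagonal lattice of circular capture
# locations plus per-blob outline polygons (capture-array analog), and a
# table annotating the label mask. All randomness flows from one seed
# through R's default generator; the ambient RNG state is saved and restored.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic blobs dataset
#'
#' @param seed integer seed; the dataset is fully deterministic given it.
#' @param image_shape `(y, x)` raster size, at least 32 per axis.
#' @param n_blobs number of Gaussian bumps (>= 1).
#' @param n_points number of points.
#' @param n_categories number of point categories (cell-type analog).
#' @param n_circles number of circular capture locations.
#' @param noise_sd standard deviation of the additive image noise (bump
#'   amplitude is 1) and, for points, the probability of a category
#'   misassignment (capped at 0.5).
#' @return A `blobs_config` list.
#' @export
blobs_config <- function(seed = 0L, image_shape = c(128L, 128L), n_blobs = 5L,
                         n_points = 1000L, n_categories = 4L, n_circles = 12L,
                         noise_sd = 0.05) {
  cfg <- list(seed = as.integer(seed), image_shape = as.integer(image_shape),
              n_blobs = as.integer(n_blobs), n_points = as.integer(n_points),
              n_categories = as.integer(n_categories),
              n_circles = as.integer(n_circles), noise_sd = noise_sd)
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 32L))
    stop("image_shape must be (y, x) with at least 32 per axis")
  if (any(c(cfg$n_blobs, cfg$n_points, cfg$n_categories, cfg$n_circles) < 1L))
    stop("all counts must be at least 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(cfg, class = "blobs_config")
}

# hexagonal lattice of circle centers covering the (y, x) extent;
# center-to-center spacing 2.4 * radius (capture-array geometry: adjacent
# spots do not touch, but one cell can straddle several)
hex_circle_centers <- function(shape, radius) {
  spacing <- 2.4 * radius
  margin <- radius + 1
  xs <- seq(margin, shape[2] - margin, by = spacing)
  ys <- seq(margin, shape[1] - margin, by = spacing * sqrt(3) / 2)
  centers <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) spacing / 2 else 0
    x <- xs + off
    x <- x[x <= shape[2] - margin]
    cbind(x = x, y = rep(ys[r], length(x)))
  }))
  centers
}

# blob centers with a minimum pairwise separation, so each bump owns a
# distinct spatial territory (the nearest-blob category rule is then pure
# inside each blob's outline by construction). Sequential rejection
# sampling; if the space is too crowded the farthest candidate is accepted.
sample_separated_centers <- function(n, nx, ny, min_sep) {
  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  for (b in seq_len(n)) {
    best <- NULL; best_d <- -Inf
    for (try in 1:200) {
      cand <- c(stats::runif(1, 0.15 * nx, 0.85 * nx),
                stats::runif(1, 0.15 * ny, 0.85 * ny))
      d <- if (b == 1L) Inf else
        min(sqrt((centers[seq_len(b - 1L), "x"] - cand[1])^2 +
                 (centers[seq_len(b - 1L), "y"] - cand[2])^2))
      if (d >= min_sep) { best <- cand; break }
      if (d > best_d) { best_d <- d; best <- cand }
    }
    centers[b, ] <- best
  }
  centers
}

octagon_ring <- function(center, radius) {
  th <- 2 * pi * (0:7) / 8
  cbind(x = center[["x"]] + radius * cos(th),
        y = center[["y"]] + radius * sin(th))
}

#' Generate the synthetic blobs dataset
#'
#' Builds one modality: image, labels, points, two shapes elements
#' (`"circles"`: the capture lattice; `"blob_polygons"`: octagonal outlines
#' around each bump, attributed with the bump's category) and a table
#' annotating the label mask with per-instance mean intensity and a category.
#'
#' @param cfg a [blobs_config()].
#' @return A validated `spatial_dataset`.
#' @examples
#' ds <- generate_blobs(blobs_config(seed = 1))
#' validate_dataset(ds)
#' @export
generate_blobs <- function(cfg = blobs_config()) {
  stopifnot(inherits(cfg, "blobs_config"))
  with_seed(cfg$seed, {
    ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
    sigma <- min(ny, nx) / 12
    centers <- sample_separated_centers(cfg$n_blobs, nx, ny, 3 * sigma)
    yc <- seq_len(ny) - 0.5; xc <- seq_len(nx) - 0.5
    img <- matrix(0, ny, nx)
    for (b in seq_len(cfg$n_blobs)) {
      gy <- exp(-(yc - centers[b, "y"])^2 / (2 * sigma^2))
      gx <- exp(-(xc - centers[b, "x"])^2 / (2 * sigma^2))
      img <- img + outer(gy, gx)
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(ny * nx, sd = cfg$noise_sd), ny, nx)
    image <- image_element(array(img, c(1L, ny, nx)), pyramid = TRUE)

    thr <- stats::quantile(img, 0.8)
    mask <- matrix(as.integer(img > thr), ny, nx)
    lab <- EBImage::bwlabel(mask)
    labels <- labels_element(array(as.integer(lab), c(ny, nx)), pyramid = TRUE)

    px <- stats::runif(cfg$n_points, 0, nx)
    py <- stats::runif(cfg$n_points, 0, ny)
    cat_levels <- paste0("ct", seq_len(cfg$n_categories))
    blob_cat <- ((seq_len(cfg$n_blobs) - 1L) %% cfg$n_categories) + 1L
    nearest <- apply(outer(px, centers[, "x"], `-`)^2 +
                     outer(py, centers[, "y"], `-`)^2, 1, which.min)
    cat_idx <- blob_cat[nearest]
    p_flip <- min(0.5, cfg$noise_sd)
    if (p_flip > 0) {
      flip <- stats::runif(cfg$n_points) < p_flip
      cat_idx[flip] <- sample.int(cfg$n_categories, sum(flip), replace = TRUE)
    }
    points <- points_element(data.frame(
      x = px, y = py,
      category = factor(cat_levels[cat_idx], levels = cat_levels)))

    radius <- min(ny, nx) / 24
    hex <- hex_circle_centers(cfg$image_shape, radius)
    if (nrow(hex) < cfg$n_circles)
      stop(sprintf("degenerate config: lattice supplies only %d circles", nrow(hex)))
    circles <- shapes_element(lapply(seq_len(cfg$n_circles), function(i)
      circle(c(x = unname(hex[i, "x"]), y = unname(hex[i, "y"])), radius)))

    blob_polys <- shapes_element(
      lapply(seq_len(cfg$n_blobs), function(b)
        polygon(octagon_ring(centers[b, ], 2 * sigma))),
      data = data.frame(category = factor(cat_levels[blob_cat],
                                          levels = cat_levels)))

    ids <- sort(unique(as.integer(lab[lab != 0])))
    comp_stats <- do.call(rbind, lapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      c(mean_intensity = mean(img[lab == id]),
        cy = mean(w[, 1] - 0.5), cx = mean(w[, 2] - 0.5))
    }))
    comp_nearest <- apply(outer(comp_stats[, "cx"], centers[, "x"], `-`)^2 +
                          outer(comp_stats[, "cy"], centers[, "y"], `-`)^2,
                          1, which.min)
    tab <- table_element(
      X = matrix(comp_stats[, "mean_intensity"], ncol = 1,
                 dimnames = list(NULL, "mean_intensity")),
      obs = data.frame(region = rep("blob_labels", length(ids)),
                       instance_id = ids,
                       category = factor(cat_levels[blob_cat[comp_nearest]],
                                         levels = cat_levels)),
      region = "blob_labels", region_key = "region",
      instance_key = "instance_id")

    ds <- spatial_dataset(
      images = list(blob_image = image),
      labels = list(blob_labels = labels),
      points = list(transcripts = points),
      shapes = list(circles = circles, blob_polygons = blob_polys),
      tables = list(blob_annotation = tab))
    attr(ds, "blob_centers") <- centers
    ds
  })
}

#' Generate a pair of modalities related by a known transform
#'
#' Returns the blobs dataset together with a second copy whose vector
#' elements are mapped through `true_transform` and whose rasters are
#' resampled through it -- a toy replica of registering two replicate slides.
#' Blob centers serve as landmarks, expressed in each modality's frame.
#' Estimating the moving-to-reference transform from the returned landmarks
#' recovers `$true_matrix` (the inverse of `true_transform` on `(x, y)`).
#'
#' @param cfg a [blobs_config()]; needs `n_blobs >= 3` (non-collinear
#'   landmarks).
#' @param true_transform an invertible `sk_transform` on `(x, y)` mapping the
#'   reference frame into the moving frame.
#' @return A list with `reference` and `moving` datasets,
#'   `reference_landmarks`, `moving_landmarks`, `true_transform` and
#'   `true_matrix` (ground-truth moving-to-reference homogeneous matrix).
#' @export
generate_aligned_pair <- function(cfg = blobs_config(),
                                  true_transform = identity_transform()) {
  if (!transform_is_invertible(true_transform, c("x", "y")))
    stop("true_transform must be invertible")
  ref <- generate_blobs(cfg)
  centers <- attr(ref, "blob_centers")
  if (nrow(centers) < 3L) stop("need at least 3 blobs to derive landmarks")
  mov <- ref
  for (k in c("points", "shapes")) {
    for (nm in names(ref[[k]])) {
      mov[[k]][[nm]] <- transform_vector_element(ref[[k]][[nm]], true_transform)
      mov[[k]][[nm]]$transformations <- list(global = identity_transform())
    }
  }
  for (k in c("images", "labels")) {
    for (nm in names(ref[[k]])) {
      e <- transform_raster(ref[[k]][[nm]], true_transform,
                            interpolation = "nearest", frame = "global")
      mov[[k]][[nm]] <- e
    }
  }
  # resampling can drop a tiny component at the raster boundary; keep the
  # moving table consistent with the resampled mask
  for (tn in names(mov$tables)) {
    tab <- mov$tables[[tn]]
    if (is.null(tab$region)) next
    keep <- logical(nrow(tab$obs))
    regions <- as.character(tab$obs[[tab$region_key]])
    for (rn in unique(regions)) {
      ids <- element_instance_ids(get_element(mov, rn))
      keep[regions == rn & tab$obs[[tab$instance_key]] %in% ids] <- TRUE
    }
    mov$tables[[tn]] <- subset_table(tab, which(keep))
  }
  moved_centers <- apply_transform(true_transform, centers)
  list(reference = ref,
       moving = mov,
       reference_landmarks = landmark_set(centers, frame = "global"),
       moving_landmarks = landmark_set(moved_centers, frame = "global"),
       true_transform = true_transform,
       true_matrix = to_affine_matrix(invert_transform(true_transform),
                                      c("x", "y")))
}
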