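# Landmark-based registration: estimate an affine or similarity transform
# from paired landmarks and register dataset elements into a shared
# coordinate system. Landmarks are selected in the same order on each
# modality with a 1-to-1 spatial correspondence; the operation works purely
# on coordinates and never touches raster data.

.SK_RANK_TOL <- 1e-10

#' Landmark sets
#'
#' An ordered list of 2D/3D coordinates expressed in a named coordinate
#' system. Two landmark sets used together must have equal length and be
#' order-matched pairs.
#'
#' @param points numeric matrix (or data.frame) with columns `x`, `y`
#'   (optionally `z`).
#' @param frame name of the coordinate system the points live in.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(points, frame = "global") {
  points <- as.matrix(as.data.frame(points))
  if (is.null(colnames(points))) colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  axes <- intersect(c("x", "y", "z"), colnames(points))
  if (!all(c("x", "y") %in% axes)) stop("landmarks need columns x and y")
  points <- points[, axes, drop = FALSE]
  if (nrow(points) < 1L || any(!is.finite(points)))
    stop("landmarks must contain at least one finite point")
  structure(list(points = points, frame = frame), class = "landmark_set")
}

#' Estimate a transform from paired landmarks
#'
#' Fits the transformation mapping `moving` landmarks onto `reference`
#' landmarks. `model = "affine"` is an ordinary least-squares homogeneous fit
#' minimizing the summed squared residuals; `model = "similarity"` is the
#' orthogonal-Procrustes closed form (rotation + isotropic scale +
#' translation), with reflections forbidden unless `allow_reflection` is set.
#' The default model is affine, which tolerates the shear that consecutive
#' tissue sections can exhibit.
#'
#' @param moving,reference `landmark_set`s (or coordinate matrices) of equal
#'   length, order-matched.
#' @param model `"affine"` or `"similarity"`.
#' @param allow_reflection permit a reflection in the similarity fit?
#' @return A list with `transform` (an affine `sk_transform` mapping moving
#'   into reference coordinates) and `rmsd` (root-mean-square residual after
#'   fitting).
#' @examples
#' mv <- landmark_set(cbind(x = c(0, 1, 0), y = c(0, 0, 1)))
#' rf <- landmark_set(cbind(x = c(1, 2, 1), y = c(1, 1, 2)))
#' estimate_transform_from_landmarks(mv, rf)$rmsd
#' @export
estimate_transform_from_landmarks <- function(moving, reference,
                                              model = c("affine", "similarity"),
                                              allow_reflection = FALSE) {
  model <- match.arg(model)
  if (!inherits(moving, "landmark_set")) moving <- landmark_set(moving)
  if (!inherits(reference, "landmark_set")) reference <- landmark_set(reference)
  M <- moving$points; R <- reference$points
  if (nrow(M) != nrow(R) || ncol(M) != ncol(R))
    stop("moving and reference landmarks must be matched 1-to-1 (equal count and dimension)")
  d <- ncol(M); n <- nrow(M)
  axes <- colnames(M)
  if (n < d + 1L)
    stop(sprintf("at least %d landmark pairs are required for a %dD fit", d + 1L, d))
  if (model == "affine") {
    X <- cbind(M, 1)
    qrX <- qr(X, tol = .SK_RANK_TOL)
    if (qrX$rank < d + 1L)
      stop("degenerate landmark configuration: points are collinear/coplanar")
    B <- qr.coef(qrX, R)                       # (d+1) x d; rows: coef per input
    A <- rbind(cbind(t(B[seq_len(d), , drop = FALSE]), B[d + 1L, ]),
               c(rep(0, d), 1))
  } else {
    mu_m <- colMeans(M); mu_r <- colMeans(R)
    Mc <- sweep(M, 2, mu_m); Rc <- sweep(R, 2, mu_r)
    S <- crossprod(Rc, Mc) / n                  # d x d cross-covariance
    sv <- svd(S)
    sgn <- rep(1, d)
    if (!allow_reflection && det(sv$u) * det(sv$v) < 0) sgn[d] <- -1
    rot <- sv$u %*% diag(sgn, d) %*% t(sv$v)
    var_m <- sum(Mc^2) / n
    if (var_m < .SK_RANK_TOL)
      stop("degenerate landmark configuration: moving points are coincident")
    s <- sum(sv$d * sgn) / var_m
    tr <- mu_r - s * as.vector(rot %*% mu_m)
    A <- rbind(cbind(s * rot, tr), c(rep(0, d), 1))
  }
  t_est <- affine_transform(A, input_axes = axes, output_axes = axes)
  fitted <- apply_transform(t_est, M)
  rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  list(transform = t_est, rmsd = rmsd)
}

#' Register dataset elements using landmarks
#'
#' Estimates the moving-to-reference transform from the landmark pairs and
#' assigns, to every named moving element, a transformation into
#' `target_system` equal to `compose(existing transform into the moving
#' landmarks' frame, estimated transform)`. Mapping the moving landmarks
#' through the assigned transform reproduces the reference landmarks within
#' the fitted rmsd.
#'
#' @param ds a `spatial_dataset` holding the moving elements.
#' @param moving_elements character vector of element names to register.
#' @param moving_landmarks,reference_landmarks `landmark_set`s; the moving set
#'   is expressed in a frame every moving element can reach.
#' @param target_system name of the common coordinate system to create.
#' @param model passed to [estimate_transform_from_landmarks()].
#' @return The dataset with updated element transformations; the fit is
#'   attached as attribute `"alignment"` (transform and rmsd).
#' @export
align_elements_using_landmarks <- function(ds, moving_elements,
                                           moving_landmarks, reference_landmarks,
                                           target_system = "aligned",
                                           model = c("affine", "similarity")) {
  fit <- estimate_transform_from_landmarks(moving_landmarks, reference_landmarks,
                                           model = model)
  frame <- if (inherits(moving_landmarks, "landmark_set")) moving_landmarks$frame else "global"
  for (nm in moving_elements) {
    found <- FALSE
    for (k in c("images", "labels", "points", "shapes")) {
      if (nm %in% names(ds[[k]])) {
        e <- ds[[k]][[nm]]
        base <- e$transformations[[frame]]
        if (is.null(base))
          stop(sprintf("element '%s' has no transformation into the landmarks' frame '%s'",
                       nm, frame))
        ds[[k]][[nm]] <- set_transformation(
          e, target_system, compose_transforms(base, fit$transform))
        found <- TRUE
        break
      }
    }
    if (!found) stop(sprintf("no element named '%s' in the dataset", nm))
  }
  attr(ds, "alignment") <- fit
  ds
}

#' Read and write landmark files
#'
#' Landmarks travel as delimited text (columns `x,y[,z]`, one landmark per
#' row, header optional) or as GeoJSON point collections.
#'
#' @param path file path (`.csv`/`.tsv`/`.txt` or `.geojson`/`.json`).
#' @param frame coordinate-system name to attach.
#' @param landmarks a `landmark_set` (for writing).
#' @return `read_landmarks`: a `landmark_set`.
#' @export
read_landmarks <- function(path, frame = "global") {
  if (!file.exists(path)) stop(sprintf("landmark file '%s' does not exist", path))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- read_json_file(path)
    feats <- if (!is.null(gj$features)) gj$features else gj$geometries
    pts <- do.call(rbind, lapply(feats, function(f) {
      geom <- if (!is.null(f$geometry)) f$geometry else f
      if (geom$type != "Point") stop("landmark GeoJSON must contain Point features")
      unlist(geom$coordinates)
    }))
    colnames(pts) <- c("x", "y", "z")[seq_len(ncol(pts))]
    return(landmark_set(pts, frame))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = sep)
  if (!has_header) colnames(df) <- c("x", "y", "z")[seq_len(ncol(df))]
  landmark_set(df, frame)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks$points), path, row.names = FALSE)
  invisible(path)
}
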