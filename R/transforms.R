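# Coordinate transformations over named axes.
#
# A transformation is an algebraic object (identity, scale, translation,
# affine, or a sequence of these) defined over named spatial axes. All
# operations resolve axes by NAME, never by position, so a 2D transform can be
# applied to a (c, y, x) raster acting on (y, x) only. Sequences apply
# left-to-right: the first member acts first.

.SK_SPATIAL_AXES <- c("z", "y", "x")
.SK_DET_TOL <- 1e-12

#' Coordinate transformations
#'
#' Constructors for the transformation variants used throughout the package:
#' `identity_transform()`, `scale_transform()`, `translation_transform()`,
#' `affine_transform()` and `sequence_transform()`. Scale factors and
#' translation offsets are named numeric vectors (names are axis names, e.g.
#' `c(x = 2, y = 3)`); axes a transformation does not mention pass through
#' unchanged when it is applied.
#'
#' @param factors named numeric vector of per-axis scale factors (nonzero).
#' @param offsets named numeric vector of per-axis offsets.
#' @param matrix homogeneous matrix of shape `(d_out + 1) x (d_in + 1)` whose
#'   last row is `(0, ..., 0, 1)`.
#' @param input_axes,output_axes character vectors naming the axes the matrix
#'   rows/columns refer to.
#' @param transforms list of transformations, applied left-to-right.
#' @return An object of class `sk_transform`.
#' @examples
#' t <- compose_transforms(scale_transform(c(x = 2, y = 2)),
#'                         translation_transform(c(x = 5, y = 7)))
#' to_affine_matrix(t, c("x", "y"))
#' @name transforms
NULL

new_transform <- function(type, fields = list()) {
  structure(c(list(type = type), fields),
            class = c(paste0("sk_", type), "sk_transform"))
}

#' @rdname transforms
#' @export
identity_transform <- function() new_transform("identity")

#' @rdname transforms
#' @export
scale_transform <- function(factors) {
  check_named_numeric(factors, "factors")
  if (any(factors == 0)) stop("scale factors must be nonzero")
  new_transform("scale", list(factors = factors))
}

#' @rdname transforms
#' @export
translation_transform <- function(offsets) {
  check_named_numeric(offsets, "offsets")
  new_transform("translation", list(offsets = offsets))
}

#' @rdname transforms
#' @export
affine_transform <- function(matrix, input_axes, output_axes = input_axes) {
  stopifnot(is.matrix(matrix), is.character(input_axes), is.character(output_axes))
  if (nrow(matrix) != length(output_axes) + 1L ||
      ncol(matrix) != length(input_axes) + 1L)
    stop("affine matrix must be (d_out + 1) x (d_in + 1)")
  last <- matrix[nrow(matrix), ]
  if (any(abs(last - c(rep(0, ncol(matrix) - 1L), 1)) > 1e-12))
    stop("last row of a homogeneous affine matrix must be (0, ..., 0, 1)")
  dimnames(matrix) <- NULL
  new_transform("affine", list(matrix = matrix,
                               input_axes = input_axes,
                               output_axes = output_axes))
}

#' @rdname transforms
#' @export
sequence_transform <- function(transforms) {
  stopifnot(is.list(transforms), length(transforms) >= 1L)
  for (t in transforms) stopifnot(inherits(t, "sk_transform"))
  # flatten nested sequences so composition stays associative by construction
  flat <- list()
  for (t in transforms) {
    if (t$type == "sequence") flat <- c(flat, t$transforms) else flat <- c(flat, list(t))
  }
  new_transform("sequence", list(transforms = flat))
}

check_named_numeric <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))) ||
      anyDuplicated(names(x)))
    stop(sprintf("%s must be a named numeric vector with unique axis names", what))
  if (any(!is.finite(x))) stop(sprintf("%s must be finite", what))
  invisible(x)
}

#' @export
print.sk_transform <- function(x, ...) {
  switch(x$type,
    identity = cat("<identity transform>\n"),
    scale = cat("<scale transform> ",
                paste(names(x$factors), x$factors, sep = "=", collapse = ", "), "\n"),
    translation = cat("<translation transform> ",
                      paste(names(x$offsets), x$offsets, sep = "=", collapse = ", "), "\n"),
    affine = {
      cat("<affine transform> (", paste(x$input_axes, collapse = ","), ") -> (",
          paste(x$output_axes, collapse = ","), ")\n", sep = "")
      print(x$matrix)
    },
    sequence = {
      cat("<transform sequence> of", length(x$transforms), "steps (applied first to last)\n")
      for (t in x$transforms) print(t)
    })
  invisible(x)
}

#' Express a transformation as a homogeneous affine matrix
#'
#' Returns the unique `(d_out + 1) x (d_in + 1)` homogeneous matrix that, when
#' applied to homogeneous coordinate vectors ordered as `output_axes` /
#' `input_axes`, equals applying `t`. Axes that `t` does not mention pass
#' through unchanged; requesting an axis `t` cannot supply is an error.
#'
#' @param t an `sk_transform`.
#' @param input_axes character vector of input axis names.
#' @param output_axes character vector of output axis names (default: same as
#'   input).
#' @return A numeric homogeneous matrix with dimnames set to the axes.
#' @export
to_affine_matrix <- function(t, input_axes, output_axes = input_axes) {
  stopifnot(inherits(t, "sk_transform"))
  m <- switch(t$type,
    identity = passthrough_matrix(input_axes, output_axes),
    scale = {
      m <- passthrough_matrix(input_axes, output_axes)
      for (ax in names(t$factors)) {
        if (!(ax %in% input_axes) || !(ax %in% output_axes))
          stop(sprintf("scale transform touches axis '%s' absent from the requested axes", ax))
        m[match(ax, output_axes), match(ax, input_axes)] <- t$factors[[ax]]
      }
      m
    },
    translation = {
      m <- passthrough_matrix(input_axes, output_axes)
      for (ax in names(t$offsets)) {
        if (!(ax %in% output_axes))
          stop(sprintf("translation touches axis '%s' absent from the requested axes", ax))
        m[match(ax, output_axes), length(input_axes) + 1L] <- t$offsets[[ax]]
      }
      m
    },
    affine = affine_on_axes(t, input_axes, output_axes),
    sequence = {
      # members are evaluated on the common axis set; adjacent members must be
      # expressible on it (the supported compatibility contract)
      m <- diag(length(input_axes) + 1L)
      axes <- input_axes
      for (step in t$transforms) {
        m <- to_affine_matrix(step, axes, axes) %*% m
      }
      if (!identical(output_axes, input_axes)) {
        m <- passthrough_matrix(input_axes, output_axes) %*% m
      }
      m
    })
  dimnames(m) <- list(c(output_axes, "1"), c(input_axes, "1"))
  m
}

passthrough_matrix <- function(input_axes, output_axes) {
  m <- matrix(0, length(output_axes) + 1L, length(input_axes) + 1L)
  m[nrow(m), ncol(m)] <- 1
  for (ax in output_axes) {
    j <- match(ax, input_axes)
    if (is.na(j))
      stop(sprintf("axis '%s' requested as output cannot be supplied from the inputs", ax))
    m[match(ax, output_axes), j] <- 1
  }
  m
}

affine_on_axes <- function(t, input_axes, output_axes) {
  if (!all(t$input_axes %in% input_axes))
    stop("affine transform requires input axes absent from the requested axes")
  m <- matrix(0, length(output_axes) + 1L, length(input_axes) + 1L)
  m[nrow(m), ncol(m)] <- 1
  for (ax in output_axes) {
    i <- match(ax, output_axes)
    k <- match(ax, t$output_axes)
    if (!is.na(k)) {
      m[i, match(t$input_axes, input_axes)] <- t$matrix[k, seq_along(t$input_axes)]
      m[i, length(input_axes) + 1L] <- t$matrix[k, ncol(t$matrix)]
    } else if (ax %in% input_axes) {
      m[i, match(ax, input_axes)] <- 1
    } else {
      stop(sprintf("axis '%s' requested as output cannot be supplied", ax))
    }
  }
  m
}

#' Compose transformations
#'
#' `compose_transforms(first, second)` returns a transformation `t` with
#' `t(p) = second(first(p))`: the first argument acts first. Any number of
#' transformations may be given and are applied left-to-right.
#'
#' @param ... transformations, applied in the order given.
#' @return An `sk_transform` (a flattened sequence, or the single member).
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "sk_transform"))
    ts <- ts[[1]]
  if (length(ts) == 0L) return(identity_transform())
  if (length(ts) == 1L) return(ts[[1]])
  sequence_transform(ts)
}

#' Invert a transformation
#'
#' Returns a transformation `s` with `compose_transforms(t, s)` equal to the
#' identity on any finite point. Errors if the linear part is singular
#' (absolute determinant below `1e-12`).
#'
#' @param t an `sk_transform`.
#' @return An `sk_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "sk_transform"))
  switch(t$type,
    identity = t,
    scale = scale_transform(1 / t$factors),
    translation = translation_transform(-t$offsets),
    affine = {
      if (length(t$input_axes) != length(t$output_axes))
        stop("only square affine transforms are invertible")
      d <- length(t$input_axes)
      lin <- t$matrix[seq_len(d), seq_len(d), drop = FALSE]
      if (abs(det(lin)) < .SK_DET_TOL)
        stop("singular transformation: |det| of the linear part is below 1e-12")
      affine_transform(solve(t$matrix), t$output_axes, t$input_axes)
    },
    sequence = sequence_transform(lapply(rev(t$transforms), invert_transform)))
}

#' Apply a transformation to coordinate rows
#'
#' @param t an `sk_transform`.
#' @param coords numeric matrix (or data.frame) whose columns are named after
#'   axes (e.g. `x`, `y`).
#' @return A numeric matrix of the same shape with transformed coordinates.
#' @export
apply_transform <- function(t, coords) {
  coords <- as.matrix(coords)
  axes <- colnames(coords)
  if (is.null(axes)) stop("coords must have axis names as column names")
  m <- to_affine_matrix(t, axes, axes)
  out <- cbind(coords, 1) %*% t(m)
  out <- out[, seq_along(axes), drop = FALSE]
  colnames(out) <- axes
  out
}

# Linear part of t restricted to the given axes (no translation).
linear_part <- function(t, axes) {
  m <- to_affine_matrix(t, axes, axes)
  m[seq_along(axes), seq_along(axes), drop = FALSE]
}

transform_is_invertible <- function(t, axes) {
  ok <- tryCatch(abs(det(linear_part(t, axes))) >= .SK_DET_TOL,
                 error = function(e) FALSE)
  isTRUE(ok)
}

#' Serialize / deserialize transformations
#'
#' Transformations serialize to typed records (`type` plus parameters) used in
#' per-element store metadata; identity/scale/translation follow the OME-NGFF
#' coordinateTransformations vocabulary and affine matrices travel in the same
#' record as a documented extension.
#'
#' @param t an `sk_transform` (for `transform_to_list`).
#' @param x a list as produced by `transform_to_list`.
#' @return `transform_to_list`: a plain list; `transform_from_list`: an
#'   `sk_transform`.
#' @keywords internal
#' @export
transform_to_list <- function(t) {
  switch(t$type,
    identity = list(type = "identity"),
    scale = list(type = "scale", scale = as.list(t$factors)),
    translation = list(type = "translation", translation = as.list(t$offsets)),
    affine = list(type = "affine",
                  affine = apply(t$matrix, 1, as.list),
                  input_axes = as.list(t$input_axes),
                  output_axes = as.list(t$output_axes)),
    sequence = list(type = "sequence",
                    transformations = lapply(t$transforms, transform_to_list)))
}

#' @rdname transform_to_list
#' @export
transform_from_list <- function(x) {
  switch(x$type,
    identity = identity_transform(),
    scale = scale_transform(unlist(x$scale)),
    translation = translation_transform(unlist(x$translation)),
    affine = {
      m <- do.call(rbind, lapply(x$affine, function(r) unlist(r)))
      affine_transform(m, unlist(x$input_axes), unlist(x$output_axes))
    },
    sequence = sequence_transform(lapply(x$transformations, transform_from_list)),
    stop(sprintf("unknown transformation type '%s'", x$type)))
}
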