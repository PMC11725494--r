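# Shared helpers: tiny geometry builders, random transforms and brute-force
# oracles used across test files. Oracles are deliberately naive (O(n*m)
# loops, stepwise evaluation) and independent of the package internals they
# check.

square_poly <- function(x0, y0, x1, y1) {
  polygon(cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}

rotation_affine <- function(theta, scale = 1, tx = 0, ty = 0) {
  affine_transform(matrix(c(cos(theta) * scale, -sin(theta) * scale, tx,
                            sin(theta) * scale,  cos(theta) * scale, ty,
                            0, 0, 1), 3, byrow = TRUE), c("x", "y"))
}

random_affine2d <- function(max_perturb = 0.5, max_shift = 5) {
  repeat {
    lin <- diag(2) + matrix(runif(4, -max_perturb, max_perturb), 2)
    if (abs(det(lin)) > 0.1) break
  }
  affine_transform(rbind(cbind(lin, runif(2, -max_shift, max_shift)),
                         c(0, 0, 1)), c("x", "y"))
}

random_transform <- function() {
  switch(sample(3, 1),
         scale_transform(c(x = runif(1, 0.5, 2), y = runif(1, 0.5, 2))),
         translation_transform(c(x = runif(1, -5, 5), y = runif(1, -5, 5))),
         random_affine2d())
}

# stepwise application of a list of transforms (the independent oracle for
# matrix composition)
apply_stepwise <- function(transforms, coords) {
  for (t in transforms) coords <- apply_transform(t, coords)
  coords
}

# brute-force point-in-closed-box / point-in-polygon filters
oracle_in_box <- function(coords, lo, hi) {
  keep <- rep(TRUE, nrow(coords))
  for (ax in names(lo)) {
    keep <- keep & coords[, ax] >= lo[[ax]] & coords[, ax] < hi[[ax]]
  }
  keep
}

# even-odd ray casting, one point at a time, plus explicit edge checks
oracle_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[if (k == n) 1L else k + 1L, ]
    # on-edge check
    cross <- (b["x"] - a["x"]) * (py - a["y"]) - (b["y"] - a["y"]) * (px - a["x"])
    dot <- (px - a["x"]) * (b["x"] - a["x"]) + (py - a["y"]) * (b["y"] - a["y"])
    len2 <- sum((b - a)^2)
    if (abs(cross) < 1e-9 && dot >= -1e-9 && dot <= len2 + 1e-9) return(TRUE)
    if ((a["y"] > py) != (b["y"] > py)) {
      xint <- a["x"] + (py - a["y"]) * (b["x"] - a["x"]) / (b["y"] - a["y"])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

small_cfg <- function(seed = 1) {
  blobs_config(seed = seed, image_shape = c(96L, 96L), n_blobs = 4L,
               n_points = 400L, n_categories = 3L, n_circles = 8L,
               noise_sd = 0.02)
}
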