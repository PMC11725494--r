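test_that("affine matrices of the basic variants are correct", {
  expect_equal(unname(to_affine_matrix(identity_transform(), c("x", "y"))),
               diag(3))
  expect_equal(unname(to_affine_matrix(scale_transform(c(x = 2, y = 3)),
                                       c("x", "y"))),
               diag(c(2, 3, 1)))
  m <- to_affine_matrix(translation_transform(c(x = 5, y = 7)), c("x", "y"))
  expect_equal(unname(m[1:2, 3]), c(5, 7))
  # sequence: scale then translate; expected matrix derived by stepwise
  # evaluation of the unit vectors (0,0), (1,0), (0,1)
  sq <- sequence_transform(list(scale_transform(c(x = 2, y = 2)),
                                translation_transform(c(x = 5, y = 7))))
  basis <- rbind(c(0, 0), c(1, 0), c(0, 1))
  colnames(basis) <- c("x", "y")
  stepped <- apply_stepwise(sq$transforms, basis)
  expected <- rbind(cbind(t(stepped[2:3, ] - rep(stepped[1, ], each = 2)),
                          stepped[1, ]), c(0, 0, 1))
  expect_equal(unname(to_affine_matrix(sq, c("x", "y"))), unname(expected))
})

test_that("axes a transform does not touch pass through; missing axes error", {
  t <- scale_transform(c(x = 2))
  m <- to_affine_matrix(t, c("x", "y"))
  expect_equal(unname(m), diag(c(2, 1, 1)))
  expect_error(to_affine_matrix(t, c("y", "z")), "absent")
  # output axis that no input can supply
  expect_error(to_affine_matrix(identity_transform(), "x", c("x", "y")),
               "cannot be supplied")
})

test_that("composition applies left-to-right and is associative", {
  p <- matrix(c(1, 0), 1, dimnames = list(NULL, c("x", "y")))
  t <- compose_transforms(scale_transform(c(x = 2)),
                          translation_transform(c(x = 1)))
  expect_equal(apply_transform(t, p)[1, "x"], c(x = 3))  # scale first
  set.seed(11)
  pts <- matrix(runif(200, -10, 10), 100, dimnames = list(NULL, c("x", "y")))
  tid <- compose_transforms(identity_transform(), random_affine2d())
  expect_equal(apply_transform(tid, pts),
               apply_transform(tid$transforms[[2]], pts), tolerance = 1e-12)
  expect_equal(apply_transform(compose_transforms(
    translation_transform(c(x = 3, y = -1)),
    translation_transform(c(x = -3, y = 1))), pts), pts, tolerance = 1e-12)
  a <- random_transform(); b <- random_transform(); c_ <- random_transform()
  left <- compose_transforms(compose_transforms(a, b), c_)
  right <- compose_transforms(a, compose_transforms(b, c_))
  expect_lt(max(abs(apply_transform(left, pts) - apply_transform(right, pts))),
            1e-9)
})

test_that("matrix application equals stepwise application for random sequences", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    ts <- replicate(n, random_transform(), simplify = FALSE)
    seqt <- sequence_transform(ts)
    pts <- matrix(runif(20, -20, 20), 10, dimnames = list(NULL, c("x", "y")))
    expect_lt(max(abs(apply_transform(seqt, pts) - apply_stepwise(ts, pts))),
              1e-9)
  }
})

test_that("inversion round-trips and rejects singular maps", {
  expect_equal(invert_transform(translation_transform(c(x = 3, y = -1)))$offsets,
               c(x = -3, y = 1))
  expect_equal(invert_transform(scale_transform(c(x = 2, y = 4)))$factors,
               c(x = 0.5, y = 0.25))
  set.seed(31)
  for (rep in 1:50) {
    t <- random_transform()
    pts <- matrix(runif(20, -20, 20), 10, dimnames = list(NULL, c("x", "y")))
    round_trip <- apply_transform(compose_transforms(t, invert_transform(t)), pts)
    expect_lt(max(abs(round_trip - pts)), 1e-9)
  }
  singular <- affine_transform(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 1), 3,
                                      byrow = TRUE), c("x", "y"))
  expect_error(invert_transform(singular), "singular")
})

test_that("vector elements transform coordinates but keep ids and attributes", {
  pts <- points_element(data.frame(x = 1, y = 2, gene = factor("g1")),
                        instance_ids = 7L)
  out <- transform_vector_element(pts, translation_transform(c(x = 10, y = 20)))
  expect_equal(out$data$x, 11)
  expect_equal(out$data$y, 22)
  expect_identical(out$instance_ids, 7L)
  expect_identical(out$data$gene, factor("g1"))
})

test_that("circle radii follow the geometric-mean singular-value rule", {
  c0 <- circle(c(x = 0, y = 0), 1)
  iso <- transform_geometry(c0, scale_transform(c(x = 2, y = 2)))
  expect_equal(iso$radius, 2)
  expect_equal(unname(iso$center), c(0, 0))
  aniso <- transform_geometry(c0, scale_transform(c(x = 2, y = 3)))
  expect_equal(aniso$radius, sqrt(6), tolerance = 1e-12)
  # the rule conserves area under any anisotropic linear map
  set.seed(41)
  for (rep in 1:20) {
    t <- random_affine2d()
    r2 <- transform_geometry(c0, t)$radius
    expect_equal(pi * r2^2,
                 abs(det(to_affine_matrix(t, c("x", "y"))[1:2, 1:2])) * pi,
                 tolerance = 1e-9)
  }
})

test_that("raster resampling matches literal and brute-force expectations", {
  img <- image_element(array(as.numeric(1:4), c(1, 2, 2)))
  same <- transform_raster(img, identity_transform(),
                           output_extent = list(y = c(0, 2), x = c(0, 2)))
  expect_equal(materialize(same$data), materialize(img$data))
  up <- transform_raster(img, scale_transform(c(y = 2, x = 2)),
                         output_extent = list(y = c(0, 4), x = c(0, 4)))
  # each input pixel becomes a 2x2 block (derived by enumerating the 16
  # output centers under the inverse scale)
  a <- materialize(img$data)[1, , ]
  expect_equal(materialize(up$data)[1, , ],
               a[rep(1:2, each = 2), rep(1:2, each = 2)])
  # 90 degree rotation of an asymmetric 2x3 array vs a per-pixel oracle
  arr <- array(as.numeric(1:6), c(1, 2, 3))
  rot <- rotation_affine(pi / 2, tx = 0, ty = 0)
  out <- transform_raster(image_element(arr), rot, interpolation = "nearest")
  oracle <- {
    corners <- expand.grid(x = c(0, 3), y = c(0, 2))
    mc <- apply_transform(rot, as.matrix(corners))
    lo <- floor(apply(mc, 2, min)); hi <- ceiling(apply(mc, 2, max))
    o <- matrix(0, unname(hi["y"] - lo["y"]), unname(hi["x"] - lo["x"]))
    inv <- to_affine_matrix(invert_transform(rot), c("x", "y"))
    for (i in seq_len(nrow(o))) for (j in seq_len(ncol(o))) {
      c_out <- c(lo["x"] + j - 0.5, lo["y"] + i - 0.5, 1)
      c_in <- inv %*% c_out
      ii <- floor(c_in[2]) + 1; jj <- floor(c_in[1]) + 1
      if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 3) o[i, j] <- arr[1, ii, jj]
    }
    o
  }
  expect_equal(materialize(out$data)[1, , ], unname(oracle))
  expect_error(transform_raster(image_element(array(0, c(1, 4, 4))),
                                scale_transform(c(x = 1e-20, y = 1))),
               "singular|invertible")
})

test_that("rasterizing a transformed polygon agrees with transforming the raster", {
  # raster/vector consistency away from the boundary
  g <- square_poly(2, 3, 9, 8)
  t <- translation_transform(c(x = 3, y = 2))
  dims <- c(y = 16L, x = 16L)
  direct <- rasterize_geometry(transform_geometry(g, t), dims)
  moved <- transform_raster(labels_element(rasterize_geometry(g, dims)), t,
                            output_extent = list(y = c(0, 16), x = c(0, 16)))
  expect_equal(materialize(moved$data), unname(direct))
})

test_that("transformation records serialize losslessly", {
  ts <- list(identity_transform(),
             scale_transform(c(x = 2.5, y = 0.1)),
             translation_transform(c(x = -3, y = 4)),
             random_affine2d(),
             sequence_transform(list(scale_transform(c(x = 2)),
                                     translation_transform(c(y = 1)))))
  for (t in ts) {
    back <- transform_from_list(jsonlite::fromJSON(
      jsonlite::toJSON(transform_to_list(t), auto_unbox = TRUE, digits = NA),
      simplifyVector = FALSE))
    expect_equal(to_affine_matrix(back, c("x", "y")),
                 to_affine_matrix(t, c("x", "y")), tolerance = 1e-12)
  }
})
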