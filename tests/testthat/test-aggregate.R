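make_agg_ds <- function(points_df, geoms, shape_data = NULL) {
  spatial_dataset(points = list(p = points_element(points_df)),
                  shapes = list(s = shapes_element(geoms, data = shape_data)))
}

test_that("point counts per shape follow closed containment", {
  ds <- make_agg_ds(data.frame(x = c(0, 0.2, -0.3, 5), y = c(0, 0.1, 0, 5)),
                    list(circle(c(x = 0, y = 0), 1)))
  tab <- aggregate_points_by_shapes(ds, "p", "s")
  expect_equal(as.vector(tab$X), 3)
  expect_identical(tab$region, "s")
  expect_identical(tab$obs$instance_id, 1L)
  # categorical counts
  ds2 <- make_agg_ds(data.frame(x = c(0.5, 0.6, 0.5, 9), y = c(0.5, 0.5, 0.6, 9),
                                g = factor(c("A", "A", "B", "A"))),
                     list(square_poly(0, 0, 1, 1)))
  tab2 <- aggregate_points_by_shapes(ds2, "p", "s", value_key = "g")
  expect_equal(tab2$X[1, ], c(A = 2, B = 1))
  # numeric sum / mean
  ds3 <- make_agg_ds(data.frame(x = c(0.5, 0.6, 9), y = c(0.5, 0.5, 9),
                                v = c(2, 4, 100)),
                     list(square_poly(0, 0, 1, 1)))
  expect_equal(as.vector(aggregate_points_by_shapes(ds3, "p", "s", "v", "sum")$X), 6)
  expect_equal(as.vector(aggregate_points_by_shapes(ds3, "p", "s", "v", "mean")$X), 3)
  expect_error(aggregate_points_by_shapes(ds3, "p", "s", "v", "count"),
               "categorical")
  expect_error(aggregate_points_by_shapes(ds3, "p", "s", "missing"), "no column")
})

test_that("random point aggregation equals the brute-force count matrix", {
  set.seed(81)
  n <- 1000; m <- 10
  pts <- data.frame(x = runif(n, 0, 50), y = runif(n, 0, 50),
                    g = factor(sample(LETTERS[1:4], n, replace = TRUE)))
  circles <- lapply(seq_len(m), function(i)
    circle(c(x = runif(1, 5, 45), y = runif(1, 5, 45)), runif(1, 2, 8)))
  ds <- make_agg_ds(pts, circles)
  tab <- aggregate_points_by_shapes(ds, "p", "s", value_key = "g")
  oracle <- matrix(0, m, 4, dimnames = list(NULL, LETTERS[1:4]))
  for (j in seq_len(m)) {
    cc <- circles[[j]]
    for (i in seq_len(n)) {
      if ((pts$x[i] - cc$center[["x"]])^2 + (pts$y[i] - cc$center[["y"]])^2 <=
          cc$radius^2) {
        oracle[j, as.character(pts$g[i])] <- oracle[j, as.character(pts$g[i])] + 1
      }
    }
  }
  expect_equal(unname(tab$X), unname(oracle))
  # conservation: disjoint-or-not, total counted <= n
  expect_lte(sum(tab$X), n)
})

test_that("overlap weights are source-normalised and conserved", {
  src <- shapes_element(list(square_poly(0, 0, 1, 1),      # fully inside
                             square_poly(0.5, 0, 1.5, 1)), # half inside
                        data = data.frame(cat = factor(c("A", "B"))))
  tgt <- shapes_element(list(square_poly(0, 0, 1, 1)))
  ds <- spatial_dataset(shapes = list(src = src, tgt = tgt))
  raw <- aggregate_shapes_by_shapes(ds, "src", "tgt", value_key = "cat")
  expect_equal(raw$X[1, ], c(A = 1, B = 0.5), tolerance = 1e-12)
  fr <- aggregate_shapes_by_shapes(ds, "src", "tgt", value_key = "cat",
                                   fractions = TRUE)
  expect_equal(fr$X[1, ], c(A = 2 / 3, B = 1 / 3), tolerance = 1e-12)
  expect_true(fr$obs$covered)
  # a source split over targets that tile it contributes exactly 1 in total
  tgt2 <- shapes_element(list(square_poly(0, 0, 0.75, 1),
                              square_poly(0.75, 0, 2, 1)))
  ds2 <- spatial_dataset(shapes = list(src = src, tgt = tgt2))
  raw2 <- aggregate_shapes_by_shapes(ds2, "src", "tgt")
  expect_equal(sum(raw2$X), 2, tolerance = 1e-9)
  expect_error(aggregate_shapes_by_shapes(ds, "src", "tgt", fractions = TRUE),
               "categorical")
})

test_that("circle-square weights match the analytic segment area within 1%", {
  # circle r = 1 at origin; square keeps the part right of x = 0.5:
  # segment area = acos(d) - d * sqrt(1 - d^2), d = 0.5
  src <- shapes_element(list(circle(c(x = 0, y = 0), 1)),
                        data = data.frame(cat = factor("A")))
  tgt <- shapes_element(list(square_poly(0.5, -2, 3, 2)))
  ds <- spatial_dataset(shapes = list(src = src, tgt = tgt))
  w <- aggregate_shapes_by_shapes(ds, "src", "tgt")$X[1, 1]
  seg <- (acos(0.5) - 0.5 * sqrt(0.75)) / pi
  expect_lt(abs(w - seg) / seg, 0.01)
})

test_that("fraction rows sum to one and no-overlap rows are flagged", {
  set.seed(82)
  n_src <- 15
  src <- shapes_element(
    lapply(seq_len(n_src), function(i)
      circle(c(x = runif(1, 0, 30), y = runif(1, 0, 30)), runif(1, 1, 3))),
    data = data.frame(cat = factor(sample(c("A", "B", "C"), n_src, TRUE))))
  tgt <- shapes_element(c(lapply(1:6, function(i)
    circle(c(x = runif(1, 0, 30), y = runif(1, 0, 30)), 4)),
    list(circle(c(x = 500, y = 500), 1))))   # guaranteed empty target
  ds <- spatial_dataset(shapes = list(src = src, tgt = tgt))
  fr <- aggregate_shapes_by_shapes(ds, "src", "tgt", value_key = "cat",
                                   fractions = TRUE)
  sums <- rowSums(fr$X)
  expect_true(all(abs(sums[fr$obs$covered] - 1) < 1e-9))
  expect_true(all(sums[!fr$obs$covered] == 0))
  expect_false(fr$obs$covered[7])
  # per-source conservation in the raw weights
  raw <- aggregate_shapes_by_shapes(ds, "src", "tgt")
  W <- spatialkit:::shape_overlap_weights(src$geometries, tgt$geometries)
  expect_true(all(rowSums(W) <= 1 + 1e-6))
})

test_that("aggregation is invariant under a joint affine of source and target", {
  set.seed(83)
  src <- shapes_element(lapply(1:5, function(i)
    circle(c(x = runif(1, 0, 20), y = runif(1, 0, 20)), runif(1, 1, 3))),
    data = data.frame(cat = factor(c("A", "B", "A", "B", "A"))))
  tgt <- shapes_element(lapply(1:4, function(i)
    square_poly(runif(1, 0, 15), runif(1, 0, 15), runif(1, 16, 20),
                runif(1, 16, 20))))
  ds <- spatial_dataset(shapes = list(src = src, tgt = tgt))
  base <- aggregate_shapes_by_shapes(ds, "src", "tgt", value_key = "cat",
                                     fractions = TRUE)
  t <- rotation_affine(0.7, 1.3, 5, -2)
  ds2 <- spatial_dataset(shapes = list(
    src = transform_vector_element(src, t),
    tgt = transform_vector_element(tgt, t)))
  moved <- aggregate_shapes_by_shapes(ds2, "src", "tgt", value_key = "cat",
                                      fractions = TRUE)
  expect_lt(max(abs(moved$X - base$X)), 1e-6)
})

test_that("label masks aggregate by pixel counting", {
  lab <- matrix(0L, 10, 10)
  lab[1:4, 1:4] <- 1L    # 16 px, half inside the box below
  lab[6:9, 6:9] <- 2L    # 16 px, all outside
  ds <- spatial_dataset(labels = list(l = labels_element(lab)),
                        shapes = list(s = shapes_element(
                          list(square_poly(0, 0, 2, 10)))))
  tab <- aggregate_labels_by_shapes(ds, "l", "s")
  expect_equal(as.vector(tab$X), 0.5)   # 8 of 16 px of id 1, 0 of id 2
})

test_that("the minor-category display filter renormalizes rows", {
  X <- rbind(c(0.9, 0.07, 0.03), c(0.5, 0.5, 0), c(0.04, 0.03, 0.93))
  colnames(X) <- c("A", "B", "C")
  tab <- table_element(X, obs = data.frame(region = rep("s", 3),
                                           instance_id = 1:3),
                       region = "s", region_key = "region",
                       instance_key = "instance_id")
  f <- filter_fraction_table(tab, min_fraction = 0.05)
  expect_equal(f$X[1, ], c(A = 0.9, B = 0.07, C = 0) / 0.97)
  expect_equal(f$X[2, ], c(A = 0.5, B = 0.5, C = 0))
  expect_equal(f$X[3, ], c(A = 0, B = 0, C = 1))
  expect_equal(rowSums(f$X), rep(1, 3))
})

test_that("aggregation tables can be stored as layers of a matching table", {
  ds <- generate_blobs(small_cfg(seed = 4))
  counts <- aggregate_points_by_shapes(ds, "transcripts", "circles",
                                       value_key = "category")
  ds <- add_aggregation_table(ds, counts, "circle_counts")
  expect_true("circle_counts" %in% names(ds$tables))
  again <- aggregate_points_by_shapes(ds, "transcripts", "circles",
                                      value_key = "category")
  ds <- add_aggregation_table(ds, again, "rep2", layer_of = "circle_counts")
  expect_identical(names(ds$tables$circle_counts$layers), "rep2")
  expect_equal(ds$tables$circle_counts$layers$rep2, as.matrix(again$X))
  truncated <- spatialkit:::subset_table(again, 1:2)
  expect_error(add_aggregation_table(ds, truncated, "bad",
                                     layer_of = "circle_counts"))
})
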