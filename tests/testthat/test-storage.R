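blobs_store <- function(seed = 2, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ds <- generate_blobs(small_cfg(seed = seed))
  path <- file.path(dir, "blobs.zarr")
  write_store(ds, path)
  list(ds = ds, path = path)
}

test_that("a written store round-trips every element exactly", {
  st <- blobs_store()
  ds <- st$ds
  back <- read_store(st$path, lazy = FALSE)
  # rasters bitwise, all pyramid levels
  for (k in c("images", "labels")) {
    for (nm in names(ds[[k]])) {
      expect_length(back[[k]][[nm]]$pyramid, length(ds[[k]][[nm]]$pyramid))
      for (i in seq_along(ds[[k]][[nm]]$pyramid)) {
        expect_identical(materialize(back[[k]][[nm]]$pyramid[[i]]) * 1,
                         materialize(ds[[k]][[nm]]$pyramid[[i]]) * 1)
      }
    }
  }
  # point coordinates exact, ids and categoricals preserved
  expect_identical(back$points$transcripts$data$x, ds$points$transcripts$data$x)
  expect_identical(back$points$transcripts$data$y, ds$points$transcripts$data$y)
  expect_identical(back$points$transcripts$instance_ids,
                   ds$points$transcripts$instance_ids)
  expect_identical(back$points$transcripts$data$category,
                   ds$points$transcripts$data$category)
  # shapes: circles as typed records, polygons via WKB
  expect_equal(back$shapes$circles$geometries, ds$shapes$circles$geometries)
  expect_equal(back$shapes$blob_polygons$geometries,
               ds$shapes$blob_polygons$geometries)
  expect_identical(back$shapes$blob_polygons$data$category,
                   ds$shapes$blob_polygons$data$category)
  # table, including linkage metadata
  expect_equal(unname(as.matrix(back$tables$blob_annotation$X)),
               unname(as.matrix(ds$tables$blob_annotation$X)))
  expect_identical(back$tables$blob_annotation$obs$category,
                   ds$tables$blob_annotation$obs$category)
  expect_identical(back$tables$blob_annotation$instance_key, "instance_id")
  # transformation matrices to 1e-12
  for (k in c("images", "labels", "points", "shapes")) {
    for (nm in names(ds[[k]])) {
      for (cs in names(ds[[k]][[nm]]$transformations)) {
        expect_equal(
          to_affine_matrix(back[[k]][[nm]]$transformations[[cs]], c("x", "y")),
          to_affine_matrix(ds[[k]][[nm]]$transformations[[cs]], c("x", "y")),
          tolerance = 1e-12)
      }
    }
  }
  expect_identical(validate_dataset(back), character(0))
})

test_that("write, read, write again reproduces identical bytes for coordinates", {
  dir <- withr::local_tempdir()
  st <- blobs_store(seed = 7, dir = dir)
  back <- read_store(st$path, lazy = FALSE)
  p2 <- file.path(dir, "copy.zarr")
  write_store(back, p2)
  f1 <- file.path(st$path, "points", "transcripts", "points.parquet")
  f2 <- file.path(p2, "points", "transcripts", "points.parquet")
  df1 <- as.data.frame(arrow::read_parquet(f1))
  df2 <- as.data.frame(arrow::read_parquet(f2))
  expect_identical(df1, df2)
  a1 <- materialize(read_store(st$path, lazy = FALSE)$images$blob_image$data)
  a2 <- materialize(read_store(p2, lazy = FALSE)$images$blob_image$data)
  expect_identical(a1, a2)
})

test_that("lazy reads and store summaries touch no raster chunks", {
  st <- blobs_store(seed = 3)
  chunk_read_count(reset = TRUE)
  ds <- read_store(st$path, lazy = TRUE)
  info <- describe_store(st$path)
  # full access to vector/tabular content and metadata, still no chunks
  invisible(ds$points$transcripts$data)
  invisible(ds$shapes$circles$geometries)
  invisible(ds$tables$blob_annotation$X)
  invisible(lapply(ds$images$blob_image$transformations, transform_to_list))
  expect_identical(chunk_read_count(), 0L)
  # materializing does read chunks
  invisible(materialize(ds$images$blob_image$data))
  expect_gt(chunk_read_count(reset = TRUE), 0L)
  # the summary has the expected content
  expect_setequal(info$kind, c("image", "labels", "points", "shapes", "table"))
  expect_equal(info$n[info$name == "transcripts"], 400)
  expect_equal(info$n[info$name == "circles"], 8)
  expect_equal(sum(info$kind == "shapes"), 2)
  expect_identical(attr(info, "format_version"), "0.1")
})

test_that("store write is refused for invalid input, path or dialect", {
  ds <- generate_blobs(small_cfg(seed = 4))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.zarr")
  write_store(ds, p)
  expect_error(write_store(ds, p), "exists")
  expect_silent(write_store(ds, p, overwrite = TRUE))
  # broken table linkage fails validation before any write
  ds_bad <- ds
  ds_bad$tables$blob_annotation$obs$instance_id[1] <- 9999L
  p_bad <- file.path(dir, "bad.zarr")
  expect_error(write_store(ds_bad, p_bad), "validation")
  expect_false(dir.exists(p_bad))
  # missing root version marker is reported by name
  unlink(file.path(p, ".zattrs"))
  expect_error(read_store(p), "missing root attributes")
  write_json <- function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE)
  write_json(list(spatialkit = list(format = "spatialkit-store")),
             file.path(p, ".zattrs"))
  expect_error(read_store(p), "format_version")
  expect_error(read_store(file.path(dir, "nope")), "no store")
})

test_that("sparse matrices round-trip as CSR triplets", {
  X <- Matrix::rsparsematrix(30, 8, density = 0.2)
  colnames(X) <- paste0("g", 1:8)
  tab <- table_element(X, obs = data.frame(sample = letters[1:30 %% 3 + 1]))
  ds <- spatial_dataset(tables = list(t = tab))
  dir <- withr::local_tempdir()
  write_store(ds, file.path(dir, "t.zarr"))
  back <- read_store(file.path(dir, "t.zarr"))
  expect_s4_class(back$tables$t$X, "dgRMatrix")
  expect_equal(as.matrix(back$tables$t$X), as.matrix(X), tolerance = 0)
  expect_identical(back$tables$t$obs$sample, tab$obs$sample)
})

test_that("tables with layers and an empty dataset survive the store", {
  ds <- generate_blobs(small_cfg(seed = 5))
  counts <- aggregate_points_by_shapes(ds, "transcripts", "circles",
                                       value_key = "category")
  ds <- add_aggregation_table(ds, counts, "counts")
  ds$tables$counts$layers$rep2 <- as.matrix(counts$X) * 2
  dir <- withr::local_tempdir()
  p <- file.path(dir, "l.zarr")
  write_store(ds, p)
  back <- read_store(p)
  expect_equal(back$tables$counts$layers$rep2,
               unname(ds$tables$counts$layers$rep2) + 0)
  # empty dataset: a valid store with an empty listing
  p0 <- file.path(dir, "empty.zarr")
  write_store(spatial_dataset(), p0)
  expect_equal(nrow(describe_store(p0)), 0L)
  expect_identical(validate_dataset(read_store(p0)), character(0))
})

test_that("transformation write-back persists through the store", {
  st <- blobs_store(seed = 6)
  ds <- read_store(st$path)
  t_new <- rotation_affine(0.25, 1.05, 3.5, -1.25)
  e <- set_transformation(ds$shapes$circles, "ccs", t_new,
                          store = st$path, name = "circles")
  back <- read_store(st$path)
  expect_equal(to_affine_matrix(back$shapes$circles$transformations$ccs,
                                c("x", "y")),
               to_affine_matrix(t_new, c("x", "y")), tolerance = 1e-12)
  # other entries untouched
  expect_identical(back$shapes$circles$transformations$global$type, "identity")
})

test_that("raster groups are readable by a generic NGFF-aware Zarr reader", {
  # the multiscales metadata and the chunked arrays themselves follow the
  # Zarr v2 / NGFF conventions; an independent reader must agree on content
  st <- blobs_store(seed = 8)
  script <- paste(
    "import zarr, numpy as np, json, sys",
    "root = sys.argv[1]",
    "a = np.asarray(zarr.open(root + '/images/blob_image/0', mode='r'))",
    "meta = json.load(open(root + '/images/blob_image/.zattrs'))",
    "axes = [ax['name'] for ax in meta['multiscales'][0]['axes']]",
    "print(json.dumps({'sum': float(a.sum()), 'shape': list(a.shape), 'axes': axes}))",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-", st$path), input = script,
                                  stdout = TRUE, stderr = FALSE))
  res <- jsonlite::fromJSON(out[length(out)])
  arr <- materialize(st$ds$images$blob_image$data)
  expect_equal(res$sum, sum(arr), tolerance = 1e-9)
  expect_equal(res$shape, dim(arr))
  expect_identical(res$axes, c("c", "y", "x"))
})
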