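test_that("TRK and TCK files round-trip world-mm streamlines", {
  affine <- diag(c(2, 2, 2, 1)); affine[1:3, 4] <- c(-10, -20, -30)
  sls <- lapply(1:3, function(s) random_polyline(10, s))
  tg <- tractogram(sls, affine, c(40L, 40L, 40L))
  for (ext in c(".trk", ".tck")) {
    f <- withr::local_tempfile(fileext = ext)
    write_tractogram(tg, f)
    back <- read_tractogram(f)
    expect_length(back$streamlines, 3L)
    for (s in 1:3)
      expect_lt(max(abs(back$streamlines[[s]] - sls[[s]])), 1e-4)
  }
})

test_that("degenerate streamlines are filtered at load with a warning", {
  good1 <- rbind(c(1, 1, 1), c(5, 5, 5), c(9, 9, 9))
  onept <- matrix(c(2, 2, 2), 1, 3)
  good2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  fake <- structure(list(streamlines = list(good1, onept, good2),
                         affine = diag(4), dim = c(20L, 20L, 20L)),
                    class = "tractogram")
  f <- withr::local_tempfile(fileext = ".tck")
  tractometr:::write_tck(fake, f)
  expect_warning(back <- read_tractogram(f), "1 degenerate")
  expect_length(back$streamlines, 2L)
})

test_that("volume sampling interpolates in voxel space", {
  vol <- unit_grid_volume(c(6, 5, 5), fill = 3.25)
  pts <- matrix(runif(30, 0, 4), 10, 3)
  expect_equal(as.numeric(sample_volume(vol, pts, "trilinear")),
               rep(3.25, 10))

  ramp <- unit_grid_volume(c(10, 5, 5))
  for (i in 1:10) ramp$data[i, , ] <- i - 1
  expect_equal(as.numeric(sample_volume(ramp, matrix(c(1.5, 0, 0), 1))), 1.5)
  expect_equal(as.numeric(sample_volume(ramp, matrix(c(3, 2, 2), 1),
                                        "nearest")), 3)
  expect_equal(as.numeric(sample_volume(ramp, matrix(c(3, 2, 2), 1),
                                        "trilinear")), 3)

  # trilinear reproduces any affine-linear field exactly in the interior
  lin <- unit_grid_volume(c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    lin$data[i, j, k] <- 2 * (i - 1) - 0.5 * (j - 1) + 0.25 * (k - 1) + 1
  set.seed(42)
  pts <- matrix(runif(60, 0.5, 6.5), 20, 3)
  want <- 2 * pts[, 1] - 0.5 * pts[, 2] + 0.25 * pts[, 3] + 1
  expect_equal(as.numeric(sample_volume(lin, pts, "trilinear")), want,
               tolerance = 1e-12)

  # out-of-grid points fill 0 and are counted
  v <- sample_volume(vol, matrix(c(100, 100, 100), 1))
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "n_outside"), 1L)
})

test_that("distance to mask matches the brute-force scan", {
  affine <- diag(c(2, 2, 2, 1))
  data <- array(0, dim = c(8, 8, 8)); data[1, 1, 1] <- 1
  mask <- mask_volume(data, affine, "roi", "single")
  expect_equal(min_distance_to_mask(matrix(c(0, 0, 0), 1), mask), 0)
  expect_equal(min_distance_to_mask(matrix(c(5, 0, 0), 1), mask), 5)

  set.seed(7)
  for (rep in 1:5) {
    d2 <- array(0, dim = c(6, 7, 5))
    d2[sample(length(d2), 12)] <- 1
    m2 <- mask_volume(d2, affine, "roi", "rand")
    pts <- matrix(runif(15, -4, 16), 5, 3)
    expect_equal(min_distance_to_mask(pts, m2), oracle_min_distance(pts, m2),
                 tolerance = 1e-9)
  }

  empty <- mask_volume(array(0, dim = c(3, 3, 3)), affine, "roi", "the_roi")
  expect_error(min_distance_to_mask(matrix(0, 1, 3), empty), "the_roi")
})

test_that("NIfTI volumes round-trip through RNifti with their affine", {
  affine <- diag(c(1.5, 1.5, 3, 1)); affine[1:3, 4] <- c(-20, -30, -10)
  vol <- scalar_volume(array(runif(4 * 5 * 6), dim = c(4, 5, 6)), affine, "FA")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_scalar_volume(f, "FA")
  expect_equal(back$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$affine, affine, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("tidy CSV writer enforces schema, order and round-trips", {
  grid <- expand.grid(node_id = 0:99, metric = c("FA", "MD"),
                      stringsAsFactors = FALSE)
  table <- data.frame(subject_id = "sub-001", tract_name = "CST_R",
                      node_id = grid$node_id, metric = grid$metric,
                      value = rnorm(nrow(grid)))
  expect_equal(nrow(table), 200L)
  expect_equal(max(table$node_id), 99L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tidy_csv(table, f)
  expect_identical(readLines(f, n = 1),
                   "subject_id,tract_name,node_id,metric,value")
  back <- read_tidy_csv(f)
  key <- function(d) paste(d$subject_id, d$tract_name, d$node_id, d$metric)
  expect_setequal(key(back), key(table))
  expect_equal(back$value[match(key(table), key(back))], table$value,
               tolerance = 1e-12)

  dup <- rbind(table, table[1, ])
  expect_error(write_tidy_csv(dup, f), "duplicate")
})

test_that("wide pivot yields one row per subject and one column per feature", {
  dat <- make_group_dataset(3, n_nodes = 5, seed = 2)
  wide <- tidy_to_wide(dat$table)
  expect_equal(nrow(wide), 6L)
  expect_equal(ncol(wide), 1L + 5L)
  expect_false(anyNA(wide))
})
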