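# ROI fixtures on an identity-affine grid: single-voxel masks at known
# world coordinates, streamlines as simple polylines.

roi_at <- function(ijk, dims = c(30, 30, 30), name = "roi") {
  data <- array(0, dim = dims)
  data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <- 1
  mask_volume(data, diag(4), "roi", name)
}

# distance-to-mask is point-based, so fixtures carry densely sampled points
dense <- function(a, b, n = 57) resample_streamline(rbind(a, b), n)

test_that("inclusion requires every waypoint, exclusion forbids any", {
  way1 <- roi_at(c(5, 10, 10))
  way2 <- roi_at(c(20, 10, 10))
  through <- dense(c(0, 10, 10), c(28, 10, 10))
  missed <- dense(c(0, 13, 10), c(28, 13, 10))  # 3 mm off both waypoints

  expect_true(passes_include(through, list(list(mask = way1, tol = 0),
                                           list(mask = way2, tol = 0))))
  expect_false(passes_include(missed, list(list(mask = way1, tol = 0),
                                           list(mask = way2, tol = 0))))
  expect_true(passes_include(missed, list(list(mask = way1, tol = 4),
                                          list(mask = way2, tol = 4))))

  expect_true(passes_exclude(missed, list(list(mask = way1, tol = 0))))
  expect_false(passes_exclude(through, list(list(mask = way1, tol = 0))))
  # grazing pass at 1.5 mm with tolerance 2 is excluded
  graze <- dense(c(0, 11.5, 10), c(28, 11.5, 10))
  expect_false(passes_exclude(graze, list(list(mask = way1, tol = 2))))
})

test_that("endpoint criterion accepts either orientation and flags the flip", {
  start <- roi_at(c(2, 10, 10))
  end <- roi_at(c(25, 10, 10))
  sl <- rbind(c(2, 10, 10), c(12, 10, 10), c(25, 10, 10))

  r <- passes_endpoints(sl, start, end)
  expect_true(r$pass); expect_false(r$flip)
  r <- passes_endpoints(flip_streamline(sl), start, end)
  expect_true(r$pass); expect_true(r$flip)
  off <- rbind(c(8, 10, 10), c(25, 10, 10))
  r <- passes_endpoints(off, start, end)
  expect_false(r$pass)
  expect_error(passes_endpoints(sl), "at least one")
})

test_that("probability-map criterion averages along 100 nodes, strictly", {
  ones <- mask_volume(array(1, dim = c(30, 30, 30)), diag(4), "prob")
  zeros <- mask_volume(array(0, dim = c(30, 30, 30)), diag(4), "prob")
  sl <- rbind(c(2, 10, 10), c(25, 10, 10))
  expect_true(passes_prob_map(sl, ones, 0.5))
  expect_false(passes_prob_map(sl, zeros, 0))   # strict inequality

  # first half of the path over 0.8, second half over 0.0 -> mean 0.4
  half <- array(0, dim = c(30, 30, 30))
  half[1:14, , ] <- 0.8
  halfmap <- mask_volume(half, diag(4), "prob")
  sl2 <- rbind(c(0, 10, 10), c(26, 10, 10))
  expect_false(passes_prob_map(sl2, halfmap, 0.5))
  expect_true(passes_prob_map(sl2, halfmap, 0.3))
})

test_that("length and primary-axis criteria threshold as documented", {
  sl50 <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_true(passes_length(sl50, 10, 200))
  expect_true(passes_length(sl50, 50, 200))     # inclusive bound
  expect_false(passes_length(rbind(c(0, 0, 0), c(250, 0, 0)), 10, 200))

  vertical <- rbind(c(5, 5, 0), c(5, 5, 40))
  expect_true(passes_primary_axis(vertical, "I/S", 90))
  diag45 <- rbind(c(0, 0, 0), c(10, 0, 10))
  expect_false(passes_primary_axis(diag45, "I/S", 60))
  expect_true(passes_primary_axis(diag45, "I/S", 50))
  sl <- random_polyline(8, 3)
  frac <- primary_axis_fraction(sl)
  expect_equal(passes_primary_axis(sl, "P/A", 30), frac[["P/A"]] * 100 >= 30)
})

test_that("shape prior thresholds the minimum MDF to the references", {
  ref <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_true(passes_shape_prior(ref, list(ref), 1))
  expect_true(passes_shape_prior(flip_streamline(ref), list(ref), 1))
  offset <- rbind(c(0, 10, 0), c(50, 10, 0))
  expect_false(passes_shape_prior(offset, list(ref), 5))
  expect_true(passes_shape_prior(offset, list(ref), 10))
  expect_error(passes_shape_prior(ref, list(), 5), "empty")
})

test_that("recognition recovers planted bundles exactly on a phantom", {
  ph <- make_phantom(default_phantom_bundles()[1:2], n_distractors = 30L,
                     seed = 5L)
  defs <- phantom_definitions(ph)
  res <- recognize(ph$tractogram, defs)
  for (tract in names(defs)) {
    got <- res$bundles[[tract]]$indices
    want <- which(ph$truth == tract)
    expect_setequal(got, want)
  }
  expect_true(all(is.na(res$assignments[ph$truth == "distractor"])))
  # tallies partition the candidate pool
  for (tract in names(defs))
    expect_equal(sum(res$tallies[[tract]]), length(ph$tractogram$streamlines))
})

test_that("ties go to the first-listed tract with one warning", {
  way <- roi_at(c(10, 10, 10))
  crit <- bundle_criteria(include = list(list(mask = way, tol = 1)))
  sl <- dense(c(0, 10, 10), c(20, 10, 10), 41)
  tg <- tractogram(list(sl), diag(4), c(30L, 30L, 30L))

  res_ab <- recognize(tg, bundle_definitions(A = crit, B = crit))
  expect_equal(res_ab$assignments, "A")
  expect_length(res_ab$warnings, 1L)
  expect_match(res_ab$warnings, "satisfies both")

  res_ba <- recognize(tg, bundle_definitions(B = crit, A = crit))
  expect_equal(res_ba$assignments, "B")
  expect_length(res_ba$warnings, 1L)
})

test_that("rejections are tallied under the earliest failing criterion", {
  zeros <- mask_volume(array(0, dim = c(30, 30, 30)), diag(4), "prob")
  way <- roi_at(c(10, 10, 10))
  # the streamline fails prob_map (mean 0 not > 0) AND misses the waypoint
  sl <- rbind(c(0, 25, 25), c(20, 25, 25))
  tg <- tractogram(list(sl), diag(4), c(30L, 30L, 30L))
  defs <- bundle_definitions(T1 = bundle_criteria(
    prob_map = list(mask = zeros, threshold = 0),
    include = list(list(mask = way, tol = 0))))
  res <- recognize(tg, defs)
  expect_equal(unname(res$tallies$T1[["prob_map"]]), 1L)
  expect_equal(unname(res$tallies$T1[["include"]]), 0L)
  expect_equal(unname(res$tallies$T1[["accepted"]]), 0L)
})

test_that("removing a criterion never shrinks the accepted set", {
  ph <- make_phantom(default_phantom_bundles()[1], n_distractors = 20L,
                     seed = 9L)
  r <- ph$rois$arc_low
  full <- bundle_criteria(include = list(list(mask = r$way1, tol = 2),
                                         list(mask = r$way2, tol = 2)),
                          start = r$start, end = r$end,
                          length = list(min_len = 40, max_len = 120))
  reduced <- bundle_criteria(include = list(list(mask = r$way1, tol = 2),
                                            list(mask = r$way2, tol = 2)))
  n_full <- sum(!is.na(recognize(ph$tractogram,
                                 bundle_definitions(x = full))$assignments))
  n_red <- sum(!is.na(recognize(ph$tractogram,
                                bundle_definitions(x = reduced))$assignments))
  expect_gte(n_red, n_full)
})

test_that("empty tractograms and unknown config keys are reported", {
  tg <- tractogram(list(), diag(4), c(10L, 10L, 10L))
  res <- recognize(tg, bundle_definitions(
    A = bundle_criteria(length = list(min_len = 1, max_len = 10))))
  expect_length(res$assignments, 0L)
  expect_match(res$warnings, "empty tractogram")

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tracts:", "  CST:", "    lenght:", "      min_len: 10",
               "      max_len: 20"), cfg)
  expect_error(read_bundle_config(cfg), "lenght")
})
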