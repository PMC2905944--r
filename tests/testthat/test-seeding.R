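test_that("peak_voxel finds the maximum with lowest-index tie-breaking", {
  vals <- rep(0, 30); vals[17] <- 5
  sd1 <- peak_voxel(vec_map(vals))
  expect_equal(which(sd1$voxel_mask$include), 17)
  expect_equal(sd1$peak_index, 17L)

  tied <- rep(0, 30); tied[c(3, 9)] <- 7
  sd2 <- peak_voxel(vec_map(tied))
  expect_equal(which(sd2$voxel_mask$include), 3)

  expect_error(peak_voxel(vec_map(rep(2, 10))), "constant")
})

test_that("peak_voxel reports 0-based voxel and world-mm coordinates", {
  # grid where voxel (i,j,k)=(4,2,3) sits at mm (-12, -102, 3)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-24, -108, -6)
  g <- geometry(c(10, 10, 5), voxel_size = c(3, 3, 3), affine = aff)
  mask <- brain_mask(rep(TRUE, 500), g)
  vals <- rnorm(500, sd = 0.5)
  lin <- 1 + 4 + 10 * (2 + 10 * 3)
  vals[lin] <- 18.27
  seed <- peak_voxel(stat_map(vals, mask, "z"))
  expect_equal(seed$peak_value, 18.27)
  expect_equal(unname(voxel_coords(g, seed$peak_linear)[1, ]), c(4, 2, 3))
  expect_equal(unname(seed$peak_world), c(-12, -102, 3))
})

test_that("few_voxel_seed keeps voxels within one z-unit of the peak", {
  vals <- c(18.27, 17.8, 17.4, 17.28, 17.5, 17.27, 17.26, rep(5, 93))
  seed <- few_voxel_seed(vec_map(vals))
  expect_equal(sum(seed$voxel_mask$include), 5)  # strictly above 17.27
  expect_equal(which(seed$voxel_mask$include), 1:5)
  expect_equal(seed$voxel_mask$threshold_used, 17.27)

  # only the peak above max - 1: reduces to the single-voxel seed
  solo <- c(10, 8.9, 8.5, rep(0, 20))
  seed2 <- few_voxel_seed(vec_map(solo))
  expect_equal(which(seed2$voxel_mask$include), 1)
  expect_error(few_voxel_seed(vec_map(rep(3, 5))), "constant")
})

test_that("many_voxel_seed picks the integer threshold closest to target", {
  # profile: 118 voxels above 13, 71 above 14 (target 100 -> z > 13);
  # counts keep growing at lower thresholds, as on a real z map
  vals <- c(rep(14.5, 71), rep(13.5, 47), rep(12.5, 150), rep(2, 400))
  seed <- many_voxel_seed(vec_map(vals), 100)
  expect_equal(seed$voxel_mask$threshold_used, 13)
  expect_equal(sum(seed$voxel_mask$include), 118)

  # profile: 40 above 11, 55 above 10 (target 42 -> z > 11)
  vals2 <- c(rep(11.5, 40), rep(10.5, 15), rep(9.5, 100), rep(1, 300))
  seed2 <- many_voxel_seed(vec_map(vals2), 42)
  expect_equal(seed2$voxel_mask$threshold_used, 11)
  expect_equal(sum(seed2$voxel_mask$include), 40)

  # equidistant counts: lower threshold (more voxels) wins
  # z>6: 8, z>5: 12, z>4: 15 -- target 10 is 2 away from both 8 and 12
  vals3 <- c(rep(6.5, 8), rep(5.5, 4), rep(4.5, 3), rep(0.2, 100))
  seed3 <- many_voxel_seed(vec_map(vals3), 10)
  expect_equal(seed3$voxel_mask$threshold_used, 5)
  expect_equal(sum(seed3$voxel_mask$include), 12)
})

test_that("seed masks are nested: the peak is in every seed", {
  set.seed(8)
  vals <- c(rnorm(400), 10 + rnorm(30))
  map <- vec_map(vals)
  peak <- which(peak_voxel(map)$voxel_mask$include)
  expect_true(few_voxel_seed(map)$voxel_mask$include[peak])
  expect_true(many_voxel_seed(map, 20)$voxel_mask$include[peak])
})

test_that("roi_timecourse averages, normalizes and flags degenerate seeds", {
  set.seed(5)
  x <- matrix(rnorm(200), 20, 10)
  run <- mat_run(x)
  one <- rep(0, 10); one[4] <- 5; one[1] <- 1
  seed1 <- peak_voxel(vec_map(one))
  tc <- roi_timecourse(run, seed1)
  expect_equal(tc$values, as.numeric(scale(x[, 4])), tolerance = 1e-12)

  # identical voxels give the same course; order never matters
  x2 <- x; x2[, 7] <- x2[, 3]
  run2 <- mat_run(x2)
  inc <- rep(FALSE, 10); inc[c(3, 7)] <- TRUE
  spec <- icaseed:::new_seed_spec("FV", voxel_mask = vec_binary(inc))
  tc2 <- roi_timecourse(run2, spec)
  expect_equal(tc2$values, as.numeric(scale(x2[, 3])), tolerance = 1e-12)

  # cancelling voxels: degenerate zero course
  x3 <- x; x3[, 2] <- -x3[, 1]
  inc3 <- rep(FALSE, 10); inc3[1:2] <- TRUE
  spec3 <- icaseed:::new_seed_spec("FV", voxel_mask = vec_binary(inc3))
  tc3 <- roi_timecourse(mat_run(x3), spec3)
  expect_true(all(tc3$values == 0))
  expect_true(isTRUE(attr(tc3, "degenerate")))
})

test_that("stage-1 dual regression recovers generating time courses", {
  set.seed(6)
  t <- 60; v <- 2000
  m <- cbind(sin(2 * pi * (1:t) / 12), cos(2 * pi * (1:t) / 30))
  cmaps <- matrix(rnorm(2 * v), 2, v); cmaps[abs(cmaps) < 1] <- 0
  run <- mat_run(m %*% cmaps)
  mask <- run$mask

  # single-component run with its true map supplied: exact recovery
  run1 <- mat_run(outer(m[, 1], cmaps[1, ]))
  tc1 <- dual_regression_stage1(run1, stat_map(cmaps[1, ], mask, "raw"))
  expect_gt(abs(cor(tc1[[1]]$values, m[, 1])), 1 - 1e-10)
  # two-component run, one map supplied: near-exact (slight leakage)
  tc <- dual_regression_stage1(run, stat_map(cmaps[1, ], mask, "raw"))
  expect_gt(abs(cor(tc[[1]]$values, m[, 1])), 0.999)

  # both maps: each course matches its generator
  tcs <- dual_regression_stage1(run, list(stat_map(cmaps[1, ], mask, "raw"),
                                          stat_map(cmaps[2, ], mask, "raw")))
  expect_gt(abs(cor(tcs[[1]]$values, m[, 1])), 0.999)
  expect_gt(abs(cor(tcs[[2]]$values, m[, 2])), 0.999)

  # adding a spatially orthogonal nuisance map leaves the course unchanged
  orth <- rnorm(v)
  orth <- orth - mean(orth)
  d1 <- cmaps[1, ] - mean(cmaps[1, ])
  orth <- orth - sum(orth * d1) / sum(d1^2) * d1
  tcs2 <- dual_regression_stage1(run, list(stat_map(cmaps[1, ], mask, "raw"),
                                           stat_map(orth, mask, "raw")))
  expect_lt(max(abs(tcs2[[1]]$values - tc[[1]]$values)), 1e-6)

  # collinear maps are rejected
  expect_error(
    dual_regression_stage1(run, list(stat_map(cmaps[1, ], mask, "raw"),
                                     stat_map(2 * cmaps[1, ], mask, "raw"))),
    "collinear")
})

test_that("single-map stage 1 equals the map-weighted average time course", {
  set.seed(9)
  x <- matrix(rnorm(40 * 300), 40, 300)
  run <- mat_run(x)
  zvals <- as.numeric(scale(rnorm(300)))
  tc <- dual_regression_stage1(run, stat_map(zvals, run$mask, "z"))[[1]]
  # oracle: regression on a demeaned map = map-weighted sum of the data
  w <- zvals - mean(zvals)
  oracle <- as.numeric(scale(x %*% w))
  expect_equal(tc$values, oracle, tolerance = 1e-8)
})

test_that("seed specs serialize to JSON with coordinates", {
  dir <- withr::local_tempdir()
  vals <- rep(0, 24); vals[10] <- 9.5; vals[11] <- 9.1
  seed <- few_voxel_seed(vec_map(vals))
  path <- file.path(dir, "seed.json")
  save_seed(seed, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$method, "FV")
  expect_equal(parsed$threshold_used, 8.5)
  expect_length(parsed$voxel_index_0based, 2)
})
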