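test_that("placental volume is voxel count times voxel volume", {
  m <- placental_mask(array(TRUE, c(30, 30, 30)), 0.5)
  expect_equal(compute_pv(m), 27000 * 0.125 / 1000)
  empty <- placental_mask(array(FALSE, c(5, 5, 5)), 0.5)
  expect_warning(pv <- compute_pv(empty), "empty")
  expect_equal(pv, 0)
  # hand count on an irregular mask
  inc <- array(FALSE, c(8, 8, 8)); inc[2:4, 3:7, 1:2] <- TRUE
  expect_equal(compute_pv(placental_mask(inc, 0.7)), sum(inc) * 0.7^3 / 1000)
})

test_that("uPVV extraction: strict threshold, mask clipping, monotonicity", {
  g <- voxel_grid(array(100, c(10, 10, 10)), 1)
  m <- placental_mask(array(TRUE, c(10, 10, 10)), 1)
  expect_equal(extract_upvv(g, m, 50)$upvv_cm3, 1.000)
  expect_equal(extract_upvv(g, m, 100)$upvv_cm3, 0)  # strict >
  # signal outside the mask is erased
  half <- placental_mask(array(rep(c(TRUE, FALSE), each = 500), c(10, 10, 10)), 1)
  expect_equal(sum(extract_upvv(g, half, 50)$voxels), 500L)
  expect_error(extract_upvv(g, placental_mask(array(TRUE, c(9, 10, 10)), 1), 50),
               "differ")
  expect_error(extract_upvv(g, m), "mandatory")
  # monotone: larger threshold gives a subset
  set.seed(5)
  gr <- voxel_grid(array(runif(1000, 0, 100), c(10, 10, 10)), 1)
  for (k in 1:5) {
    t1 <- runif(1, 0, 50); t2 <- t1 + runif(1, 0, 50)
    f1 <- extract_upvv(gr, m, t1)$voxels
    f2 <- extract_upvv(gr, m, t2)$voxels
    expect_true(all(!f2 | f1))
  }
})

test_that("skeletonize leaves 1-wide lines untouched with peel depth 0", {
  v <- array(FALSE, c(9, 3, 3)); v[2:8, 2, 2] <- TRUE
  s <- skeletonize(v, 0.5)
  expect_identical(s$voxels, v)
  expect_true(all(s$peel_depth[s$voxels] == 0))
})

test_that("skeletonize reduces a solid bar to a single centreline path", {
  b <- array(FALSE, c(11, 11, 34)); b[3:9, 3:9, 3:32] <- TRUE
  s <- classify_skeleton(skeletonize(b, 1))
  n <- sum(s$voxels)
  expect_gte(n, 20); expect_lte(n, 32)            # ~30-voxel path
  expect_equal(count_components(s$voxels), 1L)
  tab <- table(s$klass[s$voxels])
  expect_equal(unname(tab["end"]), 2L)            # a path has two ends
  expect_equal(sum(s$klass[s$voxels] == "vessel"), n - 2L)
  # peel depth reflects the 7x7 cross-section radius
  expect_gte(mean(s$peel_depth[s$voxels]), 2)
})

test_that("degenerate inputs: ball, empty volume, isolated voxel", {
  ball <- array(FALSE, c(13, 13, 13))
  for (x in 1:13) for (y in 1:13) for (z in 1:13)
    if ((x - 7)^2 + (y - 7)^2 + (z - 7)^2 <= 25) ball[x, y, z] <- TRUE
  s <- skeletonize(ball, 1)
  expect_gte(sum(s$voxels), 1)
  expect_equal(count_components(s$voxels), 1L)

  s0 <- skeletonize(array(FALSE, c(4, 4, 4)), 1)
  expect_equal(sum(s0$voxels), 0)

  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  s1 <- classify_skeleton(skeletonize(one, 1))
  expect_equal(sum(s1$voxels), 1)
  expect_equal(s1$klass[2, 2, 2], "end")  # isolated-voxel convention
})

test_that("classification follows the adjacency rule on canonical shapes", {
  # three collinear voxels
  v <- array(FALSE, c(5, 3, 3)); v[2:4, 2, 2] <- TRUE
  s <- classify_skeleton(skeletonize(v, 1))
  expect_equal(as.vector(s$klass[2:4, 2, 2]), c("end", "vessel", "end"))

  # Y-junction: junction voxel has 3 neighbours, three ends
  y <- make_voxel_y(arm = 3)
  sy <- classify_skeleton(skeletonize(y, 1))
  expect_equal(sum(sy$klass[sy$voxels] == "bifurcation"), 1L)
  expect_equal(sum(sy$klass[sy$voxels] == "end"), 3L)

  # X-junction: four arms meeting at one voxel
  x <- array(FALSE, c(9, 9, 3)); c0 <- 5
  x[c0, c0, 2] <- TRUE
  for (k in 1:3) {
    x[c0 + k, c0 + k, 2] <- TRUE; x[c0 - k, c0 - k, 2] <- TRUE
    x[c0 + k, c0 - k, 2] <- TRUE; x[c0 - k, c0 + k, 2] <- TRUE
  }
  sx <- classify_skeleton(skeletonize(x, 1))
  expect_equal(s <- sum(sx$klass[sx$voxels] == "crossing"), 1L)
  expect_equal(sum(sx$klass[sx$voxels] == "end"), 4L)
})

test_that("classification equals the brute-force neighbour recount", {
  for (s in 1:8) {
    v <- random_blob(c(14, 14, 14), n_balls = 3, seed = s)
    sk <- classify_skeleton(skeletonize(v, 1))
    counts <- brute_neighbour_counts(sk$voxels)
    on <- sk$voxels
    expect_true(all((sk$klass[on] == "end") == (counts[on] <= 1)))
    expect_true(all((sk$klass[on] == "vessel") == (counts[on] == 2)))
    expect_true(all((sk$klass[on] == "bifurcation") == (counts[on] == 3)))
    expect_true(all((sk$klass[on] == "crossing") == (counts[on] >= 4)))
  }
})

test_that("class partition is exhaustive and summary formulas are literal", {
  y <- make_voxel_y(arm = 4)
  sk <- classify_skeleton(skeletonize(y, 0.6))
  vv <- structure(list(voxels = y, upvv_cm3 = sum(y) * 0.6^3 / 1000,
                       threshold = 0, spacing_mm = 0.6),
                  class = "vascular_volume")
  m <- summarize_upvs(sk, vv, pv_cm3 = 2.0)
  n <- sum(sk$voxels)
  expect_equal(m$end_points + m$bifurcation_points + m$crossing_points +
                 m$vessel_points, n)
  expect_equal(m$total_length_mm, n * 0.6)
  expect_equal(m$avg_thickness_mm, mean(sk$peel_depth[sk$voxels]) * 0.6)
  expect_equal(m$density_end, m$end_points / vv$upvv_cm3)
  expect_equal(m$density_bifurcation, m$bifurcation_points / vv$upvv_cm3)

  # spec'd arithmetic: 100 skeleton voxels at 0.6 mm -> 60 mm;
  # 40 end points in 2 cm^3 -> 20 per cm^3 (checked via the same formulas)
  expect_equal(100 * 0.6, 60)
  expect_equal(40 / 2.0, 20)

  bad_vv <- structure(list(voxels = y, upvv_cm3 = 0, threshold = 0,
                           spacing_mm = 0.6), class = "vascular_volume")
  expect_error(summarize_upvs(sk, bad_vv, 1), "inconsistent")
})

test_that("skeletonize preserves 26-connected component count on blobs", {
  set.seed(7)
  for (s in 1:10) {
    v <- random_blob(c(15, 15, 15), n_balls = sample(1:4, 1), seed = 100 + s)
    before <- count_components(v)
    expect_equal(before, flood_components(v))  # C++ labelling vs R oracle
    sk <- skeletonize(v, 1)
    expect_equal(count_components(sk$voxels), before)
  }
})

test_that("marker pipeline recovers phantom truth end-to-end", {
  cfg <- phantom_config(generations = 1, trunk_length_mm = 10,
                        trunk_radius_mm = 1, seed = 2)
  tr <- generate_tree(cfg)
  ras <- rasterize_tree(tr, 0.425)
  m <- run_marker_pipeline(ras$grid, ras$mask, threshold = 0)
  expect_equal(m$end_points, 3)
  expect_equal(m$bifurcation_points, 1)
  expect_equal(m$pv_cm3, compute_pv(ras$mask))
  prov <- attr(m, "provenance")
  expect_equal(prov$threshold, 0)
  expect_equal(prov$spacing_mm, 0.425)

  # noiseless tube: uPVV close to analytic, thickness within 1 voxel of radius
  tube <- generate_tree(phantom_config(generations = 0, trunk_length_mm = 15,
                                       trunk_radius_mm = 1, seed = 1))
  rt <- rasterize_tree(tube, 0.5)
  mt <- run_marker_pipeline(rt$grid, rt$mask, 0)
  expect_lt(abs(mt$upvv_cm3 / (pi * 15 / 1000) - 1), 0.15)
  expect_lt(abs(mt$avg_thickness_mm - 1.0), 0.5)

  # empty grid: all-zero markers
  g0 <- voxel_grid(array(0, c(8, 8, 8)), 0.5)
  m0 <- run_marker_pipeline(g0, placental_mask(array(TRUE, c(8, 8, 8)), 0.5), 0)
  expect_equal(m0$upvv_cm3, 0)
  expect_equal(m0$end_points + m0$vessel_points + m0$bifurcation_points +
                 m0$crossing_points, 0)
  expect_equal(m0$total_length_mm, 0)
})

test_that("average thickness grows with tube radius at fixed topology", {
  th <- sapply(c(0.5, 1.0, 1.5), function(r) {
    tr <- generate_tree(phantom_config(generations = 0, trunk_length_mm = 15,
                                       trunk_radius_mm = r, seed = 1))
    ras <- rasterize_tree(tr, 0.5)
    run_marker_pipeline(ras$grid, ras$mask, 0)$avg_thickness_mm
  })
  expect_true(all(diff(th) > 0))
})

test_that("skeleton label map exports and re-reads", {
  y <- make_voxel_y(arm = 3)
  sk <- classify_skeleton(skeletonize(y, 0.5))
  p <- tempfile(fileext = ".nii.gz")
  export_skeleton(sk, p)
  lab <- read_volume(p)
  expect_equal(sum(lab$values == 1), 3)  # ends
  expect_equal(sum(lab$values == 3), 1)  # bifurcation
  expect_equal(sum(lab$values > 0), sum(sk$voxels))
  unlink(p)
})
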