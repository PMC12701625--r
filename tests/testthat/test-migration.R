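# A synthetic implant model: a ring of surface points around a known CoG.
ring_model <- function(radius = 30, cog = c(0, 75, 0), n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  pts <- cbind(cog[1] + radius * cos(th), cog[2], cog[3] + radius * sin(th))
  list(surface_points = pts, cog = cog, point_count = n)
}

test_that("relative motion is bone^-1 composed with implant", {
  set.seed(41)
  tb <- random_rigid(max_t = 3, max_deg = 5)
  ti <- random_rigid(max_t = 3, max_deg = 5)
  # stable implant: identical transforms cancel
  expect_lt(max(abs(rt_matrix(relative_motion(tb, tb)) - diag(4))), 1e-12)
  # identity bone: relative motion equals the implant transform as a map
  expect_equal(rt_matrix(relative_motion(rt_identity(), ti)), rt_matrix(ti),
               tolerance = 1e-12)
  # point-wise oracle: the relative motion maps baseline implant points to
  # their follow-up positions expressed back in the baseline bone frame
  pts <- matrix(runif(60, -40, 40), ncol = 3)
  lhs <- rt_apply(relative_motion(tb, ti), pts)
  rhs <- rt_apply(rt_invert(tb), rt_apply(ti, pts))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("mtpm equals the exhaustive per-point maximum", {
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(runif(3 * sample(5:400, 1), -50, 50), ncol = 3)
    tf <- random_rigid()
    expect_equal(mtpm(tf, pts), mtpm_bruteforce(tf, pts), tolerance = 1e-12)
  }
  # pure translation: norm of t, independent of the points
  pts <- matrix(runif(300, -50, 50), ncol = 3)
  expect_equal(mtpm(rt_from_params(t = c(1, 2, 2)), pts), 3,
               tolerance = 1e-12)
  # monotone under union
  more <- rbind(pts, matrix(runif(30, 60, 90), ncol = 3))
  tf <- random_rigid()
  expect_gte(mtpm(tf, more), mtpm(tf, pts))
  expect_error(mtpm(rt_identity(), pts[0, , drop = FALSE]), "empty")
})

test_that("mtpm depends only on the map, not the rotation pivot", {
  set.seed(43)
  pts <- matrix(runif(150, -40, 40), ncol = 3)
  tf <- random_rigid(max_deg = 5)
  tf2 <- rt_with_center(tf, c(100, -50, 25))
  expect_equal(mtpm(tf, pts), mtpm(tf2, pts), tolerance = 1e-10)
})

test_that("decomposition reproduces closed-form migration parameters", {
  model <- ring_model()
  # identity: all zero
  res0 <- decompose_motion(rt_identity(), model)
  expect_equal(res0$MTPM, 0)
  expect_equal(res0$TT, 0)
  expect_equal(res0$TR, 0)
  # pure medial translation
  res_t <- decompose_motion(rt_from_params(t = c(1, 0, 0)), model)
  expect_equal(res_t$Tx, 1, tolerance = 1e-12)
  expect_equal(res_t$MTPM, 1, tolerance = 1e-12)
  expect_equal(res_t$TT, 1, tolerance = 1e-12)
  expect_equal(res_t$TR, 0)
  # 1 degree about +y through the CoG, farthest point 30 mm off-axis
  res_r <- decompose_motion(rt_from_params(ry = 1, center = model$cog), model)
  expect_equal(res_r$Ry, 1, tolerance = 1e-9)
  expect_equal(res_r$TT, 0, tolerance = 1e-9)
  expect_equal(res_r$MTPM, 2 * 30 * sin(0.5 * pi / 180), tolerance = 1e-9)
  expect_equal(round(res_r$MTPM, 4), 0.5236)
})

test_that("decomposition agrees with the analytic oracle on ground truth", {
  spec <- small_spec()
  pts <- phantom_implant_points(spec, 90)
  cog <- phantom_implant_cog(spec)
  set.seed(44)
  for (i in 1:10) {
    tf <- random_rigid()
    a <- analytic_migration(tf, pts, cog)
    d <- decompose_motion(tf, list(surface_points = pts, cog = cog,
                                   point_count = nrow(pts)))
    for (f in c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz", "TT", "TR", "MTPM"))
      expect_equal(d[[f]], a[[f]], tolerance = 1e-9)
  }
})

test_that("migration result invariants hold for random motions", {
  model <- ring_model()
  set.seed(45)
  for (i in 1:20) {
    tf <- random_rigid()
    r <- decompose_motion(tf, model)
    expect_gte(r$MTPM, r$TT - 1e-12)
    expect_equal(r$TT, sqrt(r$Tx^2 + r$Ty^2 + r$Tz^2), tolerance = 1e-12)
    expect_equal(r$TR, sqrt(r$Rx^2 + r$Ry^2 + r$Rz^2), tolerance = 1e-12)
    # MTPM bounds the displacement of every surface point
    disp <- sqrt(rowSums((rt_apply(tf, model$surface_points) -
                          model$surface_points)^2))
    expect_gte(r$MTPM, max(disp) - 1e-12)
  }
})

test_that("left knees are mirrored to the right-knee sign convention", {
  model <- ring_model()
  set.seed(46)
  for (i in 1:10) {
    tf <- random_rigid()
    right <- decompose_motion(tf, model, "right")
    left <- decompose_motion(tf, model, "left")
    expect_equal(left$Tx, -right$Tx, tolerance = 1e-12)
    expect_equal(left$Ry, -right$Ry, tolerance = 1e-12)
    expect_equal(left$Rz, -right$Rz, tolerance = 1e-12)
    expect_equal(left$Ty, right$Ty, tolerance = 1e-12)
    expect_equal(left$Rx, right$Rx, tolerance = 1e-12)
    expect_equal(left$MTPM, right$MTPM, tolerance = 1e-12)
    expect_equal(left$TT, right$TT, tolerance = 1e-12)
    expect_equal(left$TR, right$TR, tolerance = 1e-12)
    # sign flips agree with explicit sagittal-mirror conjugation
    mtf <- rt_mirror_sagittal(tf, x0 = model$cog[1])
    mirrored <- decompose_motion(mtf, model, "right")
    expect_equal(left$Rx, mirrored$Rx, tolerance = 1e-9)
    expect_equal(left$Ry, mirrored$Ry, tolerance = 1e-9)
    expect_equal(left$Rz, mirrored$Rz, tolerance = 1e-9)
    expect_equal(left$Tx, mirrored$Tx, tolerance = 1e-9)
  }
})

test_that("implant models derive surface points and CoG from the mask", {
  grid <- array(FALSE, c(7, 7, 7))
  grid[3:5, 3:5, 3:5] <- TRUE
  mask <- voxel_mask(grid, ct_volume(array(0, c(7, 7, 7)), c(1, 1, 1)),
                     "implant")
  m <- implant_model(mask)
  # 3-cube: all but the centre voxel are 6-connectivity boundary
  expect_equal(m$point_count, 26)
  expect_equal(m$cog, c(3, 3, 3))  # world coords of voxel (4,4,4), 0-based
  bb_lo <- apply(m$surface_points, 2, min)
  bb_hi <- apply(m$surface_points, 2, max)
  expect_true(all(m$cog >= bb_lo & m$cog <= bb_hi))
  expect_error(implant_model(voxel_mask(array(FALSE, c(7, 7, 7)),
                                        ct_volume(array(0, c(7, 7, 7)),
                                                  c(1, 1, 1)), "implant")),
               "empty")
})
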